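#' Genotype matrix container
#'
#' Holds an N x m matrix of allele-dosage codes (0/1/2 = AA/AB/BB; for VCF
#' input the code is the count of ALT alleles) together with individual and
#' marker identifiers and the centering state. Missing calls are allowed
#' until [mode_impute()] has been applied; [center_columns()] requires a
#' complete matrix.
#'
#' @param codes numeric matrix, individuals in rows, markers in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param individual_ids character vector of row identifiers.
#' @param marker_ids character vector of column identifiers.
#' @return An object of class `genotype_matrix` with fields `codes`,
#'   `individual_ids`, `marker_ids`, `centered` (logical) and
#'   `column_means` (pre-centering allele-dosage means, `NULL` until
#'   centered; equal to twice the allele frequency).
#' @seealso [read_genotypes()], [mode_impute()], [center_columns()]
#' @export
genotype_matrix <- function(codes, individual_ids = rownames(codes),
                            marker_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (nrow(codes) < 2L) stop("a genotype matrix needs at least 2 individuals")
  if (ncol(codes) < 1L) stop("a genotype matrix needs at least 1 marker")
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(nrow(codes)))
  if (is.null(marker_ids)) marker_ids <- paste0("snp_", seq_len(ncol(codes)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != nrow(codes))
    stop("individual_ids length does not match the number of rows")
  if (length(marker_ids) != ncol(codes))
    stop("marker_ids length does not match the number of columns")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found value ",
         codes[which(bad)[1L]])
  dimnames(codes) <- list(individual_ids, marker_ids)
  structure(
    list(codes = codes, individual_ids = individual_ids,
         marker_ids = marker_ids, centered = FALSE, column_means = NULL),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%s)\n",
              nrow(x$codes), ncol(x$codes),
              if (x$centered) "centered" else "raw codes"))
  n_na <- sum(is.na(x$codes))
  if (n_na > 0) cat(sprintf("  %d missing calls (%.2f%%)\n",
                            n_na, 100 * n_na / length(x$codes)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Read a genotype matrix from file
#'
#' Supported formats: plain CSV (first column the individual id, header row of
#' marker ids, cells 0/1/2 or empty/NA), PLINK `.raw` (space-delimited, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP, allele
#' counts with `NA` for missing) and VCF (biallelic SNPs, `GT` field; the
#' dosage is the ALT-allele count). Multi-allelic VCF records are skipped with
#' a warning by default.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"plink_raw"`, `"vcf"`. Guessed from the
#'   file extension when omitted.
#' @param multiallelic policy for non-biallelic VCF records: `"skip"`
#'   (drop the record, warn) or `"error"`.
#' @return A [genotype_matrix()], uncentered, ids in file order.
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw", "vcf"),
                           multiallelic = c("skip", "error")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     raw = "plink_raw", vcf = "vcf", "csv")
  }
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  switch(format,
         csv = read_genotypes_csv(path),
         plink_raw = read_genotypes_raw(path),
         vcf = read_genotypes_vcf(path, multiallelic))
}

read_genotypes_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("failed to parse CSV ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("CSV ", path, " needs an id column plus >= 1 marker")
  ids <- as.character(df[[1L]])
  codes <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(codes))
    stop("non-numeric genotype cell in ", path,
         " (first offending column: ",
         colnames(codes)[which(!apply(codes, 2, is.numeric))[1L]], ")")
  genotype_matrix(codes, ids, colnames(df)[-1L])
}

read_genotypes_raw <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", "-9")),
    error = function(e) stop("failed to parse PLINK .raw ", path, ": ",
                             conditionMessage(e)))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% colnames(df)))
    stop("PLINK .raw ", path, " is missing header columns: ",
         paste(setdiff(fixed, colnames(df)), collapse = ", "))
  snp_cols <- setdiff(colnames(df), fixed)
  if (length(snp_cols) == 0L) stop("PLINK .raw ", path, " has no SNP columns")
  codes <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(codes) <- "double"
  # strip the _A allele suffix PLINK appends to SNP names
  markers <- sub("_[ACGT0-9]+$", "", snp_cols)
  genotype_matrix(codes, as.character(df$IID), markers)
}

read_genotypes_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " non-biallelic record(s) in ", path,
           " (first at ", vcfR::getCHROM(v)[which(multi)[1L]], ":",
           vcfR::getPOS(v)[which(multi)[1L]], ")")
    warning("skipping ", sum(multi), " non-biallelic VCF record(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no usable GT records in ", path)
  dose <- vapply(seq_len(ncol(gt)), function(j) {
    sapply(strsplit(gt[, j], "[/|]"), function(a) {
      if (length(a) == 0L || any(a == ".") || any(is.na(a))) NA_real_
      else sum(a != "0")
    })
  }, numeric(nrow(gt)))
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(gt))
  markers <- vcfR::getID(v)
  if (all(is.na(markers)))
    markers <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  genotype_matrix(t(dose), colnames(gt), markers)
}

#' Mode-impute missing genotype calls
#'
#' Replaces every missing call by the most frequent non-missing code of its
#' column. Ties are broken towards the smallest code, deterministically.
#'
#' @param g a [genotype_matrix()].
#' @return The genotype matrix with no missing values.
#' @export
mode_impute <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$centered) stop("impute before centering")
  codes <- g$codes
  na_cols <- which(colSums(is.na(codes)) > 0L)
  for (j in na_cols) {
    col <- codes[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0L)
      stop("marker ", g$marker_ids[j], " is entirely missing; cannot impute")
    tab <- table(obs)
    # names(tab) sorts numerically ascending, so which.max takes the
    # smallest code on ties
    mode_code <- as.numeric(names(tab)[which.max(tab)])
    codes[is.na(col), j] <- mode_code
  }
  g$codes <- codes
  g
}

#' Mean-center genotype columns
#'
#' Subtracts the column mean (= 2 x allele frequency) from every marker.
#' Columns are only centered, never variance-scaled: markers with more
#' variation keep more variation, which is what lets principal components
#' capture additive genetic variance rather than just structure.
#'
#' @param g a complete (no missing calls) [genotype_matrix()].
#' @return The centered genotype matrix; `column_means` holds the
#'   pre-centering means so the original codes can be restored exactly.
#' @export
center_columns <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$centered) return(g)
  if (anyNA(g$codes))
    stop("missing genotype calls present; run mode_impute() first")
  mu <- colMeans(g$codes)
  g$codes <- sweep(g$codes, 2L, mu, "-")
  g$column_means <- mu
  g$centered <- TRUE
  n_mono <- sum(apply(g$codes, 2L, function(x) all(x == 0)))
  if (n_mono > 0)
    message(n_mono, " monomorphic marker(s) retained (zero after centering)")
  g
}

#' Drop monomorphic markers
#'
#' Removes markers with zero variance. They contribute nothing to the
#' principal components but dropping them shrinks the matrix.
#'
#' @param g a [genotype_matrix()] (centered or raw).
#' @return The genotype matrix without monomorphic columns.
#' @export
drop_monomorphic <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- apply(g$codes, 2L, stats::var)
  keep <- !is.na(v) & v > 0
  if (all(keep)) return(g)
  message("dropping ", sum(!keep), " monomorphic marker(s)")
  g$codes <- g$codes[, keep, drop = FALSE]
  g$marker_ids <- g$marker_ids[keep]
  if (!is.null(g$column_means)) g$column_means <- g$column_means[keep]
  g
}

#' Read a phenotype/covariate table
#'
#' Plain CSV with one row per measurement. Repeated records per individual
#' are allowed (and expected for traits measured more than once).
#'
#' @param path CSV path.
#' @param id_col name of the individual-id column (default `"id"`).
#' @return A data.frame with the id column coerced to character.
#' @export
read_phenotypes <- function(path, id_col = "id") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!id_col %in% colnames(df))
    stop("phenotype table ", path, " has no column '", id_col, "'")
  df[[id_col]] <- as.character(df[[id_col]])
  df
}

#' Write a genotype matrix as CSV
#'
#' Inverse of `read_genotypes(format = "csv")`. Centered matrices are
#' written back on the raw 0/1/2 scale by re-adding the stored column means.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_csv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  if (g$centered) codes <- sweep(codes, 2L, g$column_means, "+")
  df <- data.frame(id = g$individual_ids, codes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
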