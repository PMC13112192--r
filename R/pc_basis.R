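#' Principal component basis of a centered SNP matrix
#'
#' Computes the singular value decomposition Z = U D V' of the centered
#' genotype matrix and derives the quantities the ridge model needs: the
#' right singular vectors V, the eigenvalues lambda_j (sample variances,
#' denominator N-1, of the unscaled PC score columns Z v_j, in descending
#' order), and the scaled score matrix Z* whose columns are Z v_j divided by
#' the standard deviation of the first PC. The scaling leaves
#' var(PC_1) = 1 and var(PC_j) = lambda_j / lambda_1 <= 1, so components
#' that explain less SNP variance are shrunk harder by a common ridge prior.
#'
#' Components with numerically zero singular value (below
#' `max(N, m) * eps * s_1`) are dropped, so the rank `k_max` can be smaller
#' than `min(N - 1, m)`.
#'
#' The basis is computed from genotypes only; phenotypes never enter, so one
#' basis can safely be shared across cross-validation folds.
#'
#' @param g a centered [genotype_matrix()].
#' @param scale if `TRUE` (default) also populate the scaled scores via
#'   [scale_scores()].
#' @return An object of class `pc_basis` with fields `right_vectors` (m x r),
#'   `eigenvalues` (length r, descending), `scores` (N x r unscaled),
#'   `scaled_scores` (N x r, `NULL` until scaled), `scale_constant`
#'   (sd of the first PC), `k_max`, `column_means`, `marker_ids`,
#'   `individual_ids`.
#' @export
compute_basis <- function(g, scale = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$centered) stop("compute_basis() needs a centered genotype matrix")
  Z <- g$codes
  n <- nrow(Z)
  if (n < 2L) stop("need at least 2 individuals")
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1L]
  keep <- sv$d > tol
  if (!any(keep)) stop("genotype matrix has no variation")
  d <- sv$d[keep]
  basis <- structure(
    list(right_vectors = sv$v[, keep, drop = FALSE],
         eigenvalues = d^2 / (n - 1),
         scores = sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d)),
         scaled_scores = NULL,
         scale_constant = NA_real_,
         k_max = sum(keep),
         column_means = g$column_means,
         marker_ids = g$marker_ids,
         individual_ids = g$individual_ids),
    class = "pc_basis")
  if (scale) basis <- scale_scores(basis) else basis
}

#' Scale PC scores in proportion to variance explained
#'
#' Divides every unscaled score column by the standard deviation of the
#' first PC, so the scaled columns have variances
#' lambda_j / lambda_1, descending from 1. Under a common Gaussian prior on
#' the PC effects this imposes stronger shrinkage on components that explain
#' less SNP variance.
#'
#' @param basis a `pc_basis` from [compute_basis()].
#' @return The basis with `scaled_scores` and `scale_constant` filled in.
#' @export
scale_scores <- function(basis) {
  stopifnot(inherits(basis, "pc_basis"))
  l1 <- basis$eigenvalues[1L]
  if (!is.finite(l1) || l1 <= 0)
    stop("first eigenvalue is zero: no genetic variation to scale by")
  basis$scale_constant <- sqrt(l1)
  basis$scaled_scores <- basis$scores / basis$scale_constant
  dimnames(basis$scaled_scores) <- list(basis$individual_ids,
                                        paste0("PC", seq_len(basis$k_max)))
  basis
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("pc_basis: %d individuals, %d markers, rank %d\n",
              length(x$individual_ids), length(x$marker_ids), x$k_max))
  cat(sprintf("  eigenvalues: %.4g ... %.4g (sum %.4g)\n",
              x$eigenvalues[1L], x$eigenvalues[x$k_max],
              sum(x$eigenvalues)))
  invisible(x)
}

#' Per-PC variances of the scaled scores
#'
#' @param basis a scaled `pc_basis`.
#' @param k number of leading components (default all).
#' @return Numeric vector lambda_j / lambda_1 for j = 1..k.
#' @export
pc_variances <- function(basis, k = basis$k_max) {
  stopifnot(inherits(basis, "pc_basis"))
  if (k < 1L || k > basis$k_max) stop("k must be in 1..k_max")
  basis$eigenvalues[seq_len(k)] / basis$eigenvalues[1L]
}

#' Project individuals onto a PC basis
#'
#' Computes scaled PC scores for (possibly new) individuals:
#' `(Z_new %*% V[, 1:k]) / scale_constant`, where `Z_new` is centered with
#' the TRAINING column means stored in the basis. Raw (uncentered) input is
#' centered with those means automatically; already-centered input is used
#' as is.
#'
#' @param basis a scaled `pc_basis`.
#' @param g_new a [genotype_matrix()] with the same markers, same order.
#' @param k number of leading components.
#' @return An `n_new x k` score matrix on the scale of `scaled_scores`.
#' @export
project <- function(basis, g_new, k = basis$k_max) {
  stopifnot(inherits(basis, "pc_basis"), inherits(g_new, "genotype_matrix"))
  if (k < 1L || k > basis$k_max) stop("k must be in 1..k_max")
  if (!identical(g_new$marker_ids, basis$marker_ids))
    stop("marker ids of g_new do not match the basis")
  Z <- g_new$codes
  if (!g_new$centered) Z <- sweep(Z, 2L, basis$column_means, "-")
  out <- (Z %*% basis$right_vectors[, seq_len(k), drop = FALSE]) /
    basis$scale_constant
  dimnames(out) <- list(g_new$individual_ids, paste0("PC", seq_len(k)))
  out
}

#' Persist / restore a PC basis as a CSV pair
#'
#' Writes `<stem>_eigen.csv` (component, eigenvalue, scale constant, column
#' means) and `<stem>_vectors.csv` (right singular vectors with marker ids)
#' so an expensive SVD can be reused across fits.
#'
#' @param basis a scaled `pc_basis`.
#' @param stem file stem; two CSV files are written.
#' @export
save_basis <- function(basis, stem) {
  stopifnot(inherits(basis, "pc_basis"))
  utils::write.csv(
    data.frame(component = seq_len(basis$k_max),
               eigenvalue = basis$eigenvalues,
               scale_constant = basis$scale_constant),
    paste0(stem, "_eigen.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(marker = basis$marker_ids,
               column_mean = basis$column_means,
               basis$right_vectors, check.names = FALSE),
    paste0(stem, "_vectors.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(id = basis$individual_ids, basis$scaled_scores,
               check.names = FALSE),
    paste0(stem, "_scores.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname save_basis
#' @export
load_basis <- function(stem) {
  eig <- utils::read.csv(paste0(stem, "_eigen.csv"))
  vec <- utils::read.csv(paste0(stem, "_vectors.csv"), check.names = FALSE)
  sco <- utils::read.csv(paste0(stem, "_scores.csv"), check.names = FALSE)
  scaled <- as.matrix(sco[, -1L, drop = FALSE])
  structure(
    list(right_vectors = as.matrix(vec[, -(1:2), drop = FALSE]),
         eigenvalues = eig$eigenvalue,
         scores = scaled * eig$scale_constant[1L],
         scaled_scores = scaled,
         scale_constant = eig$scale_constant[1L],
         k_max = nrow(eig),
         column_means = stats::setNames(vec$column_mean, vec$marker),
         marker_ids = as.character(vec$marker),
         individual_ids = as.character(sco[[1L]])),
    class = "pc_basis")
}
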