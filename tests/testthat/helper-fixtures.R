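# shared fixtures, built in code at test time

# small deterministic genotype matrix with known codes
toy_genotypes <- function() {
  codes <- matrix(c(0, 1,
                    2, 2,
                    1, 0), nrow = 3, byrow = TRUE)
  genotype_matrix(codes, c("a", "b", "c"), c("s1", "s2"))
}

# write a minimal VCF; one record per row of `gt` (strings like "0/1")
write_toy_vcf <- function(path, gt, alt = rep("T", nrow(gt)),
                          samples = paste0("ind", seq_len(ncol(gt)))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c("1", i * 100, paste0("snp", i), "A", alt[i], ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

write_toy_raw <- function(path, codes, ids = paste0("ind", seq_len(nrow(codes))),
                          snps = paste0("snp", seq_len(ncol(codes)))) {
  hdr <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                 paste0(snps, "_A")), collapse = " ")
  rows <- vapply(seq_len(nrow(codes)), function(i) {
    paste(c("F1", ids[i], "0", "0", "1", "-9", codes[i, ]), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# quick simulated dataset at test scale
small_sim <- function(n = 120, m = 300, seed = 101, ...) {
  simulate_dataset(n, m, seed = seed, ...)
}
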