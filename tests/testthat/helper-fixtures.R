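# In-code fixtures shared across test files.

write_fixture <- function(df, dir = tempdir(), name = "fixture.tsv") {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# tiny 2-triad dataset with hand-chosen TPMs
tiny_triads <- function() {
  validate_triad_set(data.frame(
    triad_id = c("t1", "t2"),
    gene_a = c("a1", "a2"), gene_b = c("b1", "b2"), gene_d = c("d1", "d2"),
    stringsAsFactors = FALSE))
}

tiny_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("c1", "c2", "s1", "s2"),
    tissue = "root",
    condition = c("control", "control", "stress", "stress"),
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE))
}

# genes x samples TPM matrix for tiny_triads()/tiny_sheet()
tiny_tpm <- function(values) {
  m <- matrix(values, nrow = 6L, ncol = 4L,
              dimnames = list(c("a1", "b1", "d1", "a2", "b2", "d2"),
                              c("c1", "c2", "s1", "s2")))
  attr(m, "unit") <- "TPM"
  m
}

# independent nearest-centroid oracle: plain loop over the seven centroids
oracle_classify <- function(comp) {
  cen <- hebc_centroids()
  frac <- comp / sum(comp)
  d <- apply(cen, 1L, function(c) sqrt(sum((frac - c)^2)))
  list(category = names(d)[which.min(d)], distance = min(d))
}

# independent shift-rule oracle
oracle_shift <- function(rc, rs, threshold = 1.2) {
  if (rc == 0 && rs == 0) return(list(significant = FALSE, undefined = TRUE))
  if (rc == 0 || rs == 0) return(list(significant = TRUE, undefined = TRUE))
  r <- rc / rs
  list(significant = max(r, 1 / r) >= threshold, undefined = FALSE)
}

# random simplex points, uniform (normalized exponentials)
random_simplex <- function(n) {
  g <- matrix(stats::rexp(3L * n), ncol = 3L)
  g / rowSums(g)
}
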