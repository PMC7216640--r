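test_that("the DEG filter applies inclusive boundaries and directions", {
  de <- data.frame(gene_id = paste0("g", 1:5),
                   log2fc = c(1, 3, -1, 0.999, 2),
                   padj = c(0.05, 0.051, 0.01, 0.01, 0.050001))
  f <- filter_degs(de)
  expect_setequal(f$degs, c("g1", "g3"))   # boundaries in; g2/g5 padj out; g4 fc out
  expect_equal(f$up, "g1")
  expect_equal(f$down, "g3")
  expect_error(filter_degs(de[, -3L]), "padj")
})

test_that("the DEG filter is monotone in both thresholds", {
  set.seed(31)
  de <- data.frame(gene_id = paste0("g", 1:300),
                   log2fc = rnorm(300, 0, 2),
                   padj = runif(300))
  strict <- filter_degs(de, alpha = 0.05, min_abs_log2fc = 1)$degs
  for (relaxed in list(filter_degs(de, alpha = 0.2, min_abs_log2fc = 1)$degs,
                       filter_degs(de, alpha = 0.05, min_abs_log2fc = 0.5)$degs,
                       filter_degs(de, alpha = 0.2, min_abs_log2fc = 0.25)$degs)) {
    expect_true(all(strict %in% relaxed))
  }
})

test_that("per-homeolog fold changes flag the strongest responder", {
  triads <- tiny_triads()
  de <- data.frame(gene_id = c("a1", "b1", "d1", "a2", "b2"),
                   log2fc = c(1, 1, log2(300), 1, 1),
                   fold_change = c(2, 2, 300, 2, 2),
                   padj = c(0.01, 0.2, 0.001, 0.01, 0.01))
  fc <- homeolog_fold_changes(de, triads)
  t1 <- fc[fc$triad_id == "t1", ]
  expect_equal(t1$max_homeolog, "D")
  expect_true(t1$complete)
  expect_true(t1$deg_d)
  expect_false(t1$deg_b)   # fails the padj cut
  t2 <- fc[fc$triad_id == "t2", ]   # d2 absent from the DE table
  expect_false(t2$complete)
  expect_true(is.na(t2$max_homeolog))
  # ties yield no dominant homeolog
  de2 <- de
  de2$fold_change[3L] <- 2
  expect_true(is.na(homeolog_fold_changes(de2, triads)$max_homeolog[1L]))
  # gene-set restriction
  fc_set <- homeolog_fold_changes(de, triads, genes = "d1")
  expect_equal(fc_set$triad_id, "t1")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  exact_tail <- function(k, S, N, n) {
    # P(overlap >= k) by direct summation of the hypergeometric pmf
    j <- k:min(S, n)
    sum(choose(S, j) * choose(N - S, n - j)) / choose(N, n)
  }
  # worked case from first principles: universe 20, set 5, degs 10, overlap 5
  uni <- paste0("g", 1:20)
  degs <- uni[1:10]
  sets <- list(s5 = uni[6:10], disjoint = uni[16:20], all = uni)
  res <- hypergeometric_enrichment(degs, uni, sets)
  expect_equal(res$p[res$set == "s5"], exact_tail(5, 5, 20, 10))
  expect_equal(res$p[res$set == "disjoint"], 1)  # observed 0 >= 0 always
  expect_equal(res$p[res$set == "all"], 1)
  expect_error(hypergeometric_enrichment(degs, character(0), sets), "empty")
  expect_error(hypergeometric_enrichment(c(degs, "zz"), uni, sets), "zz")

  # grid of small configurations against the enumeration oracle
  set.seed(32)
  for (N in c(8L, 15L, 30L)) {
    uni <- paste0("g", seq_len(N))
    for (trial in 1:10) {
      S <- sample.int(N, 1L)
      n <- sample.int(N, 1L)
      set <- sample(uni, S)
      degs <- sample(uni, n)
      k <- length(intersect(set, degs))
      got <- hypergeometric_enrichment(degs, uni, list(x = set))
      expect_equal(got$p, exact_tail(k, S, N, n), tolerance = 1e-12)
      expect_equal(got$overlap, k)
    }
  }
})

test_that("BH adjustment reproduces the textbook step-up procedure", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # textbook: sort ascending, q_i = p_i * n / i, enforce monotonicity from the top
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  expected <- numeric(n)
  expected[o] <- q
  uni <- paste0("g", 1:40)
  sets <- lapply(1:10, function(i) sample(uni, 8L))
  names(sets) <- paste0("s", 1:10)
  res <- hypergeometric_enrichment(uni[1:10], uni, sets)
  res$padj_oracle <- {
    oo <- order(res$p)
    qq <- res$p[oo] * 10 / seq_len(10L)
    out <- numeric(10L)
    out[oo] <- pmin(rev(cummin(rev(qq))), 1)
    out
  }
  expect_equal(res$padj, res$padj_oracle, tolerance = 1e-12)
  # and on the fixed worked vector via the same route the package uses
  expect_equal(stats::p.adjust(p, "BH"), expected, tolerance = 1e-12)
})

test_that("naive DE recovers gross signals and behaves under the null", {
  sheet <- tiny_sheet()
  counts <- matrix(
    c(5, 5, 5, 5,        # null gene
      0, 0, 100, 110),   # strong induction
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("gnull", "gup"), sheet$sample_id))
  attr(counts, "unit") <- "counts"
  de <- naive_de(counts, sheet)
  expect_equal(de$fold_change[de$gene_id == "gnull"], 1)
  expect_gt(de$fold_change[de$gene_id == "gup"], 100)
  expect_lt(de$pvalue[de$gene_id == "gup"], 0.05)
  expect_match(attr(de, "method"), "naive")
  expect_error(naive_de(counts, sheet[-1L, ]), "2 replicates")

  # null NB simulation: type-I error within nominal + 2 Monte-Carlo SE
  set.seed(33)
  n_genes <- 2000L
  mu <- rep(100, n_genes)
  null_counts <- matrix(rnbinom(n_genes * 6L, mu = mu, size = 20),
                        nrow = n_genes,
                        dimnames = list(paste0("g", seq_len(n_genes)),
                                        paste0("x", 1:6)))
  attr(null_counts, "unit") <- "counts"
  null_sheet <- validate_sample_sheet(data.frame(
    sample_id = paste0("x", 1:6), tissue = "root",
    condition = rep(c("control", "stress"), each = 3L),
    replicate = rep(1:3, 2L)))
  de0 <- naive_de(null_counts, null_sheet)
  alpha <- 0.05
  rate <- mean(de0$pvalue <= alpha)
  mc_se <- sqrt(alpha * (1 - alpha) / n_genes)
  expect_lte(rate, alpha + 2 * mc_se)
  expect_lt(abs(mean(de0$pvalue <= 0.5) - 0.5), 0.1)  # ~uniform
  expect_lt(abs(mean(de0$pvalue <= 0.2) - 0.2), 0.1)
})
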