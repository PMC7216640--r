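test_that("condition means are arithmetic replicate means", {
  m <- tiny_tpm(0)
  m["a1", ] <- c(2, 6, 4, 4)   # control reps 2, 6 -> 4
  means <- mean_by_condition(m, tiny_sheet(), "root")
  expect_equal(unname(means["a1", "control"]), 4)
  expect_equal(unname(means["a1", "stress"]), 4)
  expect_equal(attr(means, "n_replicates"), c(control = 2L, stress = 2L))
  expect_error(mean_by_condition(m, tiny_sheet(), "leaf"), "leaf")

  cm <- m
  attr(cm, "unit") <- "counts"
  expect_error(mean_by_condition(cm, tiny_sheet(), "root"), "TPM")
})

test_that("expressed-triad detection applies the summed-TPM rule", {
  m <- tiny_tpm(0)
  m[c("a1", "b1", "d1"), c("s1", "s2")] <- 10  # t1: (0, 30) across conditions
  means <- mean_by_condition(m, tiny_sheet(), "root")
  suppressMessages({
    kept <- detect_expressed_triads(means, tiny_triads(), 0.5)
    expect_equal(kept$triad_id, "t1")   # t2 is all-zero
    all0 <- detect_expressed_triads(means, tiny_triads()[2L, ], 0.5)
    expect_equal(nrow(all0), 0L)
  })
  m2 <- tiny_tpm(1)
  means2 <- mean_by_condition(m2, tiny_sheet(), "root")
  suppressMessages(kept2 <- detect_expressed_triads(means2, tiny_triads(), 0))
  expect_equal(nrow(kept2), 2L)  # threshold 0, all-positive: identity
})

test_that("REV percentages follow the share formula and close to 100", {
  m <- tiny_tpm(0)
  m[c("a1", "b1", "d1"), c("c1", "c2")] <- c(10, 10, 10)
  m[c("a1", "b1", "d1"), c("s1", "s2")] <- c(0, 0, 50)
  m[c("a2", "b2", "d2"), ] <- c(20, 30, 50)
  means <- mean_by_condition(m, tiny_sheet(), "root")
  rev <- compute_rev(means, tiny_triads())
  r1c <- rev[rev$triad_id == "t1" & rev$condition == "control", ]
  expect_equal(c(r1c$a_pct, r1c$b_pct, r1c$d_pct), rep(100 / 3, 3L))
  r1s <- rev[rev$triad_id == "t1" & rev$condition == "stress", ]
  expect_equal(c(r1s$a_pct, r1s$b_pct, r1s$d_pct), c(0, 0, 100))
  r2 <- rev[rev$triad_id == "t2" & rev$condition == "control", ]
  expect_equal(c(r2$a_pct, r2$b_pct, r2$d_pct), c(20, 30, 50))
  expect_true(all(abs(rev$a_pct + rev$b_pct + rev$d_pct - 100) < 1e-9))
})

test_that("zero-total conditions are omitted with a log, not an error", {
  m <- tiny_tpm(0)
  m[c("a1", "b1", "d1"), c("c1", "c2")] <- 5   # t1 expressed in control only
  m[c("a2", "b2", "d2"), ] <- 1
  means <- mean_by_condition(m, tiny_sheet(), "root")
  expect_message(rev <- compute_rev(means, tiny_triads()), "zero total TPM")
  expect_equal(nrow(rev[rev$triad_id == "t1", ]), 1L)
  expect_equal(rev$condition[rev$triad_id == "t1"], "control")
})

test_that("a triad gene missing from the matrix is reported, not zeroed", {
  m <- tiny_tpm(1)[-3L, ]  # drop d1
  attr(m, "unit") <- "TPM"
  means <- mean_by_condition(m, tiny_sheet(), "root")
  expect_error(compute_rev(means, tiny_triads()), "d1")
})

test_that("shift calls implement the symmetric >=20% ratio rule", {
  rev <- data.frame(
    triad_id = rep(c("t1", "t2", "t3"), 2L),
    condition = rep(c("control", "stress"), each = 3L),
    a_pct = 10, b_pct = 0,
    d_pct = c(40, 40, 25, 50, 45, 25),
    total_tpm = 1)
  calls <- call_rev_shifts(rev, "D")
  expect_equal(calls$significant, c(TRUE, FALSE, FALSE))   # 1.25, 1.125, 1
  expect_equal(calls$ratio, c(40 / 50, 40 / 45, 1))
  expect_error(call_rev_shifts(rev, "E"))

  # boundary: ratio exactly 1.2 in either direction is significant
  rev$d_pct <- c(60, 50, 30, 50, 60, 30)
  calls2 <- call_rev_shifts(rev, "D")
  expect_true(all(calls2$significant[1:2]))
})

test_that("zero REVs are tracked as undefined and counted per the rule", {
  rev <- data.frame(
    triad_id = rep(c("t1", "t2"), 2L),
    condition = rep(c("control", "stress"), each = 2L),
    a_pct = c(100, 100, 50, 100), b_pct = 0,
    d_pct = c(0, 0, 50, 0),
    total_tpm = 1)
  calls <- call_rev_shifts(rev, "D")
  expect_equal(calls$undefined, c(TRUE, TRUE))
  expect_equal(calls$significant, c(TRUE, FALSE))  # one-zero vs both-zero
  expect_true(all(is.na(calls$ratio)))
})

test_that("shift summary partitions counts and reports fractions", {
  calls <- data.frame(
    triad_id = paste0("t", 1:10), homeolog = "D",
    rev_control = 50, rev_stress = 50,
    ratio = c(rep(1.5, 3L), rep(1, 5L), NA, NA),
    significant = c(rep(TRUE, 3L), rep(FALSE, 5L), TRUE, FALSE),
    undefined = c(rep(FALSE, 8L), TRUE, TRUE))
  s <- shift_summary(calls)
  expect_equal(s$n, 10L)
  expect_equal(s$n_significant + s$n_not_significant + s$n_undefined, s$n)
  expect_equal(s$n_undefined, 2L)
  expect_equal(s$frac_significant, 0.4)  # 3 defined + 1 undefined significant
  expect_error(shift_summary(calls[0L, ]))
})

test_that("scale invariance: rescaling a condition leaves REVs and calls fixed", {
  set.seed(11)
  sim <- simulate_dataset(sim_config(n_triads = 60, seed = 11))
  fit1 <- suppressMessages(triad_bias(sim$tpm, sim$triads, sim$sheet, "root"))
  tpm2 <- sim$tpm
  stress <- sim$sheet$sample_id[sim$sheet$condition == "stress"]
  tpm2[, stress] <- tpm2[, stress] * 7.3
  attr(tpm2, "unit") <- "TPM"
  fit2 <- suppressMessages(triad_bias(tpm2, sim$triads, sim$sheet, "root"))
  expect_equal(fit1$rev[c("a_pct", "b_pct", "d_pct")],
               fit2$rev[c("a_pct", "b_pct", "d_pct")])
  expect_equal(fit1$shifts$significant, fit2$shifts$significant)
  expect_equal(as.character(fit1$rev$category), as.character(fit2$rev$category))
})

test_that("condition-swap symmetry inverts ratios but not significance", {
  set.seed(12)
  n <- 200L
  rev <- data.frame(
    triad_id = rep(paste0("t", 1:n), 2L),
    condition = rep(c("control", "stress"), each = n),
    a_pct = 0, b_pct = 0,
    d_pct = runif(2L * n, 1, 99),
    total_tpm = 1)
  rev$a_pct <- 100 - rev$d_pct
  fwd <- call_rev_shifts(rev, "D")
  swapped <- rev
  swapped$condition <- ifelse(rev$condition == "control", "stress", "control")
  bwd <- call_rev_shifts(swapped, "D")
  expect_equal(bwd$ratio, 1 / fwd$ratio)
  expect_equal(bwd$significant, fwd$significant)
})

test_that("shift calls agree with a brute-force oracle on random pairs", {
  set.seed(13)
  n <- 1000L
  rc <- round(runif(n, 0, 100), 1)
  rs <- round(runif(n, 0, 100), 1)
  rc[1:2] <- c(60, 50); rs[1:2] <- c(50, 60)  # exact 1.2 boundaries
  rc[3] <- 0; rs[4] <- 0; rc[5] <- 0; rs[5] <- 0
  rev <- data.frame(
    triad_id = rep(paste0("t", 1:n), 2L),
    condition = rep(c("control", "stress"), each = n),
    a_pct = c(100 - rc, 100 - rs), b_pct = 0,
    d_pct = c(rc, rs), total_tpm = 1)
  calls <- call_rev_shifts(rev, "D")
  oracle <- t(vapply(seq_len(n), function(i) {
    o <- oracle_shift(rc[i], rs[i])
    c(o$significant, o$undefined)
  }, logical(2L)))
  expect_equal(calls$significant, oracle[, 1L])
  expect_equal(calls$undefined, oracle[, 2L])
})
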