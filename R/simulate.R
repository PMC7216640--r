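#' Configuration for the synthetic triad-expression generator
#'
#' Builds and validates the parameter set for
#' \code{\link{simulate_dataset}}. Defaults mirror a typical allopolyploid
#' stress RNA-seq design: three biological replicates per condition, a
#' category mix dominated by balanced triads with the suppressed categories
#' more frequent than the dominant ones, lognormal triad abundances and
#' negative-binomial count noise.
#'
#' @param n_triads Number of triads to simulate.
#' @param category_mix Probabilities of the seven bias categories, in
#'   \code{\link{hebc_categories}} order; must sum to 1.
#' @param dirichlet_concentration Dirichlet concentration around the
#'   category centroid (> 0); higher means compositions hug the centroid.
#' @param abundance_log_mean,abundance_log_sd Lognormal (natural-log scale)
#'   parameters for each triad's total expression weight.
#' @param nb_dispersion Negative-binomial dispersion of counts (> 0;
#'   variance = mu + dispersion * mu^2).
#' @param n_replicates Biological replicates per condition (>= 1).
#' @param library_size Expected sequencing depth per sample (reads).
#' @param shared_effect_sd SD of the triad-level log2 condition effect
#'   applied to all three homeologs (leaves the composition unchanged).
#' @param homeolog_effect_prob Probability that a triad additionally gets a
#'   homeolog-specific effect — the mechanism that creates true bias-category
#'   changes.
#' @param homeolog_effect_log2 Magnitude of that effect (log2; applied with
#'   random sign to one uniformly chosen homeolog).
#' @param tissue Tissue label written into the sample sheet.
#' @param seed Integer seed; required, so no run depends on ambient RNG
#'   state.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_triads = 1000,
                       category_mix = c(0.70, 0.02, 0.02, 0.02,
                                        0.08, 0.08, 0.08),
                       dirichlet_concentration = 50,
                       abundance_log_mean = log(30),
                       abundance_log_sd = 1.2,
                       nb_dispersion = 0.05,
                       n_replicates = 3,
                       library_size = 2e7,
                       shared_effect_sd = 1,
                       homeolog_effect_prob = 0.15,
                       homeolog_effect_log2 = 2,
                       tissue = "root",
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  cfg <- list(n_triads = as.integer(n_triads),
              category_mix = as.numeric(category_mix),
              dirichlet_concentration = dirichlet_concentration,
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              library_size = library_size,
              shared_effect_sd = shared_effect_sd,
              homeolog_effect_prob = homeolog_effect_prob,
              homeolog_effect_log2 = homeolog_effect_log2,
              tissue = as.character(tissue),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_triads >= 1L,
              length(category_mix) == 7L,
              all(category_mix >= 0),
              abs(sum(category_mix) - 1) < 1e-8,
              dirichlet_concentration > 0,
              abundance_log_sd > 0,
              nb_dispersion > 0,
              n_replicates >= 1L,
              library_size > 0,
              shared_effect_sd >= 0,
              homeolog_effect_prob >= 0, homeolog_effect_prob <= 1,
              homeolog_effect_log2 >= 0,
              is.finite(seed))
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a triad expression dataset with known ground truth
#'
#' Generative model, per triad: a bias category drawn from
#' \code{category_mix}; a control composition drawn from a Dirichlet
#' centred on that category's centroid (parameters centroid *
#' concentration, floored at 0.01 * concentration so vertex categories keep
#' full support); a total expression weight drawn lognormal; a shared log2
#' condition effect applied to all homeologs; and, with probability
#' \code{homeolog_effect_prob}, an extra log2 effect of magnitude
#' \code{homeolog_effect_log2} (random sign) on one uniformly chosen
#' homeolog — only this last perturbation can change the true composition,
#' hence the true bias category, under stress. Expected TPM per condition is
#' the weight vector rescaled to 1e6; replicate counts are negative
#' binomial around expected TPM scaled to a lognormally jittered library
#' size; the emitted TPM matrix rescales each count column back to 1e6
#' (equal effective gene lengths). Fully reproducible from the seed.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{sim_dataset}: \code{triads} (triad set),
#'   \code{tpm} and \code{counts} (gene x sample matrices with unit
#'   attributes), \code{sheet} (sample sheet), \code{truth} (one row per
#'   triad: drawn and true categories under both conditions, true
#'   compositions, effects, abundance, whether a true bias-category change
#'   was induced), and \code{config}.
#' @export
simulate_dataset <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  set.seed(cfg$seed)
  n <- cfg$n_triads
  cen <- hebc_centroids()
  cats <- hebc_categories()

  cat_idx <- sample.int(7L, n, replace = TRUE, prob = cfg$category_mix)
  alpha <- pmax(cen[cat_idx, , drop = FALSE] * cfg$dirichlet_concentration,
                0.01 * cfg$dirichlet_concentration)
  g <- matrix(stats::rgamma(3L * n, shape = alpha), nrow = n)
  comp_c <- g / rowSums(g)

  abundance <- stats::rlnorm(n, cfg$abundance_log_mean, cfg$abundance_log_sd)
  shared <- stats::rnorm(n, 0, cfg$shared_effect_sd)
  has_eff <- stats::runif(n) < cfg$homeolog_effect_prob
  eff_h <- sample.int(3L, n, replace = TRUE)        # drawn for all, used if has_eff
  eff_sign <- sample(c(-1, 1), n, replace = TRUE)
  eff <- matrix(0, n, 3L)
  eff[cbind(which(has_eff), eff_h[has_eff])] <-
    (eff_sign * cfg$homeolog_effect_log2)[has_eff]

  ws <- comp_c * 2^eff
  comp_s <- ws / rowSums(ws)                        # true stress composition

  category_true_c <- classify_hebc(comp_c)$category
  category_true_s <- classify_hebc(comp_s)$category

  triad_id <- sprintf("Triad%05d", seq_len(n))
  gene <- function(sub) sprintf("SYNG%05d%s", seq_len(n), sub)
  triads <- validate_triad_set(data.frame(
    triad_id = triad_id, gene_a = gene("A"), gene_b = gene("B"),
    gene_d = gene("D"), syntenic = TRUE, stringsAsFactors = FALSE))
  gene_ids <- as.vector(t(cbind(triads$gene_a, triads$gene_b, triads$gene_d)))

  # expected TPM per condition: weights rescaled to 1e6 over all genes
  w_c <- as.vector(t(abundance * comp_c))
  w_s <- as.vector(t(abundance * comp_c * 2^(shared + eff)))
  mu_tpm <- cbind(control = w_c / sum(w_c) * 1e6,
                  stress = w_s / sum(w_s) * 1e6)

  conds <- rep(c("control", "stress"), each = cfg$n_replicates)
  reps <- rep(seq_len(cfg$n_replicates), times = 2L)
  sample_id <- paste(cfg$tissue, conds, reps, sep = "_")
  counts <- matrix(0, nrow = 3L * n, ncol = length(sample_id),
                   dimnames = list(gene_ids, sample_id))
  for (j in seq_along(sample_id)) {
    lib <- stats::rlnorm(1L, log(cfg$library_size), 0.1)
    mu <- mu_tpm[, conds[j]] / 1e6 * lib
    counts[, j] <- stats::rnbinom(3L * n, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  tpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  attr(counts, "unit") <- "counts"
  attr(tpm, "unit") <- "TPM"

  sheet <- validate_sample_sheet(data.frame(
    sample_id = sample_id, tissue = cfg$tissue, condition = conds,
    replicate = reps, stringsAsFactors = FALSE))

  truth <- data.frame(
    triad_id = triad_id,
    category_drawn = cats[cat_idx],
    category_true = as.character(category_true_c),
    category_true_stress = as.character(category_true_s),
    a_frac_control = comp_c[, 1L], b_frac_control = comp_c[, 2L],
    d_frac_control = comp_c[, 3L],
    a_frac_stress = comp_s[, 1L], b_frac_stress = comp_s[, 2L],
    d_frac_stress = comp_s[, 3L],
    abundance = abundance,
    shared_log2 = shared,
    effect_homeolog = ifelse(has_eff, c("A", "B", "D")[eff_h], "none"),
    effect_log2 = ifelse(has_eff, eff_sign * cfg$homeolog_effect_log2, 0),
    hebc_change_true = as.character(category_true_c) !=
      as.character(category_true_s),
    stringsAsFactors = FALSE)

  structure(list(triads = triads, tpm = tpm, counts = counts, sheet = sheet,
                 truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Compare pipeline output against simulation ground truth
#'
#' @param truth Truth table from \code{\link{simulate_dataset}}.
#' @param assignments Optional control-condition assignments
#'   (\code{\link{classify_hebc}}) to score category recovery against the
#'   category of the true underlying composition.
#' @param changes Optional \code{\link{hebc_change}} output to score
#'   bias-category-change sensitivity, specificity and false-positive rate.
#' @param shifts Optional \code{\link{call_rev_shifts}} output (one
#'   homeolog) to score shift-call sensitivity/specificity against the true
#'   compositions under the same threshold.
#' @param fold_threshold Threshold used for the true shift rule (must match
#'   the one used for \code{shifts}).
#' @return List of class \code{truth_report} with elements
#'   \code{category_recovery} (+ \code{confusion} matrix),
#'   \code{change_sensitivity}, \code{change_specificity},
#'   \code{change_fpr}, \code{shift_sensitivity}, \code{shift_specificity}
#'   (NA where the corresponding input or class is absent).
#' @export
truth_report <- function(truth, assignments = NULL, changes = NULL,
                         shifts = NULL, fold_threshold = 1.2) {
  out <- list(category_recovery = NA_real_, confusion = NULL,
              change_sensitivity = NA_real_, change_specificity = NA_real_,
              change_fpr = NA_real_,
              shift_sensitivity = NA_real_, shift_specificity = NA_real_)
  align <- function(ids, what) {
    i <- match(ids, truth$triad_id)
    if (anyNA(i)) stop(what, " contains triad IDs absent from truth")
    i
  }
  if (!is.null(assignments)) {
    i <- align(assignments$triad_id, "assignments")
    obs <- as.character(assignments$category)
    exp <- truth$category_true[i]
    out$category_recovery <- mean(obs == exp)
    out$confusion <- table(true = factor(exp, hebc_categories()),
                           assigned = factor(obs, hebc_categories()))
  }
  if (!is.null(changes)) {
    i <- align(changes$triad_id, "changes")
    tr <- truth$hebc_change_true[i]
    ob <- changes$changed
    out$change_sensitivity <- if (any(tr)) mean(ob[tr]) else NA_real_
    out$change_specificity <- if (any(!tr)) mean(!ob[!tr]) else NA_real_
    out$change_fpr <- if (any(!tr)) mean(ob[!tr]) else NA_real_
  }
  if (!is.null(shifts)) {
    i <- align(shifts$triad_id, "shifts")
    h <- match(shifts$homeolog[1L], c("A", "B", "D"))
    rc <- truth[[c("a_frac_control", "b_frac_control", "d_frac_control")[h]]][i]
    rs <- truth[[c("a_frac_stress", "b_frac_stress", "d_frac_stress")[h]]][i]
    r <- rc / rs
    tr <- ifelse(rc == 0 | rs == 0, xor(rc == 0, rs == 0),
                 pmax(r, 1 / r) >= fold_threshold)
    ob <- shifts$significant
    out$shift_sensitivity <- if (any(tr)) mean(ob[tr]) else NA_real_
    out$shift_specificity <- if (any(!tr)) mean(!ob[!tr]) else NA_real_
  }
  class(out) <- "truth_report"
  out
}

#' @export
print.truth_report <- function(x, ...) {
  cat("Synthetic-truth recovery report\n")
  fmt <- function(v) if (is.na(v)) "not scored" else sprintf("%.4f", v)
  cat("  category recovery:       ", fmt(x$category_recovery), "\n")
  cat("  HEBC-change sensitivity: ", fmt(x$change_sensitivity), "\n")
  cat("  HEBC-change specificity: ", fmt(x$change_specificity), "\n")
  cat("  HEBC-change FPR:         ", fmt(x$change_fpr), "\n")
  cat("  shift sensitivity:       ", fmt(x$shift_sensitivity), "\n")
  cat("  shift specificity:       ", fmt(x$shift_specificity), "\n")
  invisible(x)
}
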