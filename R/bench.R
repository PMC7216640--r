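#' Percent contribution of each solute to total molarity
#'
#' For one condition, each solute's share of the summed mean molar content:
#' percent = mean concentration * 100 / total mean concentration, computed
#' on condition means across replicates (umol per g DW cancels out).
#'
#' @param profile Solute profile (\code{\link{read_solute_table}} format:
#'   long data frame with \code{solute}, \code{condition}, \code{replicate},
#'   \code{concentration}).
#' @param condition \code{"control"} or \code{"stress"}.
#' @return Data frame: \code{solute}, \code{mean_concentration},
#'   \code{percent_contribution}; percentages sum to 100.
#' @export
percent_contribution <- function(profile, condition = c("control", "stress")) {
  condition <- match.arg(condition)
  sub <- profile[profile$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("condition '", condition, "' absent from profile")
  m <- tapply(sub$concentration, sub$solute, mean)
  total <- sum(m)
  if (total <= 0) stop("total molarity is zero; percent contribution undefined")
  out <- data.frame(solute = names(m),
                    mean_concentration = as.numeric(m),
                    percent_contribution = 100 * as.numeric(m) / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call significant solute changes under stress
#'
#' A solute is called up-regulated when its stress/control mean ratio is at
#' least \code{fold_threshold} (default 1.5, a 50\% increase) and a
#' two-sample t-test on the replicate concentrations gives p <
#' \code{alpha}; down-regulation is the symmetric rule (ratio <=
#' 1/fold_threshold). Everything else is "none".
#'
#' @param profile Solute profile with >= 2 replicates per condition.
#' @param fold_threshold Ratio threshold (> 1).
#' @param alpha Significance level for the t-test.
#' @param welch Use Welch's unequal-variance t-test (default) or the pooled
#'   Student test.
#' @return Data frame: \code{solute}, \code{mean_control},
#'   \code{mean_stress}, \code{ratio}, \code{p}, \code{call} in
#'   \{up, down, none\}.
#' @export
significant_solute_change <- function(profile, fold_threshold = 1.5,
                                      alpha = 0.05, welch = TRUE) {
  stopifnot(fold_threshold > 1, alpha > 0, alpha < 1)
  res <- lapply(split(profile, profile$solute), function(x) {
    ctl <- x$concentration[x$condition == "control"]
    str <- x$concentration[x$condition == "stress"]
    if (length(ctl) < 2L || length(str) < 2L) {
      stop("solute '", x$solute[1L], "' needs >= 2 replicates per condition")
    }
    mc <- mean(ctl); ms <- mean(str)
    ratio <- if (mc > 0) ms / mc else NA_real_
    p <- if (stats::var(ctl) == 0 && stats::var(str) == 0) {
      if (mc == ms) 1 else 0
    } else {
      stats::t.test(str, ctl, var.equal = !welch)$p.value
    }
    call <- "none"
    if (!is.na(ratio) && p < alpha) {
      if (ratio >= fold_threshold) call <- "up"
      else if (ratio <= 1 / fold_threshold) call <- "down"
    }
    data.frame(solute = x$solute[1L], mean_control = mc, mean_stress = ms,
               ratio = ratio, p = p, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change = 2^-ddCt with
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#'        (Ct_target,control - Ct_ref,control).
#' With several reference genes the reference Ct is their arithmetic mean
#' per sample; Cts are averaged across replicate samples before
#' differencing (set \code{per_replicate = TRUE} to also obtain
#' per-replicate folds relative to the mean control dCt).
#'
#' @param ct Ct table: data frame with \code{gene}, \code{sample},
#'   \code{ct}.
#' @param target Target gene ID.
#' @param reference Reference gene ID(s); with more than one their mean Ct
#'   per sample is used.
#' @param treated,control Character vectors of sample IDs in each group.
#' @param per_replicate If TRUE, attach the treated-group per-replicate
#'   fold changes as attribute \code{"per_replicate"}.
#' @return Scalar fold change (2^-ddCt).
#' @examples
#' ct <- data.frame(gene = rep(c("tg", "ref"), each = 2),
#'                  sample = rep(c("t1", "c1"), 2), ct = c(25, 24, 20, 20))
#' ddct_relative_expression(ct, "tg", "ref", "t1", "c1")  # 0.5
#' @export
ddct_relative_expression <- function(ct, target, reference, treated, control,
                                     per_replicate = FALSE) {
  get_ct <- function(gene, sample) {
    v <- ct$ct[ct$gene == gene & ct$sample == sample]
    if (length(v) == 0L) stop("no Ct for gene '", gene, "', sample '", sample, "'")
    mean(v)
  }
  ref_ct <- function(sample) mean(vapply(reference, get_ct, numeric(1L),
                                         sample = sample))
  dct <- function(samples) vapply(samples, function(s) {
    get_ct(target, s) - ref_ct(s)
  }, numeric(1L))
  dct_t <- dct(treated)
  dct_c <- dct(control)
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2^(-ddct)
  if (per_replicate) {
    attr(fold, "per_replicate") <- 2^(-(dct_t - mean(dct_c)))
  }
  fold
}
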