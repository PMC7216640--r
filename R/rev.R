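#' Mean expression per gene and condition
#'
#' Averages TPM across biological replicates of one tissue, giving one value
#' per gene per condition — the aggregation used before computing relative
#' expression values.
#'
#' @param matrix Expression matrix from \code{\link{read_expression_matrix}}
#'   with unit \code{"TPM"}.
#' @param sheet Sample sheet (\code{\link{read_sample_sheet}}).
#' @param tissue Tissue label to subset to.
#' @return A genes x conditions numeric matrix of class
#'   \code{condition_means} with attributes \code{tissue} and
#'   \code{n_replicates} (named integer vector).
#' @export
mean_by_condition <- function(matrix, sheet, tissue) {
  unit <- attr(matrix, "unit")
  if (!is.null(unit) && unit != "TPM") {
    stop("mean_by_condition expects a TPM matrix, got unit '", unit, "'")
  }
  sub <- sheet[sheet$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("tissue '", tissue, "' not present in the sample sheet")
  }
  missing <- setdiff(sub$sample_id, colnames(matrix))
  if (length(missing) > 0L) {
    stop("sample(s) in sheet but not in matrix: ", paste(missing, collapse = ", "))
  }
  conditions <- sort(unique(sub$condition))
  means <- vapply(conditions, function(cond) {
    ids <- sub$sample_id[sub$condition == cond]
    rowMeans(matrix[, ids, drop = FALSE])
  }, numeric(nrow(matrix)))
  means <- base::matrix(means, nrow = nrow(matrix),
                        dimnames = list(rownames(matrix), conditions))
  attr(means, "tissue") <- tissue
  attr(means, "n_replicates") <-
    vapply(conditions, function(cond) sum(sub$condition == cond), integer(1L))
  class(means) <- c("condition_means", class(means))
  means
}

# Look up the three homeolog rows of each triad, erroring (not zero-filling)
# on genes absent from the means matrix.
triad_gene_matrix <- function(means, triads, condition) {
  genes <- c(rbind(triads$gene_a, triads$gene_b, triads$gene_d))
  missing <- setdiff(genes, rownames(means))
  if (length(missing) > 0L) {
    stop("triad gene(s) missing from expression data: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  }
  cbind(A = means[triads$gene_a, condition],
        B = means[triads$gene_b, condition],
        D = means[triads$gene_d, condition])
}

#' Filter triads to those detectably expressed
#'
#' Keeps triads whose summed homeolog mean TPM exceeds \code{min_total_tpm}
#' in at least one condition. The detection threshold is a first-class
#' parameter (default 0.5 TPM summed over the three homeologs).
#'
#' @param means Condition means from \code{\link{mean_by_condition}}.
#' @param triads Triad set.
#' @param min_total_tpm Detection threshold (>= 0); a triad passes when its
#'   summed homeolog mean is strictly greater in at least one condition.
#' @return The filtered triad set; a message logs the detected count.
#' @export
detect_expressed_triads <- function(means, triads, min_total_tpm = 0.5) {
  stopifnot(min_total_tpm >= 0)
  totals <- vapply(colnames(means), function(cond) {
    rowSums(triad_gene_matrix(means, triads, cond))
  }, numeric(nrow(triads)))
  totals <- base::matrix(totals, nrow = nrow(triads))
  keep <- apply(totals > min_total_tpm, 1L, any)
  message("detected ", sum(keep), " of ", nrow(triads),
          " triads expressed (summed homeolog TPM > ", min_total_tpm,
          " in >= 1 condition)")
  out <- triads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression values of homeologs within triads
#'
#' For each triad and condition, each homeolog's share of the triad's total
#' mean TPM, as a percentage: e.g. the D homeolog's REV is
#' D\% = 100 * TPM_D / (TPM_A + TPM_B + TPM_D). Conditions where a triad's
#' total is zero yield no record (logged, not an error).
#'
#' @param means Condition means from \code{\link{mean_by_condition}}.
#' @param triads Triad set, already filtered to expressed triads.
#' @return Data frame of class \code{rev_records}: \code{triad_id},
#'   \code{condition}, \code{a_pct}, \code{b_pct}, \code{d_pct},
#'   \code{total_tpm}. Percentages sum to 100 for every row.
#' @export
compute_rev <- function(means, triads) {
  recs <- lapply(colnames(means), function(cond) {
    tpm <- triad_gene_matrix(means, triads, cond)
    total <- rowSums(tpm)
    keep <- total > 0
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message("condition '", cond, "': ", n_dropped,
              " triad(s) with zero total TPM omitted")
    }
    pct <- 100 * tpm[keep, , drop = FALSE] / total[keep]
    data.frame(triad_id = triads$triad_id[keep],
               condition = cond,
               a_pct = pct[, "A"], b_pct = pct[, "B"], d_pct = pct[, "D"],
               total_tpm = total[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("rev_records", "data.frame")
  out
}

#' Call stress-induced shifts in relative homeolog expression
#'
#' For one homeolog, pairs each triad's REV under control and stress and
#' applies the fold-change rule: the shift is significant when
#' \code{max(ratio, 1/ratio) >= fold_threshold} with
#' \code{ratio = rev_control / rev_stress} (so a 20\% change in either
#' direction is significant at the default 1.2). When exactly one of the two
#' REVs is zero the ratio is undefined; such triads are flagged and counted
#' significant (the homeolog's share moved to or from zero). When both are
#' zero the triad is flagged undefined and not significant.
#'
#' @param revs REV records covering both conditions
#'   (\code{\link{compute_rev}}).
#' @param homeolog One of \code{"A"}, \code{"B"}, \code{"D"}.
#' @param fold_threshold Significance threshold on the symmetrized ratio
#'   (> 1; default 1.2, i.e. a >= 20\% change).
#' @return Data frame of class \code{shift_calls}: \code{triad_id},
#'   \code{homeolog}, \code{rev_control}, \code{rev_stress}, \code{ratio}
#'   (NA when undefined), \code{significant}, \code{undefined}.
#' @export
call_rev_shifts <- function(revs, homeolog = c("D", "A", "B"),
                            fold_threshold = 1.2) {
  homeolog <- match.arg(toupper(homeolog), c("D", "A", "B"))
  stopifnot(fold_threshold > 1)
  col <- c(A = "a_pct", B = "b_pct", D = "d_pct")[[homeolog]]
  ctl <- revs[revs$condition == "control", c("triad_id", col)]
  str <- revs[revs$condition == "stress", c("triad_id", col)]
  shared <- intersect(ctl$triad_id, str$triad_id)
  rc <- ctl[[col]][match(shared, ctl$triad_id)]
  rs <- str[[col]][match(shared, str$triad_id)]
  undefined <- (rc == 0) | (rs == 0)
  ratio <- ifelse(undefined, NA_real_, rc / rs)
  significant <- ifelse(undefined,
                        xor(rc == 0, rs == 0),  # one side zero: real shift
                        pmax(ratio, 1 / ratio) >= fold_threshold)
  out <- data.frame(triad_id = shared,
                    homeolog = homeolog,
                    rev_control = rc,
                    rev_stress = rs,
                    ratio = ratio,
                    significant = significant,
                    undefined = undefined,
                    stringsAsFactors = FALSE)
  class(out) <- c("shift_calls", "data.frame")
  out
}

#' Summarize shift calls per homeolog
#'
#' @param calls Shift calls, possibly concatenated over homeologs.
#' @return Data frame per homeolog: \code{n}, \code{n_significant},
#'   \code{n_not_significant}, \code{n_undefined} (the three classes
#'   partition \code{n}: undefined triads are counted only in
#'   \code{n_undefined}), \code{frac_significant} (fraction of all calls
#'   flagged significant, undefined-significant included) and
#'   \code{frac_below_threshold}.
#' @export
shift_summary <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no shift calls to summarize")
  res <- lapply(split(calls, calls$homeolog), function(x) {
    data.frame(homeolog = x$homeolog[1L],
               n = nrow(x),
               n_significant = sum(x$significant & !x$undefined),
               n_not_significant = sum(!x$significant & !x$undefined),
               n_undefined = sum(x$undefined),
               frac_significant = mean(x$significant),
               frac_below_threshold = mean(!x$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
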