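#' Fit the full homeolog-bias analysis for one tissue
#'
#' The central entry point: aggregates TPM over replicates, filters to
#' expressed triads, computes per-triad relative expression values (REVs)
#' under control and stress, classifies every triad x condition into the
#' seven homeolog expression bias categories, calls stress-induced REV
#' shifts for each homeolog, and tabulates bias-category changes.
#'
#' @param expr TPM expression matrix (genes x samples) from
#'   \code{\link{read_expression_matrix}} or \code{\link{simulate_dataset}}.
#' @param triads Triad set (\code{\link{read_triad_table}}).
#' @param samples Sample sheet (\code{\link{read_sample_sheet}}).
#' @param tissue Tissue to analyse.
#' @param min_total_tpm Detection threshold on summed homeolog mean TPM
#'   (\code{\link{detect_expressed_triads}}).
#' @param fold_threshold REV shift threshold
#'   (\code{\link{call_rev_shifts}}).
#' @return Object of class \code{triad_bias}: a list with \code{rev}
#'   (REV records with category, distance and ternary x/y), \code{shifts}
#'   (all three homeologs stacked), \code{shift_summary}, \code{changes}
#'   (per-triad category change), \code{category_summary} (per condition),
#'   \code{n_input}, \code{n_detected}, and the call parameters.
#' @examples
#' sim <- simulate_dataset(sim_config(n_triads = 50, seed = 7))
#' fit <- triad_bias(sim$tpm, sim$triads, sim$sheet, tissue = "root")
#' fit
#' head(summary(fit)$category_summary$control)
#' @export
triad_bias <- function(expr, triads, samples, tissue,
                       min_total_tpm = 0.5, fold_threshold = 1.2) {
  means <- mean_by_condition(expr, samples, tissue)
  detected <- detect_expressed_triads(means, triads, min_total_tpm)
  rev <- compute_rev(means, detected)
  rev <- classify_hebc(rev)
  rev <- ternary_coordinates(rev)

  shifts <- do.call(rbind, lapply(c("A", "B", "D"), function(h) {
    call_rev_shifts(rev, h, fold_threshold)
  }))
  class(shifts) <- c("shift_calls", "data.frame")

  ctl <- rev[rev$condition == "control", ]
  str <- rev[rev$condition == "stress", ]
  changes <- hebc_change(ctl, str)

  structure(list(
    rev = rev,
    shifts = shifts,
    shift_summary = shift_summary(shifts),
    changes = changes,
    category_summary = list(control = hebc_summary(ctl),
                            stress = hebc_summary(str)),
    n_input = nrow(triads),
    n_detected = nrow(detected),
    tissue = tissue,
    min_total_tpm = min_total_tpm,
    fold_threshold = fold_threshold
  ), class = "triad_bias")
}

#' @export
print.triad_bias <- function(x, ...) {
  cat("Homeolog expression bias analysis (tissue: ", x$tissue, ")\n", sep = "")
  cat(sprintf("  %d of %d triads detected (summed homeolog TPM > %g)\n",
              x$n_detected, x$n_input, x$min_total_tpm))
  bal <- x$category_summary$control
  cat(sprintf("  balanced triads (control): %.1f%%\n",
              bal$percent[bal$category == "balanced"]))
  cat(sprintf("  triads changing bias category under stress: %.1f%% (n = %d)\n",
              100 * attr(x$changes, "fraction_changed"), nrow(x$changes)))
  d <- x$shift_summary[x$shift_summary$homeolog == "D", ]
  cat(sprintf("  D%% change < %g-fold in %.1f%% of triads\n",
              x$fold_threshold, 100 * d$frac_below_threshold))
  invisible(x)
}

#' @export
summary.triad_bias <- function(object, ...) {
  out <- list(tissue = object$tissue,
              n_input = object$n_input,
              n_detected = object$n_detected,
              fraction_changed = attr(object$changes, "fraction_changed"),
              category_summary = object$category_summary,
              shift_summary = object$shift_summary)
  class(out) <- "summary.triad_bias"
  out
}

#' @export
print.summary.triad_bias <- function(x, ...) {
  cat("Triad bias summary —", x$tissue, "\n")
  cat(sprintf("Detected %d / %d triads\n", x$n_detected, x$n_input))
  cat("\nCategory percentages (control | stress):\n")
  ctl <- x$category_summary$control
  str <- x$category_summary$stress
  for (i in seq_len(nrow(ctl))) {
    cat(sprintf("  %-13s %6.2f%% | %6.2f%%\n", ctl$category[i],
                ctl$percent[i], str$percent[i]))
  }
  cat(sprintf("\nBias category changed under stress: %.2f%%\n",
              100 * x$fraction_changed))
  cat("\nREV shift calls per homeolog:\n")
  print(x$shift_summary, row.names = FALSE)
  invisible(x)
}

#' Ternary plot of triad compositions
#'
#' Plots each triad's (A, B, D) composition inside the unit triangle
#' (vertices A bottom-left, B bottom-right, D top), coloured by bias
#' category, with the seven centroids marked.
#'
#' @param x A \code{triad_bias} fit.
#' @param condition Which condition to plot.
#' @param ... Passed to \code{points}.
#' @export
plot.triad_bias <- function(x, condition = "control", ...) {
  rev <- x$rev[x$rev$condition == condition, ]
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.05, 1.05), ylim = c(-0.08, sqrt(3) / 2 + 0.08),
                        asp = 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  graphics::lines(tri[, 1L], tri[, 2L])
  graphics::text(c(0, 1, 0.5), c(-0.04, -0.04, sqrt(3) / 2 + 0.04),
                 labels = c("A", "B", "D"))
  pal <- grDevices::hcl.colors(7L, "Dark 3")
  col <- pal[as.integer(rev$category)]
  graphics::points(rev$x, rev$y, col = col, pch = 16, cex = 0.5, ...)
  cen_xy <- ternary_coordinates(hebc_centroids())
  graphics::points(cen_xy$x, cen_xy$y, pch = 3, cex = 1.2)
  graphics::title(main = paste0("Homeolog expression bias (", condition, ")"))
  graphics::legend("topleft", legend = hebc_categories(), col = pal,
                   pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
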