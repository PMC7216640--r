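#' Filter differentially expressed genes
#'
#' A gene is a DEG when its adjusted p-value is at most \code{alpha} and its
#' absolute log2 fold change is at least \code{min_abs_log2fc} (both bounds
#' inclusive). Raw p-values are never substituted for missing adjusted ones.
#'
#' @param de DE records (\code{\link{read_de_table}} or
#'   \code{\link{naive_de}}).
#' @param alpha Adjusted-p threshold in (0, 1); default 0.05.
#' @param min_abs_log2fc Minimum |log2 fold change|; default 1.
#' @return List with \code{up}, \code{down} (gene-ID character vectors),
#'   \code{degs} (their union, in input order) and \code{table} (the DEG
#'   rows with a \code{direction} column).
#' @examples
#' de <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                  log2fc = c(1, 3, -1), padj = c(0.05, 0.051, 0.01))
#' filter_degs(de)$degs  # g1 (boundary in) and g3; g2 misses on padj
#' @export
filter_degs <- function(de, alpha = 0.05, min_abs_log2fc = 1) {
  stopifnot(alpha > 0, alpha < 1, min_abs_log2fc >= 0)
  if (is.null(de$padj)) {
    stop("DE table has no adjusted p-values (padj); raw p-values are not used")
  }
  l2 <- if (!is.null(de$log2fc)) de$log2fc else log2(de$fold_change)
  if (is.null(l2)) stop("DE table needs log2fc or fold_change")
  is_deg <- !is.na(de$padj) & !is.na(l2) &
    de$padj <= alpha & abs(l2) >= min_abs_log2fc
  tab <- data.frame(gene_id = de$gene_id[is_deg],
                    log2fc = l2[is_deg],
                    padj = de$padj[is_deg],
                    direction = ifelse(l2[is_deg] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  list(up = tab$gene_id[tab$direction == "up"],
       down = tab$gene_id[tab$direction == "down"],
       degs = tab$gene_id,
       table = tab)
}

#' Per-homeolog fold changes within selected triads
#'
#' Restricts triads to those with at least one homeolog in \code{genes}
#' (e.g. a salinity-tolerance gene list) and tabulates the stress/control
#' fold change, adjusted p and DEG status of each homeolog, plus which
#' homeolog responds most strongly. Triads with a homeolog absent from the
#' DE table are flagged incomplete and carry NAs; complete rows provide the
#' pairwise scatter data (A vs D, B vs D, A vs B).
#'
#' @param de DE records.
#' @param triads Triad set.
#' @param genes Character vector of member gene IDs (NULL keeps all triads).
#' @param alpha,min_abs_log2fc DEG thresholds applied per homeolog.
#' @return Data frame: \code{triad_id}, \code{fc_a}, \code{fc_b},
#'   \code{fc_d}, \code{padj_a}, \code{padj_b}, \code{padj_d},
#'   \code{deg_a}, \code{deg_b}, \code{deg_d}, \code{max_homeolog} (NA when
#'   tied or incomplete), \code{complete}.
#' @export
homeolog_fold_changes <- function(de, triads, genes = NULL,
                                  alpha = 0.05, min_abs_log2fc = 1) {
  if (!is.null(genes)) {
    keep <- triads$gene_a %in% genes | triads$gene_b %in% genes |
      triads$gene_d %in% genes
    triads <- triads[keep, , drop = FALSE]
  }
  idx <- function(g) match(g, de$gene_id)
  ia <- idx(triads$gene_a); ib <- idx(triads$gene_b); id <- idx(triads$gene_d)
  fc <- cbind(de$fold_change[ia], de$fold_change[ib], de$fold_change[id])
  padj <- cbind(de$padj[ia], de$padj[ib], de$padj[id])
  l2 <- cbind(de$log2fc[ia], de$log2fc[ib], de$log2fc[id])
  complete <- !is.na(ia) & !is.na(ib) & !is.na(id)
  deg <- !is.na(padj) & !is.na(l2) & padj <= alpha & abs(l2) >= min_abs_log2fc
  max_h <- rep(NA_character_, nrow(triads))
  for (i in which(complete)) {
    m <- max(fc[i, ])
    if (sum(fc[i, ] == m) == 1L) max_h[i] <- c("A", "B", "D")[which.max(fc[i, ])]
  }
  out <- data.frame(triad_id = triads$triad_id,
                    fc_a = fc[, 1L], fc_b = fc[, 2L], fc_d = fc[, 3L],
                    padj_a = padj[, 1L], padj_b = padj[, 2L], padj_d = padj[, 3L],
                    deg_a = deg[, 1L], deg_b = deg[, 2L], deg_d = deg[, 3L],
                    max_homeolog = max_h,
                    complete = complete,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test: for each set, the probability of drawing
#' at least the observed number of set members when \code{length(degs)}
#' genes are drawn without replacement from the universe. P-values are
#' BH-adjusted across all tested sets. Sets are intersected with the
#' universe before testing.
#'
#' @param degs Character vector of selected (e.g. differentially expressed)
#'   gene IDs; must be a subset of \code{universe}.
#' @param universe Character vector of all considered gene IDs.
#' @param sets Named list of gene-ID character vectors.
#' @return Data frame: \code{set}, \code{overlap}, \code{set_size},
#'   \code{universe_size}, \code{p}, \code{padj}.
#' @export
hypergeometric_enrichment <- function(degs, universe, sets) {
  universe <- unique(universe)
  degs <- unique(degs)
  if (length(universe) == 0L) stop("empty universe")
  extra <- setdiff(degs, universe)
  if (length(extra) > 0L) {
    stop("DEG(s) not in universe: ", paste(utils::head(extra, 5L), collapse = ", "))
  }
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(s, degs))
    # P(X >= k), X ~ Hypergeometric(white = |s|, black = N - |s|, drawn = |degs|)
    p <- stats::phyper(k - 1L, length(s), length(universe) - length(s),
                       length(degs), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Naive differential expression on raw counts
#'
#' A deliberately simple two-group test so the synthetic pipeline is
#' self-contained: per gene, the stress/control fold change of
#' pseudocounted means, (mean + 0.5)/(mean + 0.5), and a two-sample t-test
#' (Welch) on log2(count + 0.5), BH-adjusted. This is a plain t-test
#' stand-in, not a negative-binomial model; real analyses should supply a
#' DE table from a dedicated tool via \code{\link{read_de_table}}.
#'
#' @param counts Count matrix (genes x samples) with unit \code{"counts"}.
#' @param sheet Sample sheet; at least 2 replicates per condition.
#' @param tissue Optional tissue to subset to (NULL uses all samples).
#' @return Data frame of class \code{de_records} with \code{gene_id},
#'   \code{fold_change}, \code{log2fc}, \code{pvalue}, \code{padj};
#'   attribute \code{method = "naive-t (log2 counts)"}.
#' @export
naive_de <- function(counts, sheet, tissue = NULL) {
  unit <- attr(counts, "unit")
  if (!is.null(unit) && unit != "counts") {
    stop("naive_de expects raw counts, got unit '", unit, "'")
  }
  sub <- if (is.null(tissue)) sheet else sheet[sheet$tissue == tissue, ]
  ctl <- sub$sample_id[sub$condition == "control"]
  str <- sub$sample_id[sub$condition == "stress"]
  if (length(ctl) < 2L || length(str) < 2L) {
    stop("naive_de needs >= 2 replicates per condition; ",
         "supply an external DE table instead")
  }
  xc <- counts[, ctl, drop = FALSE]
  xs <- counts[, str, drop = FALSE]
  fc <- (rowMeans(xs) + 0.5) / (rowMeans(xc) + 0.5)
  lc <- log2(xc + 0.5)
  ls <- log2(xs + 0.5)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    a <- lc[i, ]; b <- ls[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(b, a)$p.value
    }
  }, numeric(1L))
  out <- data.frame(gene_id = rownames(counts),
                    fold_change = fc,
                    log2fc = log2(fc),
                    pvalue = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "naive-t (log2 counts)"
  rownames(out) <- NULL
  class(out) <- c("de_records", "data.frame")
  out
}
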