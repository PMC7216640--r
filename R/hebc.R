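#' Homeolog expression bias category centroids
#'
#' The seven ideal compositions on the (A, B, D) simplex that anchor the
#' bias categories: balanced expression at the barycentre, dominance of one
#' subgenome at each vertex, and suppression of one subgenome at each edge
#' midpoint opposite that vertex.
#'
#' @return A 7 x 3 numeric matrix of fractions, rows named by category in
#'   the fixed tie-break order (balanced, A/B/D-dominant, A/B/D-suppressed),
#'   columns \code{A}, \code{B}, \code{D}. Each row sums to 1.
#' @export
hebc_centroids <- function() {
  m <- rbind(
    balanced       = c(1, 1, 1) / 3,
    `A-dominant`   = c(1, 0, 0),
    `B-dominant`   = c(0, 1, 0),
    `D-dominant`   = c(0, 0, 1),
    `A-suppressed` = c(0, 0.5, 0.5),
    `B-suppressed` = c(0.5, 0, 0.5),
    `D-suppressed` = c(0.5, 0.5, 0)
  )
  colnames(m) <- c("A", "B", "D")
  m
}

#' The seven HEBC labels in canonical order
#' @return Character vector of length 7.
#' @export
hebc_categories <- function() rownames(hebc_centroids())

#' Classify triad compositions into the seven bias categories
#'
#' Each composition (percentages summing to 100, or fractions summing to 1)
#' is assigned to the nearest of the seven category centroids under
#' Euclidean distance in fraction space. Ties — which arise only on exact
#' grid points — are broken by the fixed centroid order of
#' \code{\link{hebc_centroids}}.
#'
#' @param rev Either a data frame of REV records (columns \code{a_pct},
#'   \code{b_pct}, \code{d_pct}; see \code{\link{compute_rev}}) or a numeric
#'   matrix / vector of (A, B, D) compositions.
#' @return For a REV data frame: the data frame with added \code{category}
#'   (factor over the 7 labels) and \code{distance} columns. For a matrix or
#'   vector: a data frame with \code{category} and \code{distance}.
#' @examples
#' classify_hebc(c(33.33, 33.33, 33.34))   # balanced
#' classify_hebc(c(100, 0, 0))             # A-dominant
#' classify_hebc(c(20, 40, 40))            # A-suppressed
#' @export
classify_hebc <- function(rev) {
  is_rev_df <- is.data.frame(rev)
  comp <- if (is_rev_df) {
    as.matrix(rev[, c("a_pct", "b_pct", "d_pct")])
  } else if (is.matrix(rev)) rev else matrix(rev, nrow = 1L)
  if (ncol(comp) != 3L) stop("compositions must have three components (A, B, D)")
  tot <- rowSums(comp)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("compositions must be finite with positive total")
  }
  frac <- comp / tot
  cen <- hebc_centroids()
  # squared distance to each centroid; ||x||^2 term is shared across
  # centroids so the argmin needs only the cross and centroid terms
  cross <- frac %*% t(cen)
  d2 <- matrix(rowSums(cen^2), nrow(frac), 7L, byrow = TRUE) - 2 * cross
  idx <- apply(d2, 1L, which.min)  # which.min takes the first minimum: tie-break
  dist <- sqrt(pmax(rowSums(frac^2) + d2[cbind(seq_len(nrow(frac)), idx)], 0))
  category <- factor(hebc_categories()[idx], levels = hebc_categories())
  if (is_rev_df) {
    rev$category <- category
    rev$distance <- dist
    class(rev) <- c("hebc_assignments", setdiff(class(rev), "hebc_assignments"))
    rev
  } else {
    data.frame(category = category, distance = dist)
  }
}

#' Compare bias categories between control and stress
#'
#' Matches assignments by triad, flags triads whose category label differs
#' between the two conditions, and reports the changed fraction. Triads
#' present in only one condition are excluded and counted.
#'
#' @param control,stress Assignment data frames from
#'   \code{\link{classify_hebc}} with a \code{triad_id} column.
#' @return Data frame with \code{triad_id}, \code{category_control},
#'   \code{category_stress}, \code{changed}, plus attributes
#'   \code{fraction_changed} and \code{n_excluded}.
#' @export
hebc_change <- function(control, stress) {
  shared <- intersect(control$triad_id, stress$triad_id)
  if (length(shared) == 0L) stop("no triads shared between the two conditions")
  n_excluded <- (nrow(control) - length(shared)) + (nrow(stress) - length(shared))
  cc <- control$category[match(shared, control$triad_id)]
  cs <- stress$category[match(shared, stress$triad_id)]
  out <- data.frame(triad_id = shared,
                    category_control = cc,
                    category_stress = cs,
                    changed = as.character(cc) != as.character(cs),
                    stringsAsFactors = FALSE)
  attr(out, "fraction_changed") <- mean(out$changed)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-category counts and percentages
#'
#' @param assignments Assignment data frame from \code{\link{classify_hebc}}.
#' @return Data frame with \code{category}, \code{n}, \code{percent};
#'   percentages sum to 100.
#' @export
hebc_summary <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no assignments to summarize")
  cat <- factor(assignments$category, levels = hebc_categories())
  n <- as.integer(table(cat))
  data.frame(category = hebc_categories(),
             n = n,
             percent = 100 * n / sum(n),
             stringsAsFactors = FALSE)
}

#' Map compositions to ternary-plot coordinates
#'
#' Standard barycentric-to-Cartesian map with vertices A = (0, 0),
#' B = (1, 0), D = (1/2, sqrt(3)/2): on fractions (a, b, d),
#' x = b + d/2 and y = d * sqrt(3)/2. Injective on the simplex.
#'
#' @param rev REV data frame (columns \code{a_pct}, \code{b_pct},
#'   \code{d_pct}) or numeric matrix / vector of compositions.
#' @return Data frame with columns \code{x}, \code{y} (the input data frame
#'   with those columns appended, if a data frame was given).
#' @export
ternary_coordinates <- function(rev) {
  is_rev_df <- is.data.frame(rev)
  comp <- if (is_rev_df) {
    as.matrix(rev[, c("a_pct", "b_pct", "d_pct")])
  } else if (is.matrix(rev)) rev else matrix(rev, nrow = 1L)
  frac <- comp / rowSums(comp)
  x <- frac[, 2L] + frac[, 3L] / 2
  y <- frac[, 3L] * sqrt(3) / 2
  if (is_rev_df) {
    rev$x <- x
    rev$y <- y
    rev
  } else {
    data.frame(x = x, y = y)
  }
}
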