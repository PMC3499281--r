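#' Describe the RH panels of a mapping design
#'
#' @param n_clones,kb_per_cr,retention Vectors (recycled) describing each
#'   panel; defaults are the two pig panels re-estimated at high marker
#'   density: 90 clones each at 8.6 and 5.3 Kb/cR.
#' @param panel Optional panel names.
#' @return Tibble `panel`, `n_clones`, `kb_per_cr`, `retention`.
#' @export
rh_panels <- function(n_clones = c(90, 90), kb_per_cr = c(8.6, 5.3),
                      retention = 0.3, panel = NULL) {
  n <- max(length(n_clones), length(kb_per_cr), length(retention))
  out <- tibble(
    panel = panel %||% paste0("RH", seq_len(n)),
    n_clones = rep_len(n_clones, n),
    kb_per_cr = rep_len(kb_per_cr, n),
    retention = rep_len(retention, n)
  )
  if (any(out$n_clones < 1) || any(out$kb_per_cr <= 0) ||
      any(out$retention <= 0) || any(out$retention >= 1)) {
    abort("Panels need n_clones >= 1, kb_per_cr > 0, retention in (0, 1).")
  }
  out
}

#' Probability that two adjacent markers are separable
#'
#' Analytic separability of two markers `d_kb` apart under the
#' breakage-retention model, assuming the true order, error-free vectors
#' and independent clones: in one clone of a panel with resolution `c`
#' Kb/cR and retention `r`, the markers are distinguishable when a break
#' falls between them (probability `b = 1 - exp(-(d/c)/100)`) and exactly
#' one of the two fragments is retained (probability `2 r (1-r)`).
#' Across all clones of all panels,
#' `P = 1 - prod_panels (1 - 2 r (1-r) b)^N`.
#'
#' @param panels An [rh_panels()] tibble.
#' @param d_kb Marker spacing(s) in Kb, vectorized.
#' @return Tibble `d_kb`, `prob`.
#' @export
prob_separated <- function(panels, d_kb) {
  assert_columns(panels, c("n_clones", "kb_per_cr", "retention"),
                 "`panels`")
  if (any(d_kb < 0)) abort("`d_kb` must be non-negative.")
  prob <- vapply(d_kb, function(d) {
    b <- 1 - exp(-(d / panels$kb_per_cr) / 100)
    p_clone <- 2 * panels$retention * (1 - panels$retention) * b
    1 - prod((1 - p_clone)^panels$n_clones)
  }, numeric(1))
  tibble(d_kb = d_kb, prob = prob)
}

#' Expected proportion of markers at distinct map positions
#'
#' For `n` markers evenly spaced over a genome of `genome_kb` kilobases,
#' the expected fraction assignable to distinct positions is the
#' separability probability at spacing `genome_kb / n`.
#'
#' @param panels An [rh_panels()] tibble.
#' @param n_markers Number of genotyped markers (>= 2).
#' @param genome_kb Genome (or autosome) size in Kb.
#' @return One-row tibble `n_markers`, `genome_kb`, `d_kb`, `fraction`.
#' @export
expected_distinct_fraction <- function(panels, n_markers, genome_kb) {
  n_markers <- assert_count(n_markers, "n_markers", min = 2L)
  if (genome_kb <= 0) abort("`genome_kb` must be positive.")
  d <- genome_kb / n_markers
  tibble(n_markers = n_markers, genome_kb = genome_kb, d_kb = d,
         fraction = prob_separated(panels, d)$prob)
}

#' Count distinct positions in an RH map
#'
#' Two consecutive markers share a position when their cR positions are
#' equal in every panel; the number of distinct positions is the number
#' of runs of position-sharing markers.
#'
#' @param map Map tibble with one or more `pos_cr_*` columns (or the
#'   columns named in `pos_cols`), in map order.
#' @param pos_cols Position columns to use.
#' @param tol Positions closer than this (cR) count as equal (the breakage
#'   probability is bounded away from zero in the fit, so truly
#'   unseparated markers sit a vanishing but nonzero distance apart).
#' @return Integer count of distinct positions.
#' @export
count_distinct_positions <- function(map, pos_cols = NULL, tol = 1e-3) {
  pos_cols <- pos_cols %||% grep("^pos_cr_", names(map), value = TRUE)
  if (length(pos_cols) == 0L) abort("No position columns found.")
  if (nrow(map) == 0L) return(0L)
  differs <- rep(FALSE, nrow(map) - 1)
  for (cc in pos_cols) {
    differs <- differs | (abs(diff(map[[cc]])) > tol)
  }
  as.integer(1L + sum(differs))
}

#' Observed fraction of markers separated from both neighbours
#'
#' The estimator applied to real maps: the fraction of markers whose
#' position differs from each of its neighbours in at least one panel
#' (terminal markers have a single neighbour).
#'
#' @inheritParams count_distinct_positions
#' @return Fraction in `[0, 1]`.
#' @export
observed_distinct_fraction <- function(map, pos_cols = NULL, tol = 1e-3) {
  pos_cols <- pos_cols %||% grep("^pos_cr_", names(map), value = TRUE)
  if (length(pos_cols) == 0L) abort("No position columns found.")
  n <- nrow(map)
  if (n < 2L) return(1)
  differs <- rep(FALSE, n - 1)
  for (cc in pos_cols) {
    differs <- differs | (abs(diff(map[[cc]])) > tol)
  }
  ok_prev <- c(TRUE, differs)
  ok_next <- c(differs, TRUE)
  mean(ok_prev & ok_next)
}

#' Design trade-off: markers genotyped versus markers mappable
#'
#' Evaluates, over a grid of genotyped marker counts, the expected number
#' of markers mappable to distinct positions, `n * P(genome_kb / n)`.
#' Densifying the array increases the mappable count with strongly
#' diminishing returns, since the separation probability falls as
#' spacing shrinks.
#'
#' @param panels An [rh_panels()] tibble.
#' @param genome_kb Genome size in Kb.
#' @param n_grid Grid of genotyped marker counts.
#' @return A tibble of class `rh_design_tradeoff`: `n_genotyped`, `d_kb`,
#'   `prob`, `expected_mappable`, `marginal_gain` (per additional
#'   genotyped marker, against the previous grid point); the grid argmax
#'   is stored in the `optimum` attribute.
#' @export
design_tradeoff <- function(panels, genome_kb,
                            n_grid = round(10^seq(4, 6, by = 0.1))) {
  if (length(n_grid) == 0L) abort("`n_grid` is empty.")
  n_grid <- sort(unique(round(n_grid)))
  d <- genome_kb / n_grid
  p <- prob_separated(panels, d)$prob
  out <- tibble(
    n_genotyped = n_grid, d_kb = d, prob = p,
    expected_mappable = n_grid * p,
    marginal_gain = c(NA_real_,
                      diff(n_grid * p) / diff(n_grid))
  )
  attr(out, "optimum") <- out$n_genotyped[which.max(out$expected_mappable)]
  class(out) <- c("rh_design_tradeoff", class(out))
  out
}
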