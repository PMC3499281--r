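#' Two-point linkage analysis of a pair of RH vectors
#'
#' Under the equal-retention haploid model, two markers separated by
#' breakage probability `theta` have clone-wise joint probabilities
#' `P(1,1) = r(1-theta) + r^2 theta`, `P(1,0) = P(0,1) = r theta (1-r)`,
#' `P(0,0) = (1-r)(1-theta) + (1-r)^2 theta`. The MLE of `(theta, r)` is
#' found numerically over the unit square; the LOD score is the log10
#' likelihood ratio of the fitted model against independence
#' (`theta = 1`, with the retention refitted under independence). Clones
#' with either call missing are dropped.
#'
#' @param calls Long calls tibble (`marker`, `clone`, `call`, optionally
#'   `panel`).
#' @param markers The two markers to test; defaults to the only two
#'   markers present.
#' @param panel Optional panel to restrict to.
#' @param min_overlap Minimum number of jointly non-missing clones.
#' @return One-row tibble with the 2x2 counts, `theta_hat`, `r_hat`,
#'   `loglik`, `lod` and `d_cr` (`-100 log(1 - theta_hat)`).
#' @export
two_point <- function(calls, markers = NULL, panel = NULL,
                      min_overlap = 10) {
  if (is.null(markers)) {
    markers <- unique(calls$marker)
    if (length(markers) != 2L) {
      abort("Supply `markers`: `calls` does not contain exactly 2 markers.")
    }
  }
  if (length(markers) != 2L) abort("`markers` must name exactly 2 markers.")
  m <- calls_matrix(calls, markers, panel)
  v1 <- m[, 1]; v2 <- m[, 2]
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) == 0L) {
    abort(sprintf("no overlap: markers %s and %s share no observed clone.",
                  markers[1], markers[2]))
  }
  if (sum(ok) < min_overlap) {
    abort(sprintf(
      "Markers %s and %s share only %d jointly observed clones (< %d).",
      markers[1], markers[2], sum(ok), min_overlap))
  }
  v1 <- v1[ok]; v2 <- v2[ok]
  n11 <- sum(v1 == 1 & v2 == 1); n10 <- sum(v1 == 1 & v2 == 0)
  n01 <- sum(v1 == 0 & v2 == 1); n00 <- sum(v1 == 0 & v2 == 0)
  fit <- cpp_two_point(n11, n10, n01, n00)
  tibble(
    marker1 = markers[1], marker2 = markers[2],
    panel = panel %||% NA_character_,
    n11 = n11, n10 = n10, n01 = n01, n00 = n00,
    n_informative = n11 + n10 + n01 + n00,
    theta_hat = fit$theta_hat, r_hat = fit$r_hat,
    loglik = fit$loglik, lod = fit$lod,
    d_cr = -100 * log(1 - fit$theta_hat)
  )
}

# all-pairs two-point results on one panel, via 2x2 counts from
# cross-products of the 0/1 indicator matrices
pairwise_two_point <- function(calls, panel = NULL, min_overlap = 10) {
  m <- calls_matrix(calls, panel = panel)
  keep <- colSums(!is.na(m)) > 0
  m <- m[, keep, drop = FALSE]
  p <- ncol(m)
  if (p < 2L) {
    return(tibble(marker1 = character(), marker2 = character(),
                  theta_hat = numeric(), r_hat = numeric(),
                  loglik = numeric(), lod = numeric(),
                  n_informative = numeric()))
  }
  one <- (m == 1); one[is.na(one)] <- FALSE
  zero <- (m == 0); zero[is.na(zero)] <- FALSE
  mode(one) <- "numeric"; mode(zero) <- "numeric"
  n11 <- crossprod(one)
  n10 <- crossprod(one, zero)
  n00 <- crossprod(zero)
  ut <- upper.tri(n11)
  idx <- which(ut, arr.ind = TRUE)
  a <- n11[ut]; b <- n10[ut]; cc <- t(n10)[ut]; d <- n00[ut]
  tot <- a + b + cc + d
  ok <- tot >= min_overlap
  fit <- cpp_two_point(a[ok], b[ok], cc[ok], d[ok])
  tibble(
    marker1 = colnames(m)[idx[ok, 1]],
    marker2 = colnames(m)[idx[ok, 2]],
    theta_hat = fit$theta_hat, r_hat = fit$r_hat,
    loglik = fit$loglik, lod = fit$lod,
    n_informative = tot[ok]
  )
}

#' Construct linkage groups from two-point LOD scores
#'
#' Markers are joined when their two-point LOD reaches `min_lod` in every
#' panel on which both are typed (and they share at least one panel);
#' linkage groups are the connected components of the resulting graph.
#' Components of size `min_size` or smaller are discarded and their
#' markers reported as unlinked.
#'
#' @param calls Long calls tibble covering one chromosome, with a `panel`
#'   column (markers may be typed on one or both panels).
#' @param min_lod Minimum LOD score (default 6).
#' @param min_size Groups must be strictly larger than this (default 10).
#' @param min_overlap Minimum jointly observed clones per pair.
#' @return A list of class `rh_linkage_groups`: `groups` (tibble `marker`,
#'   `group`, `group_size`), `unlinked` (tibble `marker`, `reason`),
#'   `n_groups`.
#' @export
build_linkage_groups <- function(calls, min_lod = 6, min_size = 10,
                                 min_overlap = 10) {
  if (nrow(calls) == 0L) {
    return(structure(list(
      groups = tibble(marker = character(), group = integer(),
                      group_size = integer()),
      unlinked = tibble(marker = character(), reason = character()),
      n_groups = 0L
    ), class = "rh_linkage_groups"))
  }
  assert_columns(calls, c("marker", "panel", "clone", "call"), "`calls`")
  panels <- unique(calls$panel)
  markers <- unique(calls$marker)

  per_panel <- purrr::map(panels, function(p) {
    pairwise_two_point(calls, panel = p, min_overlap = min_overlap) |>
      mutate(panel = p)
  }) |> purrr::list_rbind()

  # an edge requires lod >= min_lod in every panel where the pair is typed
  edges <- per_panel |>
    group_by(.data$marker1, .data$marker2) |>
    summarise(min_lod_seen = min(.data$lod), .groups = "drop") |>
    filter(.data$min_lod_seen >= min_lod)

  g <- igraph::graph_from_data_frame(
    edges[, c("marker1", "marker2")], directed = FALSE,
    vertices = data.frame(name = markers)
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  sizes <- comp$csize[membership]
  keep <- sizes > min_size

  grp_tbl <- tibble(marker = names(membership),
                    group = as.integer(membership),
                    group_size = as.integer(sizes))[keep, , drop = FALSE]
  # renumber groups by decreasing size
  if (nrow(grp_tbl) > 0) {
    lev <- grp_tbl |> distinct(.data$group, .data$group_size) |>
      arrange(dplyr::desc(.data$group_size), .data$group)
    grp_tbl$group <- match(grp_tbl$group, lev$group)
  }
  unlinked <- tibble(
    marker = names(membership)[!keep],
    reason = if_else(comp$csize[membership[!keep]] == 1L,
                     "no_linkage", "small_group")
  )
  structure(
    list(groups = grp_tbl, unlinked = unlinked,
         n_groups = length(unique(grp_tbl$group))),
    class = "rh_linkage_groups"
  )
}

#' @export
tidy.rh_linkage_groups <- function(x, ...) x$groups

#' @export
print.rh_linkage_groups <- function(x, ...) {
  cat(sprintf("<rh_linkage_groups> %d group(s), %d marker(s) unlinked\n",
              x$n_groups, nrow(x$unlinked)))
  invisible(x)
}

# moment initialisation for the EM: adjacent discordance / (2 r (1-r))
init_theta <- function(mat) {
  r0 <- mean(mat == 1L, na.rm = TRUE)
  r0 <- min(max(r0, 0.01), 0.99)
  m <- ncol(mat)
  d <- colMeans(mat[, -1, drop = FALSE] != mat[, -m, drop = FALSE],
                na.rm = TRUE)
  d[is.nan(d)] <- 0.5 * 2 * r0 * (1 - r0)
  th <- pmin(pmax(d / (2 * r0 * (1 - r0)), 1e-3), 1 - 1e-3)
  list(theta = unname(th), r = r0)
}

#' Multipoint log-likelihood of a marker order on one panel
#'
#' Evaluates the haploid hidden-Markov retention model along the given
#' order: initial retention probability `r`, per-interval breakage
#' probabilities `theta`, transition matrix
#' `P(1->1) = (1-theta) + theta r`, `P(1->0) = theta (1-r)`,
#' `P(0->1) = theta r`, `P(0->0) = (1-theta) + theta (1-r)`, missing
#' calls marginalised by the forward algorithm. Per-interval `theta` and
#' the panel-wide `r` are fitted by EM (convergence when the
#' log-likelihood gain drops below `tol`); the returned value is the
#' profile log-likelihood in natural-log units.
#'
#' @param calls Long calls tibble.
#' @param order Character vector: a marker order (a permutation of the
#'   markers to fit; duplicates or unknown markers are an error).
#' @param panel Panel to evaluate.
#' @param eps Genotyping-error emission probability (default 0: calls are
#'   taken at face value).
#' @param tol,max_iter EM convergence controls.
#' @return A list of class `rh_multipoint_fit`: `loglik`, `theta`
#'   (length `m - 1`), `r`, `d_cr` (per-interval centiRay lengths
#'   `-100 log(1 - theta)`), `order`, `panel`, `iterations`, `converged`.
#' @export
multipoint_loglik <- function(calls, order, panel = NULL, eps = 0,
                              tol = 1e-6, max_iter = 200) {
  if (anyDuplicated(order) > 0L) abort("`order` contains duplicate markers.")
  known <- unique(calls$marker)
  bad <- setdiff(order, known)
  if (length(bad) > 0L) {
    abort(sprintf("`order` is not a permutation of typed markers; unknown: %s.",
                  paste(bad, collapse = ", ")))
  }
  mat <- calls_matrix(calls, order, panel)
  if (ncol(mat) < 2L) abort("Need at least 2 markers.")
  ini <- init_theta(mat)
  fit <- cpp_rh_em(mat, ini$theta, ini$r, eps, tol, max_iter, TRUE)
  structure(
    list(loglik = fit$loglik, theta = as.numeric(fit$theta), r = fit$r,
         d_cr = -100 * log(1 - as.numeric(fit$theta)),
         order = order, panel = panel, eps = eps,
         iterations = fit$iterations, converged = fit$converged),
    class = "rh_multipoint_fit"
  )
}

#' @export
tidy.rh_multipoint_fit <- function(x, ...) {
  m <- length(x$order)
  tibble(
    left_marker = x$order[-m], right_marker = x$order[-1],
    theta = x$theta, d_cr = x$d_cr
  )
}

#' @export
glance.rh_multipoint_fit <- function(x, ...) {
  tibble(loglik = x$loglik, r = x$r, n_markers = length(x$order),
         length_cr = sum(x$d_cr), iterations = x$iterations,
         converged = x$converged)
}

#' Count reference-adjacency breakpoints of an order
#'
#' Number of adjacent marker pairs in `order` that are not adjacent (in
#' either orientation) in the reference order.
#'
#' @param order Character vector of markers.
#' @param reference Reference order (character vector or tibble with a
#'   `marker` column); must cover all markers in `order`.
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(order, reference) {
  ref <- as_reference(reference)
  pos <- ref$ref_index[match(order, ref$marker)]
  if (any(is.na(pos))) {
    abort(sprintf("Markers absent from reference: %s.",
                  paste(order[is.na(pos)], collapse = ", ")))
  }
  sum(abs(diff(pos)) != 1L)
}

# -- internal scoring context -------------------------------------------

# Precompiles per-panel call matrices and reference indices so that orders
# (given as integer vectors over 1..m) can be scored repeatedly and cached.
make_score_ctx <- function(calls, reference, lambda, markers = NULL,
                           eps = 0, tol = 1e-6, max_iter = 100) {
  ref <- as_reference(reference)
  markers <- markers %||% intersect(ref$marker, unique(calls$marker))
  bad <- setdiff(markers, ref$marker)
  if (length(bad) > 0L) {
    abort(sprintf("Markers absent from reference: %s.",
                  paste(bad, collapse = ", ")))
  }
  panels <- unique(calls$panel)
  mats <- lapply(panels, function(p) calls_matrix(calls, markers, p))
  names(mats) <- panels
  list(
    markers = markers,
    m = length(markers),
    mats = mats,
    ref_pos = ref$ref_index[match(markers, ref$marker)],
    ref_bp = if ("ref_bp" %in% names(ref))
      ref$ref_bp[match(markers, ref$marker)] else NULL,
    lambda = lambda, eps = eps, tol = tol, max_iter = max_iter,
    cache = new.env(parent = emptyenv())
  )
}

score_order_idx <- function(ctx, idx, detail = FALSE) {
  key_f <- paste(idx, collapse = ".")
  key_r <- paste(rev(idx), collapse = ".")
  key <- if (key_f < key_r) key_f else key_r
  hit <- ctx$cache[[key]]
  if (!is.null(hit) && !detail) return(hit$score)
  if (!is.null(hit) && detail && !is.null(hit$fits)) return(hit)
  fits <- lapply(ctx$mats, function(mat) {
    sub <- mat[, idx, drop = FALSE]
    ini <- init_theta(sub)
    cpp_rh_em(sub, ini$theta, ini$r, ctx$eps, ctx$tol, ctx$max_iter, TRUE)
  })
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  bp <- sum(abs(diff(ctx$ref_pos[idx])) != 1L)
  score <- sum(ll) - ctx$lambda * bp
  res <- list(score = score, loglik_by_panel = ll, breakpoints = bp,
              fits = if (detail) fits else NULL)
  ctx$cache[[key]] <- res
  if (detail) res else score
}

#' Comparative ordering criterion: RH likelihood plus an assembly prior
#'
#' Scores a marker order as the sum over panels of the multipoint profile
#' log-likelihood minus `lambda` (natural-log units) per reference
#' breakpoint. With an uninformative likelihood the penalty makes the
#' search keep the prior (assembly) ordering; `lambda = 0` gives the pure
#' RH score.
#'
#' @param calls Long calls tibble with a `panel` column (one or two
#'   panels).
#' @param order Character vector of markers.
#' @param reference Reference order covering all markers of `order`.
#' @param lambda Breakpoint penalty weight; the default `3 log(10)` is a
#'   LOD-3-equivalent prior cost per breakpoint.
#' @param eps,tol,max_iter Passed to the multipoint fits.
#' @return A list of class `rh_comparative_score`: `score`,
#'   `loglik_by_panel`, `breakpoints`, `lambda`.
#' @export
comparative_score <- function(calls, order, reference,
                              lambda = 3 * log(10), eps = 0, tol = 1e-6,
                              max_iter = 200) {
  ctx <- make_score_ctx(calls, reference, lambda, markers = order,
                        eps = eps, tol = tol, max_iter = max_iter)
  res <- score_order_idx(ctx, seq_len(ctx$m), detail = TRUE)
  structure(
    list(score = res$score, loglik_by_panel = res$loglik_by_panel,
         breakpoints = res$breakpoints, lambda = lambda, order = order),
    class = "rh_comparative_score"
  )
}

#' @export
print.rh_comparative_score <- function(x, ...) {
  cat(sprintf(
    "<rh_comparative_score> score = %.3f (%d breakpoint(s), lambda = %.2f)\n",
    x$score, x$breakpoints, x$lambda))
  invisible(x)
}

# orientation rule: emit the orientation whose first marker has the
# smaller reference position
orient_idx <- function(idx, ref_pos) {
  if (ref_pos[idx[1]] > ref_pos[idx[length(idx)]]) rev(idx) else idx
}

#' Search for a locally optimal marker order
#'
#' Tour-improvement search over the comparative criterion: segment
#' reversals (2-opt) and relocations of short segments (Or-opt, lengths
#' 1-3) are applied until no move improves the score. The default initial
#' order is the reference (assembly prior) restricted to the markers at
#' hand.
#'
#' @inheritParams comparative_score
#' @param initial Optional initial order (default: reference order).
#' @param or_opt_lengths Segment lengths tried for relocation moves.
#' @param max_sweeps Safety cap on improvement sweeps.
#' @return An `rh_map` tibble (see [as_rh_map()]) carrying the fitted
#'   per-panel centiRay positions and the final score as attributes.
#' @export
order_search <- function(calls, reference, initial = NULL,
                         lambda = 3 * log(10), or_opt_lengths = 1:3,
                         max_sweeps = 60, eps = 0, tol = 1e-6,
                         max_iter = 100) {
  ref <- as_reference(reference)
  markers <- initial %||% intersect(ref$marker, unique(calls$marker))
  ctx <- make_score_ctx(calls, ref, lambda, markers = markers,
                        eps = eps, tol = tol, max_iter = max_iter)
  m <- ctx$m
  cur <- seq_len(m)
  cur_score <- score_order_idx(ctx, cur)

  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    # 2-opt: reverse segment [i, j]
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        cand <- cur
        cand[i:j] <- cand[j:i]
        s <- score_order_idx(ctx, cand)
        if (s > cur_score + 1e-9) {
          cur <- cand; cur_score <- s; improved <- TRUE
        }
      }
    }
    # Or-opt: relocate short segments
    for (L in or_opt_lengths) {
      if (L >= m) next
      for (s0 in seq_len(m - L + 1)) {
        seg <- cur[s0:(s0 + L - 1)]
        rest <- cur[-(s0:(s0 + L - 1))]
        for (at in 0:length(rest)) {
          if (at == s0 - 1) next
          cand <- append(rest, seg, after = at)
          s <- score_order_idx(ctx, cand)
          if (s > cur_score + 1e-9) {
            cur <- cand; cur_score <- s; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }

  cur <- orient_idx(cur, ctx$ref_pos)
  build_rh_map(ctx, cur)
}

# assemble an rh_map tibble from a scored order
build_rh_map <- function(ctx, idx) {
  res <- score_order_idx(ctx, idx, detail = TRUE)
  out <- tibble(
    marker = ctx$markers[idx],
    order_index = seq_along(idx)
  )
  for (p in names(ctx$mats)) {
    th <- as.numeric(res$fits[[p]]$theta)
    pos <- cumsum(c(0, -100 * log(1 - th)))
    out[[paste0("pos_cr_", tolower(p))]] <- pos
  }
  if (!is.null(ctx$ref_bp)) out$ref_bp <- ctx$ref_bp[idx]
  attr(out, "score") <- res$score
  attr(out, "loglik_by_panel") <- res$loglik_by_panel
  attr(out, "breakpoints") <- res$breakpoints
  attr(out, "lambda") <- ctx$lambda
  attr(out, "r_by_panel") <- vapply(res$fits, function(f) f$r, numeric(1))
  class(out) <- c("rh_map", class(out))
  out
}

#' Coerce a marker table to an RH map
#'
#' An `rh_map` is a tibble with one row per marker in map order, columns
#' `marker`, `order_index`, per-panel centiRay positions
#' (`pos_cr_<panel>`) and optionally `ref_bp` and `chrom`.
#'
#' @param x A data frame with at least `marker` and one `pos_cr_*` column.
#' @return The input with class `rh_map`.
#' @export
as_rh_map <- function(x) {
  assert_columns(x, "marker", "`x`")
  if (!any(grepl("^pos_cr_", names(x)))) {
    abort("An rh_map needs at least one `pos_cr_<panel>` column.")
  }
  x <- as_tibble(x)
  if (!"order_index" %in% names(x)) x$order_index <- seq_len(nrow(x))
  if (!inherits(x, "rh_map")) class(x) <- c("rh_map", class(x))
  x
}

#' @export
tidy.rh_map <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rh_map")
  out
}

#' @export
glance.rh_map <- function(x, ...) {
  pos_cols <- grep("^pos_cr_", names(x), value = TRUE)
  lens <- vapply(pos_cols, function(cc) max(x[[cc]]) - min(x[[cc]]),
                 numeric(1))
  out <- tibble(n_markers = nrow(x))
  for (cc in pos_cols) out[[sub("^pos_cr_", "length_cr_", cc)]] <- lens[[cc]]
  out$score <- attr(x, "score") %||% NA_real_
  out$breakpoints <- attr(x, "breakpoints") %||% NA_integer_
  out
}
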