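#' Sample marker orders from their posterior by MCMC
#'
#' Metropolis-Hastings over marker orders with target density proportional
#' to `exp(comparative_score)`. The proposal mixture draws an adjacent
#' transposition with probability 0.4, a random segment reversal with
#' probability 0.3 and a random short-segment relocation with probability
#' 0.3; all three are symmetric, so no Hastings correction is needed.
#' Every post-burn-in state is recorded (no thinning). Because the
#' likelihood is invariant to whole-order reversal, each recorded sample
#' is canonicalised to the orientation aligned with the reference before
#' storage, so that pair frequencies are well defined.
#'
#' @inheritParams comparative_score
#' @param initial Optional initial order (default: reference order
#'   restricted to the typed markers).
#' @param n_iter Total MCMC iterations (default 5000).
#' @param burnin Iterations discarded as burn-in (default 1000).
#' @param max_seg Maximum relocated segment length.
#' @param seed Optional integer seed.
#' @return A list of class `rh_order_sample`: `orders` (integer matrix,
#'   one retained iteration per row, entries are indices into `markers`),
#'   `markers`, `scores`, `n_iter`, `burnin`, `acceptance_rate`, `seed`,
#'   `lambda`.
#' @export
mcmc_orders <- function(calls, reference, initial = NULL,
                        lambda = 3 * log(10), n_iter = 5000, burnin = 1000,
                        max_seg = 3, seed = NULL, eps = 0, tol = 1e-6,
                        max_iter = 100) {
  n_iter <- assert_count(n_iter, "n_iter", min = 1L)
  burnin <- assert_count(burnin, "burnin")
  if (n_iter <= burnin) abort("`n_iter` must exceed `burnin`.")
  ref <- as_reference(reference)
  markers <- initial %||% intersect(ref$marker, unique(calls$marker))
  ctx <- make_score_ctx(calls, ref, lambda, markers = markers,
                        eps = eps, tol = tol, max_iter = max_iter)
  m <- ctx$m
  if (m < 2L) abort("Need at least 2 markers.")

  keep_n <- n_iter - burnin
  orders <- matrix(NA_integer_, keep_n, m)
  scores <- numeric(keep_n)
  accepted <- 0L

  with_seed_(seed, {
    cur <- seq_len(m)
    cur_score <- score_order_idx(ctx, cur)
    for (it in seq_len(n_iter)) {
      u <- runif(1)
      cand <- cur
      if (u < 0.4) {
        i <- sample.int(m - 1L, 1L)
        cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
      } else if (u < 0.7) {
        ij <- sort(sample.int(m, 2L))
        cand[ij[1]:ij[2]] <- cand[ij[2]:ij[1]]
      } else {
        L <- sample.int(min(max_seg, m - 1L), 1L)
        s0 <- sample.int(m - L + 1L, 1L)
        seg <- cand[s0:(s0 + L - 1L)]
        rest <- cand[-(s0:(s0 + L - 1L))]
        at <- sample.int(length(rest) + 1L, 1L) - 1L
        cand <- append(rest, seg, after = at)
      }
      cand_score <- score_order_idx(ctx, cand)
      if (log(runif(1)) < cand_score - cur_score) {
        cur <- cand; cur_score <- cand_score; accepted <- accepted + 1L
      }
      if (it > burnin) {
        orders[it - burnin, ] <- orient_idx(cur, ctx$ref_pos)
        scores[it - burnin] <- cur_score
      }
    }
  })

  structure(
    list(orders = orders, markers = ctx$markers, scores = scores,
         n_iter = n_iter, burnin = burnin,
         acceptance_rate = accepted / n_iter, seed = seed, lambda = lambda,
         ref_pos = ctx$ref_pos),
    class = "rh_order_sample"
  )
}

#' @export
print.rh_order_sample <- function(x, ...) {
  cat(sprintf(
    "<rh_order_sample> %d retained orders over %d markers (acceptance %.1f%%)\n",
    nrow(x$orders), length(x$markers), 100 * x$acceptance_rate))
  invisible(x)
}

#' @export
tidy.rh_order_sample <- function(x, ...) {
  key <- apply(x$orders, 1, paste, collapse = ".")
  tab <- sort(table(key), decreasing = TRUE)
  tibble(
    order = purrr::map_chr(names(tab), function(k) {
      paste(x$markers[as.integer(strsplit(k, ".", fixed = TRUE)[[1]])],
            collapse = " ")
    }),
    n = as.integer(tab),
    frequency = as.integer(tab) / nrow(x$orders)
  )
}

#' @export
glance.rh_order_sample <- function(x, ...) {
  tibble(n_retained = nrow(x$orders), n_iter = x$n_iter, burnin = x$burnin,
         acceptance_rate = x$acceptance_rate,
         n_distinct_orders = nrow(tidy(x)))
}

#' Posterior pair-order agreement
#'
#' For every marker pair `(i, j)`, the posterior frequency `q_ij` with
#' which `i` precedes `j` across the retained MCMC samples. Antisymmetry
#' `q_ij + q_ji = 1` holds exactly; the diagonal is `NA`.
#'
#' @param sample An [mcmc_orders()] result.
#' @return A matrix of class `rh_pair_agreement` with marker dimnames.
#' @export
pair_agreement <- function(sample) {
  if (!inherits(sample, "rh_order_sample")) {
    abort("`sample` must be an rh_order_sample.")
  }
  if (nrow(sample$orders) == 0L) abort("Empty order sample.")
  m <- length(sample$markers)
  # positions of each marker in each sample
  pos <- matrix(NA_integer_, nrow(sample$orders), m)
  for (s in seq_len(nrow(sample$orders))) {
    pos[s, sample$orders[s, ]] <- seq_len(m)
  }
  q <- cpp_pair_agreement(pos)
  dimnames(q) <- list(sample$markers, sample$markers)
  class(q) <- c("rh_pair_agreement", class(q))
  attr(q, "n_samples") <- nrow(sample$orders)
  q
}

#' Extract a robust map from an order sample
#'
#' Greedy elimination in the spirit of framework-map construction: while
#' any retained marker pair is ordered with posterior support below
#' `eta`, remove the marker involved in the most weakly-supported pairs
#' (ties broken by the lower summed two-point LOD to its current
#' neighbours when `calls` is supplied, then by marker name). The
#' consensus order of the retained markers is their Copeland ranking
#' (number of pairs won with `q >= 0.5`); on output every retained pair
#' satisfies `max(q_ij, q_ji) >= eta`, which is re-checked and recorded
#' as a certificate.
#'
#' @param sample An [mcmc_orders()] result.
#' @param eta Required posterior support per pair, in (0.5, 1].
#' @param calls Optional calls tibble used to fit centiRay positions of
#'   the consensus order per panel (and to break elimination ties).
#' @return A list of class `rh_robust_map`: `map` (tibble `marker`,
#'   `order_index`, and `pos_cr_<panel>` columns when `calls` is given),
#'   `removed` (tibble `marker`, `n_weak_pairs`), `eta`, `certified`.
#' @export
extract_robust <- function(sample, eta = 0.95, calls = NULL) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0.5 || eta > 1) {
    abort("`eta` must lie in (0.5, 1].")
  }
  q <- pair_agreement(sample)
  markers <- sample$markers
  alive <- rep(TRUE, length(markers))
  removed <- list()

  # support of a pair = max(q_ij, q_ji); weak pairs fall below eta
  support <- pmax(q, t(q))
  diag(support) <- 1

  neighbour_lod <- function(mk) {
    if (is.null(calls)) return(NA_real_)
    idx_alive <- which(alive)
    wins <- rowSums(q[idx_alive, idx_alive, drop = FALSE] >= 0.5,
                    na.rm = TRUE)
    cons <- markers[idx_alive][order(-wins)]
    i <- match(mk, cons)
    nb <- cons[c(i - 1, i + 1)]
    nb <- nb[!is.na(nb)]
    sum(vapply(nb, function(nm) {
      out <- tryCatch(
        sum(purrr::map_dbl(unique(calls$panel), function(p) {
          tp <- tryCatch(two_point(calls, c(mk, nm), panel = p),
                         error = function(e) NULL)
          if (is.null(tp)) 0 else tp$lod
        })),
        error = function(e) 0
      )
      out
    }, numeric(1)))
  }

  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    sub <- support[idx, idx, drop = FALSE]
    weak <- sub < eta
    if (!any(weak)) break
    n_weak <- rowSums(weak)
    worst <- which(n_weak == max(n_weak))
    if (length(worst) > 1L && !is.null(calls)) {
      lods <- vapply(markers[idx[worst]], neighbour_lod, numeric(1))
      worst <- worst[order(lods, markers[idx[worst]])][1]
    } else {
      worst <- worst[order(markers[idx[worst]])][1]
    }
    removed[[length(removed) + 1L]] <- tibble(
      marker = markers[idx[worst]],
      n_weak_pairs = as.integer(n_weak[worst])
    )
    alive[idx[worst]] <- FALSE
  }

  idx <- which(alive)
  copeland <- rowSums(q[idx, idx, drop = FALSE] >= 0.5, na.rm = TRUE)
  # high Copeland score = precedes many = early position
  cons_idx <- idx[order(-copeland, sample$ref_pos[idx])]
  map <- tibble(marker = markers[cons_idx],
                order_index = seq_along(cons_idx))

  certified <- {
    s <- support[cons_idx, cons_idx, drop = FALSE]
    all(s[upper.tri(s)] >= eta)
  }

  if (!is.null(calls) && length(cons_idx) >= 2L) {
    for (p in unique(calls$panel)) {
      fit <- multipoint_loglik(calls, map$marker, panel = p)
      map[[paste0("pos_cr_", tolower(p))]] <- cumsum(c(0, fit$d_cr))
    }
  }

  structure(
    list(
      map = map,
      removed = if (length(removed)) purrr::list_rbind(removed) else
        tibble(marker = character(), n_weak_pairs = integer()),
      eta = eta, certified = certified,
      n_input = length(markers)
    ),
    class = "rh_robust_map"
  )
}

#' @export
tidy.rh_robust_map <- function(x, ...) x$map

#' @export
glance.rh_robust_map <- function(x, ...) {
  tibble(n_input = x$n_input, n_retained = nrow(x$map),
         n_removed = nrow(x$removed), eta = x$eta, certified = x$certified)
}

#' @export
print.rh_robust_map <- function(x, ...) {
  cat(sprintf(
    "<rh_robust_map> %d/%d markers retained at eta = %.2f (certified: %s)\n",
    nrow(x$map), x$n_input, x$eta, x$certified))
  invisible(x)
}
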