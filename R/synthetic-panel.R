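#' Simulate a radiation hybrid panel
#'
#' Simulates the haploid breakage-retention process for every clone of a
#' panel: chromosome breaks arrive as an exact Poisson process along the
#' chromosome (rate 1 break per 100 centiRays, i.e. exponential inter-break
#' distances in cR), each resulting fragment is independently retained with
#' probability `retention`, and a marker is present in a clone when the
#' fragment carrying it was retained. Observation noise (miscalls, missing
#' calls) is applied on top of the true retention states.
#'
#' The exact fragment process (rather than per-interval coin flips) means
#' the multipoint hidden-Markov likelihood used for mapping is correctly
#' specified for these data, so parameter recovery is a fair test.
#'
#' @param genome An `rh_genome` tibble (see [simulate_genome()]).
#' @param config An [panel_config()] object.
#' @param panel Panel identifier stored in the output (e.g. `"RH1"`).
#' @param keep_fragments Build the per-clone fragment table (set to `FALSE`
#'   for very large panels where only the calls are needed; the `breaks`
#'   table is always kept).
#' @param seed Optional integer seed; same seed, same output.
#'
#' @return A list of class `rh_panel_sim` with elements
#'   * `calls`: long tibble `marker`, `panel`, `clone`, `call` (1/0/NA),
#'   * `true_calls`: same layout, error-free retention states,
#'   * `breaks`: tibble `clone`, `chrom`, `pos_cr` of every break,
#'   * `fragments`: tibble `clone`, `chrom`, `fragment`, `start_cr`,
#'     `end_cr`, `retained` — sufficient to recompute every clone's
#'     retained fragments,
#'   * `config`, `genome`, `panel`, `seed`.
#' @export
#' @examples
#' g <- simulate_genome(n_chromosomes = 1, chrom_kb = 2000, n_markers = 10)
#' sim <- simulate_rh_panel(g, panel_config(n_clones = 30), seed = 1)
#' dplyr::count(sim$calls, call)
simulate_rh_panel <- function(genome, config = panel_config(),
                              panel = "RH1", keep_fragments = TRUE,
                              seed = NULL) {
  if (!inherits(config, "rh_panel_config")) {
    abort("`config` must be created with panel_config().")
  }
  assert_columns(genome, c("marker", "chrom", "pos_kb"), "`genome`")
  if (nrow(genome) == 0L) abort("`genome` has no markers.")
  n <- config$n_clones
  r <- config$retention
  clones <- sprintf("%s_c%03d", panel, seq_len(n))
  lens_kb <- genome_lengths(genome)

  res <- with_seed_(seed, {
    purrr::map(unique(genome$chrom), function(ch) {
      gm <- genome[genome$chrom == ch, , drop = FALSE]
      gm <- gm[order(gm$pos_kb), , drop = FALSE]
      m <- nrow(gm)
      len_cr <- if (is.infinite(config$kb_per_cr)) 0 else
        lens_kb[[ch]] / config$kb_per_cr
      pos_cr <- if (is.infinite(config$kb_per_cr)) rep(0, m) else
        gm$pos_kb / config$kb_per_cr

      k_breaks <- rpois(n, len_cr / 100)
      total_breaks <- sum(k_breaks)
      clone_of_break <- rep.int(seq_len(n), k_breaks)
      break_pos <- runif(total_breaks, 0, len_cr)

      # fragment index of each marker in each clone = 1 + breaks before it
      frag_idx <- matrix(1L, nrow = n, ncol = m)
      if (total_breaks > 0) {
        split_pos <- split(break_pos, factor(clone_of_break, levels = seq_len(n)))
        counts <- vapply(split_pos, function(p) {
          findInterval(pos_cr, sort(p))
        }, integer(m))
        # counts is m x n (or a vector when m == 1)
        frag_idx <- frag_idx + t(matrix(counts, nrow = m))
      }

      n_frags <- k_breaks + 1L
      retained_flat <- rbinom(n + total_breaks, 1L, r)
      offsets <- cumsum(c(0L, n_frags))[seq_len(n)]
      state <- matrix(
        retained_flat[rep(offsets, m) + as.vector(frag_idx)],
        nrow = n, ncol = m
      )

      obs <- state
      if (config$miscall_rate > 0) {
        flip <- matrix(runif(n * m) < config$miscall_rate, n, m)
        obs[flip] <- 1L - obs[flip]
      }
      if (config$missing_rate > 0) {
        miss <- matrix(runif(n * m) < config$missing_rate, n, m)
        obs[miss] <- NA_integer_
      }

      frag_tbl <- if (!keep_fragments) NULL else {
        bounds <- split(break_pos, factor(clone_of_break, levels = seq_len(n)))
        purrr::map(seq_len(n), function(ci) {
          b <- sort(bounds[[ci]])
          tibble(
            clone = clones[ci], chrom = ch,
            fragment = seq_len(n_frags[ci]),
            start_cr = c(0, b), end_cr = c(b, len_cr),
            retained = retained_flat[offsets[ci] + seq_len(n_frags[ci])] == 1L
          )
        }) |> purrr::list_rbind()
      }

      list(
        calls = tibble(
          marker = rep(gm$marker, each = n),
          panel = panel,
          clone = rep(clones, m),
          call = as.integer(obs)
        ),
        true_calls = tibble(
          marker = rep(gm$marker, each = n),
          panel = panel,
          clone = rep(clones, m),
          call = as.integer(state)
        ),
        breaks = tibble(clone = clones[clone_of_break], chrom = ch,
                        pos_cr = break_pos),
        fragments = frag_tbl
      )
    })
  })

  structure(
    list(
      calls = purrr::list_rbind(purrr::map(res, "calls")),
      true_calls = purrr::list_rbind(purrr::map(res, "true_calls")),
      breaks = purrr::list_rbind(purrr::map(res, "breaks")),
      fragments = purrr::list_rbind(purrr::compact(purrr::map(res, "fragments"))),
      config = config, genome = genome, panel = panel, seed = seed
    ),
    class = "rh_panel_sim"
  )
}

#' @export
tidy.rh_panel_sim <- function(x, ...) x$calls

#' @export
print.rh_panel_sim <- function(x, ...) {
  cat(sprintf(
    "<rh_panel_sim> panel %s: %d markers x %d clones (kb/cR = %s, r = %.2f)\n",
    x$panel, length(unique(x$calls$marker)), x$config$n_clones,
    format(x$config$kb_per_cr), x$config$retention
  ))
  invisible(x)
}
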