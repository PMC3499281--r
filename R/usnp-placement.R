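# 2x2 presence/absence chi-square scores between two sets of RH vectors.
# Returns a list of matrices (n_u x n_m): score, chi2, n11, n, flag.
score_matrices <- function(mat_u, mat_m, min_overlap = 10,
                           method = c("table", "match")) {
  method <- match.arg(method)
  ou <- !is.na(mat_u); om <- !is.na(mat_m)
  u1 <- mat_u == 1L; u1[!ou] <- FALSE
  u0 <- mat_u == 0L; u0[!ou] <- FALSE
  m1 <- mat_m == 1L; m1[!om] <- FALSE
  m0 <- mat_m == 0L; m0[!om] <- FALSE
  mode(u1) <- "numeric"; mode(u0) <- "numeric"
  mode(m1) <- "numeric"; mode(m0) <- "numeric"
  n11 <- crossprod(u1, m1)
  n10 <- crossprod(u1, m0)
  n01 <- crossprod(u0, m1)
  n00 <- crossprod(u0, m0)
  n <- n11 + n10 + n01 + n00
  r1 <- n11 + n10  # u present margin
  c1 <- n11 + n01  # m present margin
  e11 <- r1 * c1 / pmax(n, 1)
  if (method == "table") {
    den <- r1 * (n - r1) * c1 * (n - c1)
    chi2 <- ifelse(den > 0, n * (n11 * n00 - n10 * n01)^2 / den, 0)
  } else {
    # single-cell test on the (present, present) count
    v <- e11 * (1 - (r1 / pmax(n, 1)) * (c1 / pmax(n, 1)))
    chi2 <- ifelse(v > 0, (n11 - e11)^2 / v, 0)
  }
  degenerate <- (r1 == 0) | (r1 == n) | (c1 == 0) | (c1 == n)
  score <- -pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  # one-sided: only positive co-retention counts as evidence of proximity
  score[n11 < e11] <- 0
  score[degenerate] <- 0
  score[n < min_overlap] <- 0
  list(score = score, chi2 = chi2, n11 = n11, n = n,
       degenerate = degenerate)
}

#' Chi-square similarity score between two RH vectors
#'
#' Over the jointly non-missing clones, counts the number of clones
#' showing the presence of both SNPs and derives the 1-df chi-square
#' statistic (no continuity correction) of the 2x2 presence/absence table
#' against independence; the score is `-log10(p)`. The score is one-sided:
#' pairs whose observed co-presence falls below its expectation score 0
#' (only positive co-retention is evidence of physical proximity), and
#' degenerate tables (a marker all-present or all-absent) score 0 with a
#' flag. `method = "match"` instead tests the single (present, present)
#' cell against its binomial expectation.
#'
#' @param calls Long calls tibble.
#' @param usnp,msnp Marker ids of the pair (unmapped / mapped SNP).
#' @param panel Optional panel restriction.
#' @param min_overlap Minimum jointly observed clones (default 10).
#' @param method `"table"` (full 2x2, default) or `"match"`.
#' @return One-row tibble `usnp`, `msnp`, `n11`, `n`, `chi2`, `score`,
#'   `degenerate`.
#' @export
similarity_score <- function(calls, usnp, msnp, panel = NULL,
                             min_overlap = 10,
                             method = c("table", "match")) {
  method <- match.arg(method)
  mat <- calls_matrix(calls, c(usnp, msnp), panel)
  ok <- !is.na(mat[, 1]) & !is.na(mat[, 2])
  if (sum(ok) < min_overlap) {
    abort(sprintf("Markers %s and %s share only %d observed clones (< %d).",
                  usnp, msnp, sum(ok), min_overlap))
  }
  sm <- score_matrices(mat[, 1, drop = FALSE], mat[, 2, drop = FALSE],
                       min_overlap, method)
  tibble(usnp = usnp, msnp = msnp,
         n11 = as.integer(sm$n11[1, 1]), n = as.integer(sm$n[1, 1]),
         chi2 = sm$chi2[1, 1], score = sm$score[1, 1],
         degenerate = sm$degenerate[1, 1])
}

#' Empirical null distribution of cross-chromosome similarity scores
#'
#' Samples a mapped SNP, computes its maximum similarity score against
#' the mapped SNPs of a different chromosome, and repeats; the resulting
#' maxima calibrate the score threshold above which a chromosome
#' assignment is considered genuine.
#'
#' @param calls Long calls tibble of mapped SNPs.
#' @param assignments Tibble `marker`, `chrom` giving each mapped SNP's
#'   chromosome.
#' @param panel Optional panel restriction.
#' @param n_rep Number of resamples (default 1000).
#' @param min_overlap Minimum jointly observed clones per pair.
#' @param seed Optional integer seed.
#' @return A list of class `rh_empirical_null`: `maxima` (length
#'   `n_rep`), `quantiles` tibble, `seed`.
#' @export
empirical_null <- function(calls, assignments, panel = NULL, n_rep = 1000,
                           min_overlap = 10, seed = NULL) {
  assert_columns(assignments, c("marker", "chrom"), "`assignments`")
  n_rep <- assert_count(n_rep, "n_rep", min = 1L)
  chroms <- unique(assignments$chrom)
  if (length(chroms) < 2L) {
    abort("empirical_null needs mapped SNPs on at least 2 chromosomes.")
  }
  mat <- calls_matrix(calls, panel = panel)
  mat <- mat[, colnames(mat) %in% assignments$marker, drop = FALSE]
  chrom_of <- setNames(assignments$chrom, assignments$marker)

  maxima <- with_seed_(seed, {
    src <- sample(colnames(mat), n_rep, replace = TRUE)
    tgt <- vapply(src, function(mk) {
      sample(setdiff(chroms, chrom_of[[mk]]), 1L)
    }, character(1))
    out <- numeric(n_rep)
    for (ch in unique(tgt)) {
      reps <- which(tgt == ch)
      cols_t <- colnames(mat)[chrom_of[colnames(mat)] == ch]
      sm <- score_matrices(mat[, src[reps], drop = FALSE],
                           mat[, cols_t, drop = FALSE], min_overlap)
      out[reps] <- apply(sm$score, 1, max)
    }
    out
  })

  structure(
    list(
      maxima = maxima,
      quantiles = tibble(
        prob = c(0.5, 0.9, 0.95, 0.99),
        value = unname(quantile(maxima, c(0.5, 0.9, 0.95, 0.99)))
      ),
      n_rep = n_rep, seed = seed
    ),
    class = "rh_empirical_null"
  )
}

#' @export
tidy.rh_empirical_null <- function(x, ...) x$quantiles

#' @export
print.rh_empirical_null <- function(x, ...) {
  cat(sprintf("<rh_empirical_null> %d resampled cross-chromosome maxima\n",
              x$n_rep))
  print(x$quantiles)
  invisible(x)
}

#' Assign unmapped SNPs to chromosomes
#'
#' Computes each uSNP's maximum similarity score per chromosome (against
#' the mapped SNPs, on the lower-resolution panel in the two-panel
#' design) and assigns the uSNP when exactly one chromosome reaches the
#' threshold; otherwise it is left unassigned with the reason (`none` or
#' `multiple`). A threshold of 5 is supported by the empirical null but
#' allows multiple assignments; 7 yields unique assignments.
#'
#' @param usnp_calls Long calls tibble of the unmapped SNPs.
#' @param mapped_calls Long calls tibble of the mapped SNPs.
#' @param assignments Tibble `marker`, `chrom` for the mapped SNPs.
#' @param panel Panel used for the chromosome assignment.
#' @param threshold Assignment score threshold (default 7).
#' @param min_overlap Minimum jointly observed clones per pair.
#' @return Tibble `usnp`, `chrom` (NA if unassigned), `reason`
#'   (`assigned` / `none` / `multiple`), `best_score`, `best_chrom`,
#'   `second_chrom_score`.
#' @export
assign_chromosome <- function(usnp_calls, mapped_calls, assignments,
                              panel = NULL, threshold = 7,
                              min_overlap = 10) {
  assert_columns(assignments, c("marker", "chrom"), "`assignments`")
  mat_u <- calls_matrix(usnp_calls, panel = panel)
  mat_m <- calls_matrix(mapped_calls, panel = panel)
  common <- intersect(rownames(mat_u), rownames(mat_m))
  mat_u <- mat_u[common, , drop = FALSE]
  mat_m <- mat_m[common, , drop = FALSE]
  mat_m <- mat_m[, colnames(mat_m) %in% assignments$marker, drop = FALSE]
  chrom_of <- setNames(assignments$chrom, assignments$marker)[colnames(mat_m)]

  sm <- score_matrices(mat_u, mat_m, min_overlap)
  chroms <- unique(chrom_of)
  per_chrom <- vapply(chroms, function(ch) {
    apply(sm$score[, chrom_of == ch, drop = FALSE], 1, max)
  }, numeric(nrow(sm$score)))
  if (is.null(dim(per_chrom))) {
    per_chrom <- matrix(per_chrom, nrow = 1,
                        dimnames = list(colnames(mat_u), chroms))
  }

  purrr::map(seq_len(nrow(per_chrom)), function(i) {
    sc <- per_chrom[i, ]
    above <- which(sc >= threshold)
    best <- which.max(sc)
    tibble(
      usnp = colnames(mat_u)[i],
      chrom = if (length(above) == 1L) chroms[above] else NA_character_,
      reason = if (length(above) == 1L) "assigned" else
        if (length(above) == 0L) "none" else "multiple",
      best_chrom = chroms[best],
      best_score = sc[best],
      second_chrom_score = if (length(sc) > 1L)
        max(sc[-best]) else NA_real_
    )
  }) |> purrr::list_rbind()
}

#' Predict the RH-map position of an assigned uSNP
#'
#' On the higher-resolution panel, identifies the two highest-scoring
#' mapped SNPs of the assigned chromosome as flanking neighbours and
#' predicts the uSNP's RH position as their score-weighted barycenter
#' `(S1 p1 + S2 p2) / (S1 + S2)` — the weighting pulls the prediction
#' toward the best-matching neighbour.
#'
#' @param usnp_calls,mapped_calls Long calls tibbles.
#' @param map An `rh_map`-like tibble with `marker` and the position
#'   column named in `pos_col`.
#' @param chrom_assign Tibble `usnp`, `chrom` from [assign_chromosome()]
#'   (rows with NA chromosome are passed through unplaced).
#' @param map_chrom Tibble `marker`, `chrom` giving mapped SNPs'
#'   chromosomes.
#' @param panel Panel used for position prediction.
#' @param pos_col Name of the position column in `map`.
#' @param min_overlap Minimum jointly observed clones per pair.
#' @return Tibble `usnp`, `chrom`, `rh_position`, `best_score`,
#'   `second_score`, `best_msnp`, `second_msnp`, `status`
#'   (`placed` / `chromosome_only` / `unassigned`).
#' @export
predict_position <- function(usnp_calls, mapped_calls, map, chrom_assign,
                             map_chrom, panel = NULL,
                             pos_col = "pos_cr_rh2", min_overlap = 10) {
  assert_columns(map, c("marker", pos_col), "`map`")
  assert_columns(chrom_assign, c("usnp", "chrom"), "`chrom_assign`")
  assert_columns(map_chrom, c("marker", "chrom"), "`map_chrom`")
  mat_u <- calls_matrix(usnp_calls, panel = panel)
  mat_m <- calls_matrix(mapped_calls, panel = panel)
  common <- intersect(rownames(mat_u), rownames(mat_m))
  mat_u <- mat_u[common, , drop = FALSE]
  mat_m <- mat_m[common, colnames(mat_m) %in% map$marker, drop = FALSE]
  pos_of <- setNames(map[[pos_col]], map$marker)
  chrom_of <- setNames(map_chrom$chrom, map_chrom$marker)

  sm <- score_matrices(mat_u, mat_m, min_overlap)

  purrr::map(seq_len(nrow(chrom_assign)), function(i) {
    u <- chrom_assign$usnp[i]
    ch <- chrom_assign$chrom[i]
    base <- tibble(usnp = u, chrom = ch, rh_position = NA_real_,
                   best_score = NA_real_, second_score = NA_real_,
                   best_msnp = NA_character_, second_msnp = NA_character_,
                   status = "unassigned")
    if (is.na(ch)) return(base)
    cols <- which(chrom_of[colnames(mat_m)] == ch)
    sc <- sm$score[match(u, colnames(mat_u)), cols]
    names(sc) <- colnames(mat_m)[cols]
    sc <- sc[sc > 0]
    if (length(sc) < 2L) {
      base$status <- "chromosome_only"
      if (length(sc) == 1L) {
        base$best_score <- unname(sc)
        base$best_msnp <- names(sc)
      }
      return(base)
    }
    top <- names(sort(sc, decreasing = TRUE))[1:2]
    s1 <- sc[[top[1]]]; s2 <- sc[[top[2]]]
    p1 <- pos_of[[top[1]]]; p2 <- pos_of[[top[2]]]
    base$rh_position <- (s1 * p1 + s2 * p2) / (s1 + s2)
    base$best_score <- s1; base$second_score <- s2
    base$best_msnp <- top[1]; base$second_msnp <- top[2]
    base$status <- "placed"
    base
  }) |> purrr::list_rbind()
}

# longest increasing subsequence (indices) of y
lis_indices <- function(y) {
  n <- length(y)
  if (n == 0L) return(integer(0))
  tails <- integer(0)   # indices ending the best subsequence of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    vals <- y[tails]
    k <- findInterval(y[i], vals) # number of tail values <= y[i]
    # strict increase: step back over ties
    while (k >= 1L && y[tails[k]] >= y[i]) k <- k - 1L
    prev[i] <- if (k >= 1L) tails[k] else 0L
    if (k + 1L > length(tails)) tails <- c(tails, i) else tails[k + 1L] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(out))) { out[j] <- k; k <- prev[k] }
  out
}

#' Fit a monotone map-position to assembly-position spline
#'
#' Fits, per chromosome, a monotone piecewise-cubic interpolant of the
#' assembly position (bp) on the RH map position (cR) through the mapped
#' SNPs, after reducing the point set to a maximal increasing subsequence
#' (a non-monotone fit would locally invert coordinates). Predictions are
#' clamped to `[1, chrom_length]`; positions outside the fitted cR range
#' are extrapolated with the terminal slope and flagged.
#'
#' @param map Tibble with `marker`, `chrom`, the cR position column
#'   `pos_col` and assembly positions `ref_bp`.
#' @param pos_col Name of the cR position column.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp
#'   (defaults to the largest mapped `ref_bp` per chromosome).
#' @param min_points Minimum mapped SNPs per chromosome (default 10).
#' @return A list of class `rh_assembly_spline` of per-chromosome
#'   prediction functions; use [map_to_assembly()] to predict.
#' @export
fit_assembly_spline <- function(map, pos_col = "pos_cr_rh2",
                                chrom_lengths = NULL, min_points = 10) {
  assert_columns(map, c("marker", "chrom", pos_col, "ref_bp"), "`map`")
  chroms <- unique(map$chrom)
  fits <- lapply(chroms, function(ch) {
    d <- map[map$chrom == ch & !is.na(map$ref_bp), , drop = FALSE]
    d <- d[order(d[[pos_col]]), , drop = FALSE]
    if (nrow(d) < min_points) {
      abort(sprintf(
        "Chromosome %s has only %d mapped SNPs with bp positions (< %d).",
        ch, nrow(d), min_points))
    }
    keep <- lis_indices(d$ref_bp)
    x <- d[[pos_col]][keep]
    y <- d$ref_bp[keep]
    dedup <- !duplicated(x)
    x <- x[dedup]; y <- y[dedup]
    f <- splinefun(x, y, method = "hyman")
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(y)
    list(f = f, range = range(x), length = len,
         slope_lo = (f(x[2]) - f(x[1])) / (x[2] - x[1]),
         slope_hi = (f(x[length(x)]) - f(x[length(x) - 1])) /
           (x[length(x)] - x[length(x) - 1]),
         lo = x[1], hi = x[length(x)])
  })
  names(fits) <- chroms
  structure(fits, class = "rh_assembly_spline")
}

#' Project RH positions onto assembly coordinates
#'
#' @param spline An [fit_assembly_spline()] result.
#' @param chrom Chromosome of each position.
#' @param rh_position RH map positions (cR), vectorized.
#' @return Tibble `chrom`, `rh_position`, `bp_position` (1-based, clamped
#'   to the chromosome), `extrapolated`.
#' @export
map_to_assembly <- function(spline, chrom, rh_position) {
  if (!inherits(spline, "rh_assembly_spline")) {
    abort("`spline` must come from fit_assembly_spline().")
  }
  n <- max(length(chrom), length(rh_position))
  chrom <- rep_len(chrom, n); rh_position <- rep_len(rh_position, n)
  bp <- rep(NA_real_, n); extra <- rep(FALSE, n)
  for (ch in unique(chrom[!is.na(chrom)])) {
    s <- spline[[ch]]
    if (is.null(s)) abort(sprintf("No spline fitted for chromosome %s.", ch))
    i <- which(chrom == ch & !is.na(rh_position))
    p <- rh_position[i]
    v <- s$f(pmin(pmax(p, s$lo), s$hi))
    below <- p < s$lo; above <- p > s$hi
    v[below] <- s$f(s$lo) + (p[below] - s$lo) * s$slope_lo
    v[above] <- s$f(s$hi) + (p[above] - s$hi) * s$slope_hi
    extra[i] <- below | above
    bp[i] <- pmin(pmax(round(v), 1), s$length)
  }
  tibble(chrom = chrom, rh_position = rh_position, bp_position = bp,
         extrapolated = extra)
}

#' Place unmapped SNPs end to end
#'
#' Convenience wrapper running the full placement procedure: chromosome
#' assignment on the lower-resolution panel, position prediction by
#' score-weighted barycenter on the higher-resolution panel, and
#' projection to assembly coordinates through the monotone spline.
#'
#' @param usnp_calls,mapped_calls Long calls tibbles (both panels).
#' @param map Map tibble with `marker`, `chrom`, per-panel `pos_cr_*`
#'   columns and `ref_bp`.
#' @param low_panel,high_panel Panel ids used for assignment and for
#'   position prediction.
#' @param pos_col cR position column of `map` used for prediction.
#' @param threshold Assignment threshold (default 7).
#' @param chrom_lengths Optional named chromosome lengths (bp).
#' @param min_overlap Minimum jointly observed clones per pair.
#' @param spline_min_points Minimum mapped SNPs per chromosome for the
#'   cR-to-bp spline.
#' @return A tibble of class `rh_placements`.
#' @export
place_usnps <- function(usnp_calls, mapped_calls, map,
                        low_panel = "RH1", high_panel = "RH2",
                        pos_col = "pos_cr_rh2", threshold = 7,
                        chrom_lengths = NULL, min_overlap = 10,
                        spline_min_points = 10) {
  assert_columns(map, c("marker", "chrom", pos_col, "ref_bp"), "`map`")
  map_chrom <- map[, c("marker", "chrom")]
  assign <- assign_chromosome(usnp_calls, mapped_calls, map_chrom,
                              panel = low_panel, threshold = threshold,
                              min_overlap = min_overlap)
  pred <- predict_position(usnp_calls, mapped_calls, map,
                           assign[, c("usnp", "chrom")], map_chrom,
                           panel = high_panel, pos_col = pos_col,
                           min_overlap = min_overlap)
  spl <- fit_assembly_spline(map, pos_col = pos_col,
                             chrom_lengths = chrom_lengths,
                             min_points = spline_min_points)
  proj <- map_to_assembly(spl, pred$chrom, pred$rh_position)
  out <- pred |>
    mutate(bp_position = proj$bp_position,
           extrapolated = proj$extrapolated,
           assign_reason = assign$reason[match(.data$usnp, assign$usnp)])
  class(out) <- c("rh_placements", class(out))
  out
}

#' Anchor unplaced scaffolds through their placed SNPs
#'
#' Aggregates SNP placements per scaffold: when the supporting SNPs
#' disagree on the chromosome, minority SNPs are dropped if a strict
#' majority exists (otherwise the scaffold is unresolved); the scaffold
#' position is the interval spanned by the surviving predictions. Each
#' scaffold is then cross-validated against a comparative-homology table
#' and classified: `discordant` (homology points to a different
#' chromosome), `noinfo` (no homology entry: not alignable to the
#' reference organism), `nosynt` (aligned but no homologous region on
#' this genome), `valid` (same chromosome, homology and RH positions
#' within 1 Mb) or `sscvalid` (same chromosome, further apart).
#'
#' @param placements An [place_usnps()] result (or tibble with `usnp`,
#'   `chrom`, `bp_position`, `status`).
#' @param snp_scaffolds Tibble `marker`, `scaffold` linking SNPs to their
#'   scaffold.
#' @param homology Tibble `scaffold`, `homolog_chrom` (NA when the
#'   aligned region has no identified homologous region), `homolog_bp`;
#'   scaffolds absent from the table are `noinfo`.
#' @param max_valid_dist Distance (bp) separating `valid` from
#'   `sscvalid` (default 1 Mb).
#' @return A tibble of class `rh_scaffold_placements`: `scaffold`,
#'   `chrom`, `bp_start`, `bp_end`, `n_snps`, `n_dropped`, `category`,
#'   `resolved`.
#' @export
anchor_scaffolds <- function(placements, snp_scaffolds, homology,
                             max_valid_dist = 1e6) {
  assert_columns(placements, c("usnp", "chrom", "bp_position", "status"),
                 "`placements`")
  assert_columns(snp_scaffolds, c("marker", "scaffold"), "`snp_scaffolds`")
  assert_columns(homology, c("scaffold", "homolog_chrom", "homolog_bp"),
                 "`homology`")
  placed <- placements |>
    filter(.data$status == "placed", !is.na(.data$bp_position)) |>
    inner_join(snp_scaffolds, by = c(usnp = "marker"))

  out <- placed |>
    group_by(.data$scaffold) |>
    dplyr::group_map(function(d, key) {
      tab <- sort(table(d$chrom), decreasing = TRUE)
      resolved <- length(tab) == 1L ||
        tab[1] > sum(tab) - tab[1]  # strict majority
      if (!resolved) {
        return(tibble(scaffold = key$scaffold, chrom = NA_character_,
                      bp_start = NA_real_, bp_end = NA_real_,
                      n_snps = nrow(d), n_dropped = 0L,
                      resolved = FALSE))
      }
      ch <- names(tab)[1]
      keep <- d[d$chrom == ch, , drop = FALSE]
      tibble(scaffold = key$scaffold, chrom = ch,
             bp_start = min(keep$bp_position),
             bp_end = max(keep$bp_position),
             n_snps = nrow(keep),
             n_dropped = nrow(d) - nrow(keep),
             resolved = TRUE)
    }) |> purrr::list_rbind()

  if (nrow(out) == 0L) {
    out <- tibble(scaffold = character(), chrom = character(),
                  bp_start = numeric(), bp_end = numeric(),
                  n_snps = integer(), n_dropped = integer(),
                  resolved = logical())
  }

  out <- out |>
    left_join(homology, by = "scaffold") |>
    mutate(
      in_homology = .data$scaffold %in% homology$scaffold,
      category = dplyr::case_when(
        !.data$resolved ~ "unresolved",
        !.data$in_homology ~ "noinfo",
        is.na(.data$homolog_chrom) ~ "nosynt",
        .data$homolog_chrom != .data$chrom ~ "discordant",
        abs((.data$bp_start + .data$bp_end) / 2 - .data$homolog_bp) <
          max_valid_dist ~ "valid",
        TRUE ~ "sscvalid"
      )
    ) |>
    select(-"in_homology")
  class(out) <- c("rh_scaffold_placements", class(out))
  out
}

#' Summarise scaffold-placement categories
#'
#' Computes, per validation category, the scaffold counts, sequence
#' lengths and uSNP counts together with their proportions of the
#' overall totals, plus the aggregate `tentative` row (every
#' non-discordant category). Accepts either an [anchor_scaffolds()]
#' result joined to scaffold lengths, or a pre-tabulated per-category
#' tibble with columns `category`, `n_scaffolds` and optionally
#' `length_mb`, `n_usnps`.
#'
#' @param x Scaffold placements or per-category counts.
#' @param scaffold_lengths Optional tibble `scaffold`, `length_bp` used
#'   when `x` is a placement table.
#' @return Tibble `category`, `n_scaffolds`, `pct_scaffolds`, and when
#'   available `length_mb`, `pct_length`, `n_usnps`; proportions are
#'   percentages of the grand totals, with `tentative` aggregating the
#'   non-discordant categories.
#' @export
placement_category_summary <- function(x, scaffold_lengths = NULL) {
  if (!"category" %in% names(x)) abort("`x` needs a `category` column.")
  if (!"n_scaffolds" %in% names(x)) {
    if (!is.null(scaffold_lengths)) {
      x <- x |> left_join(scaffold_lengths, by = "scaffold")
    }
    x <- x |>
      filter(.data$category != "unresolved") |>
      group_by(.data$category) |>
      summarise(
        n_scaffolds = dplyr::n(),
        length_mb = if ("length_bp" %in% names(x))
          sum(.data$length_bp) / 1e6 else NA_real_,
        n_usnps = sum(.data$n_snps),
        .groups = "drop"
      )
  }
  x <- as_tibble(x)
  sub <- c("noinfo", "nosynt", "sscvalid", "valid")
  tentative <- x |>
    filter(.data$category %in% sub) |>
    summarise(category = "tentative",
              across(dplyr::any_of(c("n_scaffolds", "length_mb", "n_usnps")),
                     sum))
  all_rows <- bind_rows(x |> filter(.data$category == "discordant"),
                        tentative,
                        x |> filter(.data$category %in% sub))
  tot_n <- sum(x$n_scaffolds)
  out <- all_rows |>
    mutate(pct_scaffolds = 100 * .data$n_scaffolds / tot_n)
  if ("length_mb" %in% names(x) && !all(is.na(x$length_mb))) {
    tot_l <- sum(x$length_mb)
    out$pct_length <- 100 * out$length_mb / tot_l
  }
  out
}
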