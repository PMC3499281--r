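#' Simulate a marker genome for RH mapping experiments
#'
#' Generates chromosomes with SNP markers at known physical positions.
#' The marker table is the ground truth against which maps built from
#' simulated RH data can be checked.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_kb Chromosome length(s) in kilobases, recycled across
#'   chromosomes.
#' @param n_markers Number of markers per chromosome, recycled.
#' @param spacing `"even"` places markers on a regular grid; `"uniform"`
#'   draws positions uniformly at random (sorted, distinct).
#' @param seed Optional integer seed; the generator is reproducible.
#'
#' @return A tibble of class `rh_genome` with columns `marker`, `chrom`,
#'   `pos_kb`, and an attribute `chrom_kb` (named chromosome lengths).
#' @export
#' @examples
#' g <- simulate_genome(n_chromosomes = 2, chrom_kb = 5000, n_markers = 20)
#' head(g)
simulate_genome <- function(n_chromosomes = 1, chrom_kb = 20000,
                            n_markers = 100,
                            spacing = c("even", "uniform"), seed = NULL) {
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", min = 1L)
  spacing <- match.arg(spacing)
  chrom_kb <- rep_len(chrom_kb, n_chromosomes)
  n_markers <- rep_len(n_markers, n_chromosomes)
  if (any(chrom_kb <= 0)) abort("`chrom_kb` must be positive.")
  if (any(n_markers < 1)) abort("`n_markers` must be >= 1.")
  chroms <- paste0("chr", seq_len(n_chromosomes))

  markers <- with_seed_(seed, {
    purrr::map2(seq_len(n_chromosomes), n_markers, function(ci, nm) {
      pos <- switch(spacing,
        even = chrom_kb[ci] * seq_len(nm) / (nm + 1),
        uniform = {
          p <- sort(runif(nm, min = 1, max = chrom_kb[ci] - 1))
          while (anyDuplicated(p) > 0) {
            p <- sort(jitter(p, amount = 0.5))
          }
          pmin(pmax(p, 0.5), chrom_kb[ci] - 0.5)
        }
      )
      tibble(
        marker = sprintf("%s_M%04d", chroms[ci], seq_len(nm)),
        chrom = chroms[ci],
        pos_kb = pos
      )
    }) |> purrr::list_rbind()
  })

  attr(markers, "chrom_kb") <- setNames(chrom_kb, chroms)
  class(markers) <- c("rh_genome", class(markers))
  markers
}

#' Chromosome lengths of a (possibly simulated) genome
#'
#' @param genome An `rh_genome` tibble, or any tibble with `chrom` and
#'   `pos_kb` columns (lengths are then taken as the last marker position).
#' @return Named numeric vector of chromosome lengths in Kb.
#' @export
genome_lengths <- function(genome) {
  len <- attr(genome, "chrom_kb")
  if (!is.null(len)) return(len)
  assert_columns(genome, c("chrom", "pos_kb"), "`genome`")
  tapply(genome$pos_kb, genome$chrom, max)[unique(genome$chrom)]
}

#' Configuration of a radiation hybrid panel
#'
#' Holds the parameters of the haploid breakage-retention process: panel
#' size, resolution (Kb per centiRay), per-fragment retention probability
#' and observation error rates. One centiRay is the distance at which a
#' clone has a 1% chance of carrying at least one break, so breaks arrive
#' as a Poisson process with rate 1 per 100 cR.
#'
#' @param n_clones Number of hybrid clones (>= 1).
#' @param kb_per_cr Resolution parameter in Kb per centiRay (> 0); the two
#'   pig panels were estimated at 8.6 (IMpRH) and 5.3 (IMNpRH2) Kb/cR.
#' @param retention Probability `r` that a fragment is retained in a clone,
#'   strictly between 0 and 1 (panel-wide "equal retention" working model).
#' @param miscall_rate Probability a true call is flipped.
#' @param missing_rate Probability a call is reported unknown.
#' @return A list of class `rh_panel_config`.
#' @export
panel_config <- function(n_clones = 90, kb_per_cr = 8.6, retention = 0.30,
                         miscall_rate = 0, missing_rate = 0) {
  n_clones <- assert_count(n_clones, "n_clones", min = 1L)
  if (!is.numeric(kb_per_cr) || length(kb_per_cr) != 1L || is.na(kb_per_cr) ||
      kb_per_cr <= 0) {
    abort("`kb_per_cr` must be a single positive number (Inf allowed).")
  }
  if (!is.numeric(retention) || length(retention) != 1L ||
      !is.finite(retention) || retention <= 0 || retention >= 1) {
    # retention = 1 is admitted as an explicit degenerate case for testing
    if (!identical(retention, 1)) {
      abort("`retention` must be a single probability in (0, 1).")
    }
  }
  assert_prob(miscall_rate, "miscall_rate", open_right = TRUE)
  assert_prob(missing_rate, "missing_rate", open_right = TRUE)
  structure(
    list(n_clones = n_clones, kb_per_cr = kb_per_cr, retention = retention,
         miscall_rate = miscall_rate, missing_rate = missing_rate),
    class = "rh_panel_config"
  )
}

#' Corrupt a marker order the way draft assemblies go wrong
#'
#' Applies the three error classes observed when comparing RH maps to a
#' draft assembly: misplacement of a single marker, relocation of a
#' contiguous segment, and default placement of a segment at the
#' chromosome end. Every edit is logged so detection can be verified.
#'
#' @param true_order Tibble with columns `marker`, `chrom` and a position
#'   column (`pos_kb` or `ref_bp`), sorted in the true order.
#' @param n_single_misplacements,n_segment_relocations,n_end_placements
#'   Number of edits of each class.
#' @param segment_length_range_kb Length range (Kb) of relocated and
#'   end-placed segments.
#' @param seed Optional integer seed.
#' @return A list of class `rh_corrupted_order` with elements `order`
#'   (the corrupted tibble, a permutation of the input) and `edits`
#'   (one row per move).
#' @export
corrupt_assembly_order <- function(true_order, n_single_misplacements = 0,
                                   n_segment_relocations = 0,
                                   segment_length_range_kb = c(300, 1500),
                                   n_end_placements = 0, seed = NULL) {
  assert_columns(true_order, c("marker", "chrom"), "`true_order`")
  n_single_misplacements <- assert_count(n_single_misplacements,
                                         "n_single_misplacements")
  n_segment_relocations <- assert_count(n_segment_relocations,
                                        "n_segment_relocations")
  n_end_placements <- assert_count(n_end_placements, "n_end_placements")
  pos_col <- intersect(c("pos_kb", "ref_bp"), names(true_order))[1]
  if (is.na(pos_col)) abort("`true_order` needs a `pos_kb` or `ref_bp` column.")
  ord <- as_tibble(true_order)

  by_chrom <- split(seq_len(nrow(ord)), ord$chrom)
  # row indices per chromosome, in current order; edits permute these
  perm <- lapply(by_chrom, identity)

  pick_segment <- function(rows, span_kb) {
    pos <- ord[[pos_col]][rows]
    if (pos_col == "ref_bp") span <- span_kb * 1000 else span <- span_kb
    s <- sample.int(length(rows), 1L)
    seg <- which(pos >= pos[s] & pos <= pos[s] + span)
    seg[seg >= s]
  }

  edits <- list()
  log_edit <- function(type, chrom, markers, from, to) {
    edits[[length(edits) + 1L]] <<- tibble(
      type = type, chrom = chrom,
      markers = paste(markers, collapse = ","),
      n_markers = length(markers), from_index = from, to_index = to
    )
  }

  with_seed_(seed, {
    chrom_pool <- names(perm)[vapply(perm, length, 1L) >= 3L]
    if ((n_single_misplacements + n_segment_relocations + n_end_placements) >
        0L && length(chrom_pool) == 0L) {
      abort("No chromosome has enough markers (>= 3) to corrupt.")
    }
    for (i in seq_len(n_single_misplacements)) {
      ch <- sample(chrom_pool, 1L)
      rows <- perm[[ch]]
      i0 <- sample.int(length(rows), 1L)
      j0 <- sample(setdiff(seq_along(rows), i0), 1L)
      moved <- rows[i0]
      rows <- append(rows[-i0], moved, after = j0 - 1L)
      perm[[ch]] <- rows
      log_edit("single_misplacement", ch, ord$marker[moved], i0, j0)
    }
    for (i in seq_len(n_segment_relocations)) {
      ch <- sample(chrom_pool, 1L)
      rows <- perm[[ch]]
      span <- runif(1, segment_length_range_kb[1], segment_length_range_kb[2])
      chrom_span <- diff(range(ord[[pos_col]][rows]))
      if (pos_col == "ref_bp") chrom_span <- chrom_span / 1000
      if (span >= chrom_span) {
        abort("Requested segment span exceeds the chromosome length.")
      }
      seg <- pick_segment(rows, span)
      if (length(seg) >= length(rows)) {
        abort("Relocated segment covers the whole chromosome.")
      }
      rest <- rows[-seg]
      to <- sample.int(length(rest) + 1L, 1L) - 1L
      perm[[ch]] <- append(rest, rows[seg], after = to)
      log_edit("segment_relocation", ch, ord$marker[rows[seg]],
               seg[1], to + 1L)
    }
    for (i in seq_len(n_end_placements)) {
      ch <- sample(chrom_pool, 1L)
      rows <- perm[[ch]]
      span <- runif(1, segment_length_range_kb[1], segment_length_range_kb[2])
      seg <- pick_segment(rows, span)
      if (length(seg) >= length(rows)) {
        abort("End-placed segment covers the whole chromosome.")
      }
      rest <- rows[-seg]
      perm[[ch]] <- c(rest, rows[seg])
      log_edit("end_placement", ch, ord$marker[rows[seg]],
               seg[1], length(rest) + 1L)
    }
    NULL
  })

  out <- ord[unlist(perm, use.names = FALSE), , drop = FALSE]
  out <- out |>
    group_by(.data$chrom) |>
    mutate(corrupt_index = row_number()) |>
    ungroup()
  structure(
    list(
      order = out,
      edits = if (length(edits)) purrr::list_rbind(edits) else
        tibble(type = character(), chrom = character(), markers = character(),
               n_markers = integer(), from_index = integer(),
               to_index = integer())
    ),
    class = "rh_corrupted_order"
  )
}
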