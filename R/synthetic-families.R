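#' Build an evenly spread genetic map over a marker genome
#'
#' Convenience helper giving each chromosome a total genetic length and
#' splitting it over the marker intervals proportionally to physical
#' distance.
#'
#' @param genome An `rh_genome` tibble.
#' @param total_cm Total genetic length per chromosome in centiMorgans,
#'   recycled across chromosomes.
#' @return Tibble `chrom`, `marker` (left marker of the interval), `cm`
#'   (distance to the next marker); the last marker of each chromosome has
#'   `cm = 0`.
#' @export
even_genetic_map <- function(genome, total_cm = 100) {
  assert_columns(genome, c("marker", "chrom", "pos_kb"), "`genome`")
  chroms <- unique(genome$chrom)
  total_cm <- rep_len(total_cm, length(chroms))
  purrr::map2(chroms, total_cm, function(ch, tot) {
    gm <- genome[genome$chrom == ch, , drop = FALSE]
    gm <- gm[order(gm$pos_kb), , drop = FALSE]
    gaps <- diff(gm$pos_kb)
    cm <- if (length(gaps) == 0) numeric(0) else tot * gaps / sum(gaps)
    tibble(chrom = ch, marker = gm$marker, cm = c(cm, 0))
  }) |> purrr::list_rbind()
}

#' Simulate half-sib families for genetic validation of marker orders
#'
#' Each family has one sire and at least two offspring, each offspring from
#' a different (ungenotyped) dam — the family structure in which only
#' paternal meioses are informative. Sire haplotypes are drawn from allele
#' frequencies and kept as internal truth; each offspring receives a
#' paternal gamete carrying Poisson-distributed crossovers with
#' per-interval means `cm/100`, and a maternal allele drawn from the
#' population frequencies. Emitted genotypes are unphased diploid calls;
#' dams are never emitted.
#'
#' @param genome An `rh_genome` tibble.
#' @param map_cm Genetic map tibble as from [even_genetic_map()]:
#'   `chrom`, `marker`, `cm` (distance to next marker, >= 0).
#' @param n_families Number of families.
#' @param n_meioses Total number of offspring (= paternal meioses) to
#'   distribute over families; every family gets at least 2. Ignored when
#'   `offspring_per_family` is given.
#' @param offspring_per_family Optional vector of per-family offspring
#'   counts (each >= 2), recycled to `n_families`.
#' @param allele_freq Allele-1 frequency, single number or per-marker
#'   tibble `marker`, `freq`, all strictly inside (0, 1).
#' @param seed Optional integer seed.
#' @return A list of class `rh_family_sim`:
#'   * `genotypes`: tibble `family`, `individual`, `father`, `role`,
#'     `chrom`, `marker`, `a1`, `a2` (alleles coded 1/2, unphased),
#'   * `truth`: list with `crossovers` (per meiosis and interval, true
#'     event counts) and `origins` (paternal haplotype origin per marker),
#'   * `n_meioses`, `seed`.
#' @export
simulate_halfsib_families <- function(genome, map_cm, n_families = 263,
                                      n_meioses = 728,
                                      offspring_per_family = NULL,
                                      allele_freq = 0.5, seed = NULL) {
  assert_columns(genome, c("marker", "chrom", "pos_kb"), "`genome`")
  assert_columns(map_cm, c("chrom", "marker", "cm"), "`map_cm`")
  if (any(map_cm$cm < 0)) abort("`map_cm$cm` must be non-negative.")
  n_families <- assert_count(n_families, "n_families", min = 1L)

  if (is.null(offspring_per_family)) {
    n_meioses <- assert_count(n_meioses, "n_meioses", min = 2L * n_families)
    base <- rep(2L, n_families)
    extra <- n_meioses - 2L * n_families
    if (extra > 0) {
      add <- rep(extra %/% n_families, n_families)
      rem <- extra %% n_families
      if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
      base <- base + add
    }
    offspring_per_family <- base
  } else {
    offspring_per_family <- rep_len(as.integer(offspring_per_family),
                                    n_families)
  }
  if (any(offspring_per_family < 2L)) {
    abort("Every family must have at least 2 offspring.")
  }

  markers_all <- genome$marker
  if (is.data.frame(allele_freq)) {
    assert_columns(allele_freq, c("marker", "freq"), "`allele_freq`")
    freq <- setNames(allele_freq$freq, allele_freq$marker)[markers_all]
  } else {
    freq <- setNames(rep_len(allele_freq, length(markers_all)), markers_all)
  }
  if (any(is.na(freq)) || any(freq <= 0) || any(freq >= 1)) {
    abort("`allele_freq` must cover all markers with values in (0, 1).")
  }

  n_off_total <- sum(offspring_per_family)
  fam_ids <- sprintf("F%03d", seq_len(n_families))
  fam_of_off <- rep.int(seq_len(n_families), offspring_per_family)
  off_ids <- sprintf("%s_o%d", fam_ids[fam_of_off],
                     unlist(lapply(offspring_per_family, seq_len)))

  out <- with_seed_(seed, {
    per_chrom <- purrr::map(unique(genome$chrom), function(ch) {
      gm <- genome[genome$chrom == ch, , drop = FALSE]
      gm <- gm[order(gm$pos_kb), , drop = FALSE]
      m <- nrow(gm)
      mk <- gm$marker
      fr <- freq[mk]
      cm <- map_cm$cm[match(mk, map_cm$marker)]
      if (any(is.na(cm))) abort(sprintf(
        "`map_cm` is missing markers on %s.", ch))
      rate <- cm[-m] / 100  # Morgans per interval

      draw_allele <- function(nr) {
        # allele 1 with probability fr (matrix nr x m)
        matrix(ifelse(runif(nr * m) < rep(fr, each = nr), 1L, 2L), nr, m)
      }
      sire_h1 <- draw_allele(n_families)
      sire_h2 <- draw_allele(n_families)

      # crossovers per meiosis and interval; odd counts switch the origin
      xo <- if (m > 1) {
        matrix(rpois(n_off_total * (m - 1), rep(rate, each = n_off_total)),
               n_off_total, m - 1)
      } else {
        matrix(0L, n_off_total, 0)
      }
      start <- rbinom(n_off_total, 1L, 0.5)
      parity <- if (m > 1) t(apply(xo, 1, cumsum)) %% 2 else
        matrix(0L, n_off_total, 0)
      origin <- (cbind(start, parity + start) %% 2) + 1L  # 1 = hap1
      if (m == 1) origin <- matrix(start + 1L, n_off_total, 1)

      pat <- ifelse(origin == 1L,
                    sire_h1[fam_of_off, , drop = FALSE],
                    sire_h2[fam_of_off, , drop = FALSE])
      mat <- draw_allele(n_off_total)
      a1 <- pmin(pat, mat)
      a2 <- pmax(pat, mat)

      genotypes <- bind_rows(
        tibble(
          family = rep(fam_ids, m),
          individual = rep(paste0(fam_ids, "_sire"), m),
          father = "0", role = "sire", chrom = ch,
          marker = rep(mk, each = n_families),
          a1 = as.integer(pmin(sire_h1, sire_h2)),
          a2 = as.integer(pmax(sire_h1, sire_h2))
        ),
        tibble(
          family = rep(fam_ids[fam_of_off], m),
          individual = rep(off_ids, m),
          father = rep(paste0(fam_ids[fam_of_off], "_sire"), m),
          role = "offspring", chrom = ch,
          marker = rep(mk, each = n_off_total),
          a1 = as.integer(a1), a2 = as.integer(a2)
        )
      )

      crossovers <- if (m > 1) {
        tibble(
          family = rep(fam_ids[fam_of_off], m - 1),
          offspring = rep(off_ids, m - 1),
          chrom = ch,
          interval = rep(seq_len(m - 1), each = n_off_total),
          left_marker = rep(mk[-m], each = n_off_total),
          n_events = as.integer(xo)
        ) |> filter(.data$n_events > 0)
      } else {
        tibble(family = character(), offspring = character(),
               chrom = character(), interval = integer(),
               left_marker = character(), n_events = integer())
      }

      origins <- tibble(
        family = rep(fam_ids[fam_of_off], m),
        offspring = rep(off_ids, m),
        chrom = ch,
        marker = rep(mk, each = n_off_total),
        origin = as.integer(origin)
      )

      list(genotypes = genotypes, crossovers = crossovers, origins = origins)
    })
    per_chrom
  })

  structure(
    list(
      genotypes = purrr::list_rbind(purrr::map(out, "genotypes")),
      truth = list(
        crossovers = purrr::list_rbind(purrr::map(out, "crossovers")),
        origins = purrr::list_rbind(purrr::map(out, "origins"))
      ),
      n_meioses = n_off_total,
      offspring_per_family = offspring_per_family,
      seed = seed
    ),
    class = "rh_family_sim"
  )
}

#' @export
tidy.rh_family_sim <- function(x, ...) x$genotypes

#' @export
print.rh_family_sim <- function(x, ...) {
  cat(sprintf("<rh_family_sim> %d families, %d meioses, %d markers\n",
              length(x$offspring_per_family), x$n_meioses,
              length(unique(x$genotypes$marker))))
  invisible(x)
}
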