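#' Infer paternal alleles of half-sib offspring
#'
#' In a half-sib family only the sire is genotyped among the parents. At a
#' sire-heterozygous marker, a homozygous offspring determines the
#' paternal allele; a heterozygous offspring is ambiguous (the dam is
#' unobserved) and is treated as missing rather than imputed.
#' Sire-homozygous markers are uninformative for phase. An offspring
#' allele pair incompatible with the sire (neither allele present in a
#' homozygous sire) is flagged as a Mendelian error and excluded.
#'
#' @param genotypes Long genotype tibble (`family`, `individual`, `role`,
#'   `marker`, `a1`, `a2`), as produced by [simulate_halfsib_families()].
#' @param order Marker order (character vector); markers absent from
#'   `order` are dropped.
#' @return Tibble `family`, `offspring`, `marker`, `paternal_allele`
#'   (NA unless informative), `status` in informative / ambiguous /
#'   uninformative / mendel_error.
#' @export
infer_paternal_alleles <- function(genotypes, order) {
  assert_columns(genotypes,
                 c("family", "individual", "role", "marker", "a1", "a2"),
                 "`genotypes`")
  g <- genotypes |> filter(.data$marker %in% order)
  sire <- g |>
    filter(.data$role == "sire") |>
    select("family", "marker", s1 = "a1", s2 = "a2")
  off <- g |>
    filter(.data$role == "offspring") |>
    select("family", offspring = "individual", "marker", "a1", "a2")
  off |>
    inner_join(sire, by = c("family", "marker")) |>
    mutate(
      sire_het = .data$s1 != .data$s2,
      off_het = .data$a1 != .data$a2,
      status = dplyr::case_when(
        !.data$sire_het & .data$a1 != .data$s1 & .data$a2 != .data$s1 ~
          "mendel_error",
        !.data$sire_het ~ "uninformative",
        .data$off_het ~ "ambiguous",
        TRUE ~ "informative"
      ),
      paternal_allele = if_else(.data$status == "informative",
                                .data$a1, NA_integer_)
    ) |>
    select("family", "offspring", "marker", "paternal_allele", "status")
}

# Exact minimum-recombinant phasing of one family by dynamic programming
# over informative sites. The DP state is the vector of current
# grandparental origins of the offspring (2^n_off states, small for
# half-sib families); at each site the sire phase takes one of two
# orientations and every offspring informative there either keeps or
# switches its origin. Returns the optimal phase bit per site (0 = first
# sire allele on haplotype 1). The true sire phase is always a feasible
# solution, so the minimised switch total never exceeds the number of
# observable crossovers.
min_recombinant_phase <- function(a_bit) {
  n_off <- nrow(a_bit); ns <- ncol(a_bit)
  n_states <- 2L^n_off
  bit_of <- 2L^(seq_len(n_off) - 1L)
  cost <- rep(0, n_states)
  bp_state <- matrix(NA_integer_, ns, n_states)
  bp_phi <- matrix(NA_integer_, ns, n_states)
  seen <- rep(FALSE, n_off)
  for (s in seq_len(ns)) {
    infm <- which(!is.na(a_bit[, s]))
    new_cost <- rep(Inf, n_states)
    for (st in 0:(n_states - 1L)) {
      base <- cost[st + 1L]
      if (!is.finite(base)) next
      for (phi in 0:1) {
        add <- 0
        nst <- st
        for (o in infm) {
          org <- bitwXor(phi, a_bit[o, s])
          old <- as.integer(bitwAnd(nst, bit_of[o]) > 0L)
          if (seen[o] && old != org) add <- add + 1
          nst <- bitwOr(bitwAnd(nst, bitwNot(bit_of[o])),
                        if (org == 1L) bit_of[o] else 0L)
        }
        nst <- bitwAnd(nst, n_states - 1L)
        if (base + add < new_cost[nst + 1L]) {
          new_cost[nst + 1L] <- base + add
          bp_state[s, nst + 1L] <- st
          bp_phi[s, nst + 1L] <- phi
        }
      }
    }
    cost <- new_cost
    seen[infm] <- TRUE
  }
  phi_seq <- integer(ns)
  st <- which.min(cost) - 1L
  for (s in rev(seq_len(ns))) {
    phi_seq[s] <- bp_phi[s, st + 1L]
    st <- bp_state[s, st + 1L]
  }
  phi_seq
}

#' Phase sires and count crossovers under a marker order
#'
#' Minimum-recombinant phasing per family: over the family's informative
#' sites (sire heterozygous, offspring homozygous), the sire phase is
#' chosen to minimise the total number of grandparental-origin switches
#' across all offspring, by an exact dynamic program whose state is the
#' offspring origin vector (half-sib families are small, so the
#' `2^n_offspring` state space is tiny). An offspring's crossover count
#' is the number of switches in its resulting origin path; each
#' crossover's probability mass is spread uniformly over the map
#' intervals between its two flanking informative sites, giving the
#' per-interval recombination profile.
#'
#' @inheritParams infer_paternal_alleles
#' @param max_dp_offspring Families with more offspring than this fall
#'   back to phasing on the most-informative subset (the remaining
#'   offspring are assigned origins against the fixed phase).
#' @return A list of class `rh_crossover_counts`: `meioses` (tibble
#'   `family`, `offspring`, `n_crossovers`, `n_informative`), `intervals`
#'   (tibble `interval`, `left_marker`, `right_marker`, `mass`, `rate`),
#'   `skipped` (families without informative sites), `n_meioses`,
#'   `length_cm` (`100 * sum(mass) / n_meioses`).
#' @export
phase_and_count <- function(genotypes, order, max_dp_offspring = 10) {
  order <- as.character(order)
  m <- length(order)
  inf <- infer_paternal_alleles(genotypes, order)
  inf$pos <- match(inf$marker, order)

  mendel <- inf |> filter(.data$status == "mendel_error")
  informative <- inf |> filter(.data$status == "informative")

  fam_split <- split(informative, informative$family)
  all_fams <- unique(genotypes$family)
  all_off <- genotypes |>
    filter(.data$role == "offspring") |>
    distinct(.data$family, offspring = .data$individual)
  sires <- genotypes |> filter(.data$role == "sire")
  sire_split <- split(sires[, c("marker", "a1", "a2")], sires$family)

  mass <- numeric(m - 1)
  meiosis_rows <- vector("list", length(fam_split))
  skipped <- setdiff(all_fams, names(fam_split))

  for (fi in seq_along(fam_split)) {
    fam <- fam_split[[fi]]
    offs <- unique(fam$offspring)
    sites <- sort(unique(fam$pos))
    ns <- length(sites)
    # offspring x site matrix of paternal alleles (NA where uninformative)
    A <- matrix(NA_integer_, length(offs), ns,
                dimnames = list(offs, NULL))
    A[cbind(match(fam$offspring, offs), match(fam$pos, sites))] <-
      fam$paternal_allele

    # the sire's two alleles at each informative site (het, so they differ)
    sire_g <- sire_split[[names(fam_split)[fi]]]
    sidx <- match(order[sites], sire_g$marker)
    h_a <- sire_g$a1[sidx]
    h_b <- sire_g$a2[sidx]

    # a_bit[o, s] = 0 when the offspring's paternal allele equals the
    # sire's first allele at the site; the DP works on these bits
    a_bit <- matrix(NA_integer_, length(offs), ns)
    obs_mask <- !is.na(A)
    a_bit[obs_mask] <- as.integer(A[obs_mask] !=
                                    h_a[col(A)[obs_mask]])

    if (length(offs) <= max_dp_offspring) {
      phi <- min_recombinant_phase(a_bit)
    } else {
      # phase on the most informative offspring, then project the rest
      core <- order(rowSums(obs_mask), decreasing = TRUE)[
        seq_len(max_dp_offspring)]
      phi <- min_recombinant_phase(a_bit[core, , drop = FALSE])
    }

    # origin path per offspring: 1 / 2 at informative sites, NA elsewhere
    paths <- matrix(NA_integer_, length(offs), ns)
    for (o in seq_along(offs)) {
      obs <- which(obs_mask[o, ])
      paths[o, obs] <- bitwXor(phi[obs], a_bit[o, obs]) + 1L
    }

    # count switches and spread crossover mass
    fam_rows <- tibble(
      family = fam$family[1], offspring = offs,
      n_crossovers = 0L,
      n_informative = rowSums(!is.na(A))
    )
    for (o in seq_along(offs)) {
      obs <- which(!is.na(paths[o, ]))
      if (length(obs) < 2L) next
      p <- paths[o, obs]
      sw <- which(diff(p) != 0L)
      fam_rows$n_crossovers[o] <- length(sw)
      for (s in sw) {
        left <- sites[obs[s]]
        right <- sites[obs[s + 1]]
        ivals <- left:(right - 1L)
        mass[ivals] <- mass[ivals] + 1 / length(ivals)
      }
    }
    meiosis_rows[[fi]] <- fam_rows
  }

  meioses <- if (length(meiosis_rows)) purrr::list_rbind(meiosis_rows) else
    tibble(family = character(), offspring = character(),
           n_crossovers = integer(), n_informative = integer())
  # meioses without informative data still belong to skipped bookkeeping
  n_meioses <- nrow(all_off)

  intervals <- tibble(
    interval = seq_len(m - 1),
    left_marker = order[-m], right_marker = order[-1],
    mass = mass, rate = mass / n_meioses
  )

  structure(
    list(meioses = meioses, intervals = intervals,
         skipped = skipped, mendel_errors = mendel,
         n_meioses = n_meioses,
         length_cm = 100 * sum(mass) / n_meioses,
         order = order),
    class = "rh_crossover_counts"
  )
}

#' @export
tidy.rh_crossover_counts <- function(x, ...) x$intervals

#' @export
glance.rh_crossover_counts <- function(x, ...) {
  tibble(n_meioses = x$n_meioses,
         n_crossovers = sum(x$meioses$n_crossovers),
         length_cm = x$length_cm,
         n_families_skipped = length(x$skipped),
         n_mendel_errors = nrow(x$mendel_errors))
}

#' @export
print.rh_crossover_counts <- function(x, ...) {
  cat(sprintf(
    "<rh_crossover_counts> %d crossovers in %d meioses; length %.1f cM\n",
    sum(x$meioses$n_crossovers), x$n_meioses, x$length_cm))
  invisible(x)
}

#' Compare the genetic length implied by two marker orders
#'
#' Runs crossover detection under each order on the same families and the
#' same markers, and reports the per-chromosome genetic lengths and their
#' difference, together with per-interval recombination-rate profiles. A
#' shorter genetic length means the order is more parsimonious in the
#' number of recombination events needed to explain the genotypes —
#' the core logic of validating a physical map with genetic data.
#'
#' @inheritParams infer_paternal_alleles
#' @param order_a,order_b Marker orders: character vectors (single
#'   chromosome) or tibbles with `chrom` and `marker` columns. The two
#'   orders must contain the same marker set per chromosome.
#' @param labels Length-2 names used in the output.
#' @return A list of class `rh_order_comparison`: `chromosomes` (tibble
#'   `chrom`, per-order lengths, `delta_cm` = length(a) - length(b)),
#'   `intervals` (per order, interval rates), `n_meioses`.
#' @export
compare_orders <- function(genotypes, order_a, order_b,
                           labels = c("a", "b")) {
  norm <- function(o) {
    if (is.character(o)) return(tibble(chrom = "chr", marker = o))
    assert_columns(o, c("chrom", "marker"), "order")
    as_tibble(o)[, c("chrom", "marker")]
  }
  oa <- norm(order_a); ob <- norm(order_b)
  mism <- c(setdiff(oa$marker, ob$marker), setdiff(ob$marker, oa$marker))
  if (length(mism) > 0L) {
    abort(sprintf("Orders cover different marker sets; differing: %s.",
                  paste(head(mism, 10), collapse = ", ")))
  }
  chroms <- unique(oa$chrom)
  res <- purrr::map(chroms, function(ch) {
    mk_a <- oa$marker[oa$chrom == ch]
    mk_b <- ob$marker[ob$chrom == ch]
    g <- genotypes |> filter(.data$marker %in% mk_a)
    ca <- phase_and_count(g, mk_a)
    cb <- phase_and_count(g, mk_b)
    list(
      chrom_row = tibble(
        chrom = ch,
        !!paste0("length_cm_", labels[1]) := ca$length_cm,
        !!paste0("length_cm_", labels[2]) := cb$length_cm,
        delta_cm = ca$length_cm - cb$length_cm
      ),
      intervals = bind_rows(
        ca$intervals |> mutate(order = labels[1], chrom = ch),
        cb$intervals |> mutate(order = labels[2], chrom = ch)
      ),
      n_meioses = ca$n_meioses
    )
  })
  structure(
    list(
      chromosomes = purrr::list_rbind(purrr::map(res, "chrom_row")),
      intervals = purrr::list_rbind(purrr::map(res, "intervals")),
      n_meioses = res[[1]]$n_meioses,
      labels = labels
    ),
    class = "rh_order_comparison"
  )
}

#' @export
tidy.rh_order_comparison <- function(x, ...) x$intervals

#' @export
glance.rh_order_comparison <- function(x, ...) {
  x$chromosomes |> mutate(n_meioses = x$n_meioses)
}

#' @export
print.rh_order_comparison <- function(x, ...) {
  cat("<rh_order_comparison>\n")
  print(x$chromosomes)
  invisible(x)
}
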