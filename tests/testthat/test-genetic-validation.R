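# hand-built family: sire heterozygous 1/2 at every marker, offspring
# homozygous for their paternal allele (maternal allele set equal), so
# every site is informative and crossovers are fully visible
planted_family <- function(origins_list, n_markers = 10) {
  mk <- sprintf("m%02d", seq_len(n_markers))
  hap1 <- rep(1L, n_markers); hap2 <- rep(2L, n_markers)
  rows <- list(tibble::tibble(
    family = "F1", individual = "F1_sire", father = "0", role = "sire",
    chrom = "chr1", marker = mk, a1 = 1L, a2 = 2L
  ))
  for (i in seq_along(origins_list)) {
    pat <- ifelse(origins_list[[i]] == 1L, hap1, hap2)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      family = "F1", individual = paste0("F1_o", i), father = "F1_sire",
      role = "offspring", chrom = "chr1", marker = mk,
      a1 = pat, a2 = pat
    )
  }
  dplyr::bind_rows(rows)
}

test_that("paternal allele inference follows half-sib rules", {
  g <- tibble::tibble(
    family = "F1",
    individual = c("F1_sire", rep("F1_o1", 4)),
    father = c("0", rep("F1_sire", 4)),
    role = c("sire", rep("offspring", 4)),
    chrom = "chr1",
    marker = c("m1", "m1", "m2", "m3", "m4"),
    a1 = c(1L, 1L, 1L, 2L, 1L),
    a2 = c(2L, 1L, 2L, 2L, 1L)
  )
  sire_more <- tibble::tibble(
    family = "F1", individual = "F1_sire", father = "0", role = "sire",
    chrom = "chr1", marker = c("m2", "m3", "m4"),
    a1 = c(1L, 1L, 1L), a2 = c(2L, 1L, 1L)
  )
  inf <- infer_paternal_alleles(dplyr::bind_rows(g, sire_more),
                                paste0("m", 1:4))
  expect_equal(inf$status[inf$marker == "m1"], "informative")
  expect_equal(inf$paternal_allele[inf$marker == "m1"], 1L)
  expect_equal(inf$status[inf$marker == "m2"], "ambiguous")
  expect_equal(inf$status[inf$marker == "m3"], "mendel_error")
  expect_equal(inf$status[inf$marker == "m4"], "uninformative")
})

test_that("planted crossovers are detected and localized exactly", {
  # two constant offspring pin the sire phase by majority; the third
  # carries switches after m04 and after m07
  orig3 <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L)
  fam <- planted_family(list(rep(1L, 10), rep(1L, 10), orig3))
  res <- phase_and_count(fam, sprintf("m%02d", 1:10))
  cnt <- res$meioses
  expect_equal(cnt$n_crossovers[cnt$offspring == "F1_o1"], 0L)
  expect_equal(cnt$n_crossovers[cnt$offspring == "F1_o2"], 0L)
  expect_equal(cnt$n_crossovers[cnt$offspring == "F1_o3"], 2L)
  expect_equal(res$intervals$mass[c(4, 7)], c(1, 1))
  expect_equal(sum(res$intervals$mass), 2)
  expect_equal(res$length_cm, 100 * 2 / 3)
})

test_that("crossover mass spreads uniformly over uninformative gaps", {
  # make m05..m06 uninformative by removing the offspring's calls there:
  # a crossover between m04 and m07 is localized to 3 candidate intervals
  orig3 <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)
  fam <- planted_family(list(rep(1L, 10), rep(1L, 10), orig3))
  fam$a1[fam$individual == "F1_o3" & fam$marker %in% c("m05", "m06")] <- 1L
  fam$a2[fam$individual == "F1_o3" & fam$marker %in% c("m05", "m06")] <- 2L
  res <- phase_and_count(fam, sprintf("m%02d", 1:10))
  expect_equal(res$meioses$n_crossovers[res$meioses$offspring == "F1_o3"],
               1L)
  expect_equal(res$intervals$mass[4:6], rep(1 / 3, 3))
})

test_that("Mendelian inconsistencies are logged and excluded", {
  fam <- planted_family(list(rep(1L, 10)))
  fam$a1[fam$individual == "F1_sire" & fam$marker == "m03"] <- 1L
  fam$a2[fam$individual == "F1_sire" & fam$marker == "m03"] <- 1L
  fam$a1[fam$individual == "F1_o1" & fam$marker == "m03"] <- 2L
  fam$a2[fam$individual == "F1_o1" & fam$marker == "m03"] <- 2L
  res <- phase_and_count(fam, sprintf("m%02d", 1:10))
  expect_equal(nrow(res$mendel_errors), 1L)
  expect_equal(res$meioses$n_crossovers, 0L)
})

test_that("a 1-Morgan chromosome yields ~100 cM from 728 meioses", {
  # dense markers so that parsimony losses (end censoring, cancelling
  # crossovers in sparsely informative stretches) stay small
  g <- simulate_genome(1, chrom_kb = 101000, n_markers = 500, seed = 301)
  gmap <- even_genetic_map(g, total_cm = 100)
  fam <- simulate_halfsib_families(g, gmap, n_families = 263,
                                   n_meioses = 728, seed = 302)
  res <- phase_and_count(fam$genotypes, g$marker)
  se_cm <- 100 * sqrt(728) / 728
  expect_lt(abs(res$length_cm - 100), 3 * se_cm)

  # parsimony: no family reports more crossovers than truly occurred
  # (within a family the attribution of a switch to a specific offspring
  # can be ambiguous, but the minimised total cannot exceed the truth)
  truth <- fam$truth$crossovers |>
    dplyr::group_by(family) |>
    dplyr::summarise(true_n = sum(n_events))
  det <- res$meioses |>
    dplyr::group_by(family) |>
    dplyr::summarise(det_n = sum(n_crossovers))
  joined <- dplyr::left_join(det, truth, by = "family")
  joined$true_n[is.na(joined$true_n)] <- 0L
  expect_true(all(joined$det_n <= joined$true_n))
  expect_lte(sum(res$meioses$n_crossovers),
             sum(fam$truth$crossovers$n_events))

  # genetic length is invariant to whole-order reversal (the interval
  # profile may reallocate mass among tied minimum-recombinant
  # explanations, but the detected total cannot change)
  res_rev <- phase_and_count(fam$genotypes, rev(g$marker))
  expect_equal(res_rev$length_cm, res$length_cm, tolerance = 1e-9)
  expect_equal(sum(res_rev$intervals$mass), sum(res$intervals$mass),
               tolerance = 1e-9)
})

test_that("order comparison is null for identical orders, penalises edits", {
  g <- simulate_genome(1, chrom_kb = 51000, n_markers = 50, seed = 303)
  gmap <- even_genetic_map(g, total_cm = 80)
  fam <- simulate_halfsib_families(g, gmap, n_families = 80,
                                   n_meioses = 200, seed = 304)
  ord <- tibble::tibble(chrom = "chr1", marker = g$marker)
  same <- compare_orders(fam$genotypes, ord, ord)
  expect_equal(same$chromosomes$delta_cm, 0)

  corrupted <- corrupt_assembly_order(
    g, n_segment_relocations = 1,
    segment_length_range_kb = c(9000, 10000), seed = 305)
  cmp <- compare_orders(fam$genotypes, corrupted$order[, c("chrom", "marker")],
                        ord, labels = c("corrupted", "true"))
  expect_gt(cmp$chromosomes$delta_cm, 0)

  # the excess recombination concentrates at the relocation junctions:
  # intervals of the corrupted order that pair markers which are not
  # adjacent in the true order show inflated apparent rates
  prof <- phase_and_count(fam$genotypes, corrupted$order$marker)
  junctions <- which(abs(diff(match(corrupted$order$marker,
                                    g$marker))) != 1)
  iv <- prof$intervals
  expect_true(iv$interval[which.max(iv$rate)] %in% junctions)
  expect_gt(mean(iv$rate[junctions]), 2 * mean(iv$rate[-junctions]))

  expect_error(compare_orders(fam$genotypes, ord[-1, ], ord),
               "different marker sets")
})
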