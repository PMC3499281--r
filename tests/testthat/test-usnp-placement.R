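calls_from_vec <- function(v, marker, panel = "RH1") {
  tibble::tibble(marker = marker, panel = panel,
                 clone = sprintf("c%03d", seq_along(v)),
                 call = as.integer(v))
}

test_that("similarity score matches the hand-evaluated 2x2 chi-square", {
  # table n11=30, n10=5, n01=5, n00=50 over 90 clones
  u <- c(rep(1L, 35), rep(0L, 55))
  m <- c(rep(1L, 30), rep(0L, 5), rep(1L, 5), rep(0L, 50))
  calls <- dplyr::bind_rows(calls_from_vec(u, "u1"), calls_from_vec(m, "m1"))
  s <- similarity_score(calls, "u1", "m1")
  chi2_exp <- 90 * (30 * 50 - 25)^2 / (35 * 55 * 35 * 55)
  expect_equal(s$chi2, chi2_exp, tolerance = 1e-10)
  expect_equal(s$chi2, 52.84, tolerance = 0.01)
  expect_equal(s$score, 12.4, tolerance = 0.1)
  # independent oracle: base R chi-square test without correction
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(30, 5, 5, 50), 2), correct = FALSE))
  expect_equal(s$chi2, unname(oracle$statistic), tolerance = 1e-8)
  expect_equal(s$score, -log10(oracle$p.value), tolerance = 1e-8)
})

test_that("scoring is symmetric, one-sided and guards degenerate margins", {
  u <- c(rep(1L, 35), rep(0L, 55))
  m <- c(rep(1L, 30), rep(0L, 5), rep(1L, 5), rep(0L, 50))
  calls <- dplyr::bind_rows(calls_from_vec(u, "a"), calls_from_vec(m, "b"))
  expect_equal(similarity_score(calls, "a", "b")$score,
               similarity_score(calls, "b", "a")$score)

  # negative association scores zero
  neg <- dplyr::bind_rows(calls_from_vec(u, "a"),
                          calls_from_vec(1L - u, "c"))
  expect_equal(similarity_score(neg, "a", "c")$score, 0)

  # an all-present marker is degenerate
  deg <- dplyr::bind_rows(calls_from_vec(u, "a"),
                          calls_from_vec(rep(1L, 90), "d"))
  sd_ <- similarity_score(deg, "a", "d")
  expect_equal(sd_$score, 0)
  expect_true(sd_$degenerate)

  expect_error(similarity_score(calls[1:95, ], "a", "b"), "observed clones")
})

test_that("a uSNP scores highest against its own duplicate", {
  g <- tiny_genome(n_markers = 10, spacing_kb = 300)
  sim <- simulate_rh_panel(g, panel_config(90, 8.6, 0.4),
                           keep_fragments = FALSE, seed = 401)
  dup <- sim$calls[sim$calls$marker == g$marker[5], ]
  dup$marker <- "u_dup"
  all_calls <- dplyr::bind_rows(sim$calls, dup)
  scores <- vapply(g$marker, function(mk) {
    similarity_score(all_calls, "u_dup", mk)$score
  }, numeric(1))
  expect_equal(names(which.max(scores)), g$marker[5])
})

test_that("independent vectors rarely reach the assignment threshold", {
  set.seed(402)
  n <- 90
  draws <- vapply(seq_len(1000), function(i) {
    calls <- dplyr::bind_rows(
      calls_from_vec(rbinom(n, 1, 0.3), "x"),
      calls_from_vec(rbinom(n, 1, 0.3), "y"))
    similarity_score(calls, "x", "y")$score
  }, numeric(1))
  expect_gte(mean(draws < 5), 0.99)
})

test_that("the empirical null is reproducible and flags planted links", {
  g <- simulate_genome(2, chrom_kb = 4000, n_markers = 15)
  sim <- simulate_rh_panel(g, panel_config(90, 8.6, 0.3),
                           keep_fragments = FALSE, seed = 403)
  assignments <- g[, c("marker", "chrom")]
  n1 <- empirical_null(sim$calls, assignments, n_rep = 200, seed = 404)
  n2 <- empirical_null(sim$calls, assignments, n_rep = 200, seed = 404)
  expect_identical(n1$maxima, n2$maxima)
  expect_length(n1$maxima, 200)
  expect_true(all(is.finite(n1$quantiles$value)))

  one_chrom <- assignments[assignments$chrom == "chr1", ]
  expect_error(
    empirical_null(sim$calls[sim$calls$marker %in% one_chrom$marker, ],
                   one_chrom, n_rep = 10, seed = 1),
    "2 chromosomes")
})

test_that("chromosome assignment requires a unique panel-wide winner", {
  g <- simulate_genome(2, chrom_kb = 6000, n_markers = 20)
  calls <- two_panel_calls(g, n_clones = 90, seed = 405)
  assignments <- g[, c("marker", "chrom")]
  mapped <- calls[calls$marker != g$marker[5], ]
  u <- calls[calls$marker == g$marker[5], ]
  res <- assign_chromosome(u, mapped, assignments, panel = "RH1",
                           threshold = 7)
  expect_equal(res$chrom, "chr1")
  expect_equal(res$reason, "assigned")

  # unreachable threshold: unassigned with reason "none"
  res_hi <- assign_chromosome(u, mapped, assignments, panel = "RH1",
                              threshold = 1e6)
  expect_true(is.na(res_hi$chrom))
  expect_equal(res_hi$reason, "none")

  # a duplicate of the uSNP planted on the other chromosome forces
  # a multiple assignment at a low threshold
  fake <- u
  fake$marker <- "planted"
  mapped2 <- dplyr::bind_rows(mapped, fake)
  assignments2 <- dplyr::bind_rows(assignments,
                                   tibble::tibble(marker = "planted",
                                                  chrom = "chr2"))
  res_mult <- assign_chromosome(u, mapped2, assignments2, panel = "RH1",
                                threshold = 7)
  expect_equal(res_mult$reason, "multiple")
  expect_true(is.na(res_mult$chrom))

  # raising the threshold never increases multiple assignments
  thr_grid <- c(2, 5, 7, 10, 20)
  n_mult <- vapply(thr_grid, function(th) {
    sum(assign_chromosome(u, mapped2, assignments2, panel = "RH1",
                          threshold = th)$reason == "multiple")
  }, numeric(1))
  expect_true(all(diff(n_mult) <= 0))
})

test_that("position prediction is the score-weighted barycenter", {
  # neighbours at 100 cR (S=10) and 120 cR (S=5) -> 106.67 cR
  expect_equal((10 * 100 + 5 * 120) / 15, 106.67, tolerance = 0.01)

  g <- tiny_genome(n_markers = 12, spacing_kb = 250)
  calls <- two_panel_calls(g, n_clones = 90, seed = 406)
  map <- order_search(calls, g$marker)
  map$chrom <- "chr1"
  map$ref_bp <- round(g$pos_kb[match(map$marker, g$marker)] * 1000)
  u <- calls[calls$marker == g$marker[6], ]
  mapped <- calls[calls$marker != g$marker[6], ]
  mm <- map[map$marker != g$marker[6], ]
  assign <- tibble::tibble(usnp = g$marker[6], chrom = "chr1")
  pred <- predict_position(u, mapped, mm, assign, mm[, c("marker", "chrom")],
                           panel = "RH2", pos_col = "pos_cr_rh2")
  expect_equal(pred$status, "placed")
  s1 <- pred$best_score; s2 <- pred$second_score
  p1 <- mm$pos_cr_rh2[mm$marker == pred$best_msnp]
  p2 <- mm$pos_cr_rh2[mm$marker == pred$second_msnp]
  expect_equal(pred$rh_position, (s1 * p1 + s2 * p2) / (s1 + s2))
  # the held-out marker sits between markers 5 and 7 on the true map
  lo <- min(mm$pos_cr_rh2[mm$marker %in% g$marker[c(4, 5)]])
  hi <- max(mm$pos_cr_rh2[mm$marker %in% g$marker[c(7, 8)]])
  expect_gte(pred$rh_position, lo)
  expect_lte(pred$rh_position, hi)
})

test_that("the monotone spline projects cR to bp with clamping", {
  map <- tibble::tibble(
    marker = sprintf("m%02d", 1:20), chrom = "chr1",
    pos_cr_rh2 = seq(0, 95, by = 5),
    ref_bp = 10 * seq(0, 95, by = 5) + 1
  )
  spl <- fit_assembly_spline(map, chrom_lengths = c(chr1 = 2000))
  got <- map_to_assembly(spl, "chr1", c(50, -10, 300))
  expect_equal(got$bp_position[1], 501, tolerance = 1)
  expect_false(got$extrapolated[1])
  expect_true(all(got$extrapolated[2:3]))
  expect_gte(got$bp_position[2], 1)
  expect_lte(got$bp_position[3], 2000)

  # monotone in rh_position even with local inversions in the input
  map2 <- map
  map2$ref_bp[8] <- map2$ref_bp[12]  # a misplaced point
  spl2 <- fit_assembly_spline(map2)
  grid <- map_to_assembly(spl2, "chr1", seq(0, 95, by = 1))
  expect_true(all(diff(grid$bp_position) >= 0))

  expect_error(fit_assembly_spline(map[1:5, ]), "only 5")
})

test_that("scaffold anchoring applies majority and the 5-way categories", {
  placements <- tibble::tibble(
    usnp = paste0("u", 1:8),
    chrom = c("chr6", "chr6", "chr6", "chr1",
              "chr2", "chr2", "chr3", "chr3"),
    bp_position = c(5e6, 5.2e6, 5.4e6, 9e6,
                    2e6, 2.1e6, 7e6, 7.1e6),
    status = "placed"
  )
  snp_scaffolds <- tibble::tibble(
    marker = paste0("u", 1:8),
    scaffold = c("s1", "s1", "s1", "s1", "s2", "s2", "s3", "s3")
  )
  homology <- tibble::tibble(
    scaffold = c("s1", "s2", "s4"),
    homolog_chrom = c("chr6", NA, "chr9"),
    homolog_bp = c(5.6e6, NA, 1e6)
  )
  anc <- anchor_scaffolds(placements, snp_scaffolds, homology)
  s1 <- anc[anc$scaffold == "s1", ]
  expect_equal(s1$chrom, "chr6")      # minority SNP on chr1 dropped
  expect_equal(s1$n_dropped, 1L)
  expect_equal(s1$category, "valid")  # 5.2 Mb midpoint vs 5.6 Mb homology
  expect_equal(anc$category[anc$scaffold == "s2"], "nosynt")
  expect_equal(anc$category[anc$scaffold == "s3"], "noinfo")

  # discordant and sscvalid cases
  homology2 <- tibble::tibble(
    scaffold = c("s1", "s2", "s3"),
    homolog_chrom = c("chr5", "chr2", "chr3"),
    homolog_bp = c(5.6e6, 2.05e6, 30e6)
  )
  anc2 <- anchor_scaffolds(placements, snp_scaffolds, homology2)
  expect_equal(anc2$category[anc2$scaffold == "s1"], "discordant")
  expect_equal(anc2$category[anc2$scaffold == "s2"], "valid")
  expect_equal(anc2$category[anc2$scaffold == "s3"], "sscvalid")

  # a 2 vs 2 split has no strict majority
  placements3 <- placements
  placements3$chrom[placements3$usnp == "u2"] <- "chr1"
  anc3 <- anchor_scaffolds(placements3, snp_scaffolds, homology)
  expect_false(anc3$resolved[anc3$scaffold == "s1"])
  expect_equal(anc3$category[anc3$scaffold == "s1"], "unresolved")
})

test_that("category summaries recompute totals and proportions", {
  counts <- tibble::tibble(
    category = c("discordant", "noinfo", "nosynt", "sscvalid", "valid"),
    n_scaffolds = c(100, 197, 187, 166, 778),
    length_mb = c(6.9, 1.2, 5.0, 12.4, 53.7),
    n_usnps = c(149, 213, 249, 242, 1094)
  )
  s <- placement_category_summary(counts)
  expect_equal(s$n_scaffolds[s$category == "tentative"], 1328)
  expect_equal(s$pct_scaffolds[s$category == "discordant"], 7.0,
               tolerance = 0.05)
  expect_equal(s$pct_scaffolds[s$category == "tentative"], 93.0,
               tolerance = 0.05)
  expect_equal(s$pct_length[s$category == "valid"], 67.8, tolerance = 0.1)
  expect_equal(sum(s$n_usnps[s$category %in% c("discordant", "tentative")]),
               1947)
})
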