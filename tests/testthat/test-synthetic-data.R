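test_that("degenerate retention and no-breakage limits behave exactly", {
  g <- tiny_genome(n_markers = 6)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 25, retention = 1.0),
                           seed = 3)
  expect_true(all(sim$calls$call == 1L))

  sim0 <- simulate_rh_panel(
    g, panel_config(n_clones = 25, kb_per_cr = Inf, retention = 0.4),
    seed = 4)
  per_clone <- tapply(sim0$calls$call, sim0$calls$clone,
                      function(v) length(unique(v)))
  expect_true(all(per_clone == 1L))
  expect_equal(nrow(sim0$breaks), 0L)
})

test_that("pairwise discordance matches the Markov closed form", {
  # two markers 100 Kb apart on the 8.6 Kb/cR panel
  g <- simulate_genome(1, chrom_kb = 300, n_markers = 2)
  expect_equal(diff(g$pos_kb), 100)
  r <- 0.3
  sim <- simulate_rh_panel(
    g, panel_config(n_clones = 100000, kb_per_cr = 8.6, retention = r),
    keep_fragments = FALSE, seed = 11)
  m <- rhmapper:::calls_matrix(sim$calls)
  p_exp <- 2 * r * (1 - r) * (1 - exp(-(100 / 8.6) / 100))
  expect_equal(round(p_exp, 4), 0.0461)
  p_obs <- mean(m[, 1] != m[, 2])
  se <- sqrt(p_exp * (1 - p_exp) / nrow(m))
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # marginal retention converges to r
  expect_lt(abs(mean(m) - r), 3 * sqrt(r * (1 - r) / length(m)))
})

test_that("discordance follows the fragment process at all distances", {
  g <- tiny_genome(n_markers = 5, spacing_kb = 80)
  r <- 0.25
  sim <- simulate_rh_panel(
    g, panel_config(n_clones = 20000, kb_per_cr = 8.6, retention = r),
    keep_fragments = FALSE, seed = 12)
  m <- rhmapper:::calls_matrix(sim$calls, markers = g$marker)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      d <- (g$pos_kb[j] - g$pos_kb[i])
      p_exp <- 2 * r * (1 - r) * (1 - exp(-(d / 8.6) / 100))
      p_obs <- mean(m[, i] != m[, j])
      se <- sqrt(p_exp * (1 - p_exp) / nrow(m))
      expect_lt(abs(p_obs - p_exp), 3.5 * se)
    }
  }
})

test_that("the denser-breakage panel separates markers more often", {
  g <- tiny_genome(n_markers = 10, spacing_kb = 60)
  s_low <- simulate_rh_panel(g, panel_config(5000, 8.6, 0.3),
                             keep_fragments = FALSE, seed = 21)
  s_high <- simulate_rh_panel(g, panel_config(5000, 5.3, 0.3),
                              keep_fragments = FALSE, seed = 22)
  disc <- function(sim) {
    m <- rhmapper:::calls_matrix(sim$calls, markers = g$marker)
    mean(m[, -1] != m[, -10])
  }
  expect_gt(disc(s_high), disc(s_low))
})

test_that("generators are reproducible and truth records are coherent", {
  g <- tiny_genome(n_markers = 4)
  a <- simulate_rh_panel(g, panel_config(n_clones = 20), seed = 7)
  b <- simulate_rh_panel(g, panel_config(n_clones = 20), seed = 7)
  expect_identical(a$calls, b$calls)
  expect_identical(a$breaks, b$breaks)

  # fragments tile each chromosome and determine the true calls
  sim <- simulate_rh_panel(g, panel_config(n_clones = 15), seed = 8)
  frag <- sim$fragments
  for (cl in unique(frag$clone)) {
    f <- frag[frag$clone == cl, ]
    expect_equal(f$start_cr[-1], f$end_cr[-nrow(f)])
  }
  # recompute calls from fragments
  pos_cr <- g$pos_kb / 8.6
  recomputed <- sim$true_calls
  for (i in seq_len(nrow(recomputed))) {
    cl <- recomputed$clone[i]
    p <- pos_cr[match(recomputed$marker[i], g$marker)]
    f <- frag[frag$clone == cl & frag$start_cr <= p & frag$end_cr >= p, ]
    expect_equal(recomputed$call[i], as.integer(f$retained[1]))
  }
})

test_that("invalid panel configurations name the offending field", {
  expect_error(panel_config(n_clones = 0), "n_clones")
  expect_error(panel_config(kb_per_cr = -1), "kb_per_cr")
  expect_error(panel_config(retention = 0), "retention")
  expect_error(panel_config(miscall_rate = 1), "miscall_rate")
  expect_error(panel_config(missing_rate = -0.1), "missing_rate")
})

test_that("miscall and missing rates are applied at the requested level", {
  g <- tiny_genome(n_markers = 3)
  sim <- simulate_rh_panel(
    g, panel_config(n_clones = 3000, miscall_rate = 0.05,
                    missing_rate = 0.1), seed = 31)
  p_missing <- mean(is.na(sim$calls$call))
  expect_lt(abs(p_missing - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(sim$calls)))
  flips <- mean(sim$calls$call != sim$true_calls$call, na.rm = TRUE)
  expect_lt(abs(flips - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(sim$calls)))
})

test_that("designed cross-hybridizers follow the binomial bookkeeping", {
  g <- simulate_genome(1, chrom_kb = 50000, n_markers = 1000)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 5),
                           keep_fragments = FALSE, seed = 41)
  intens <- simulate_intensities(
    sim$true_calls, intensity_model(crosshyb_frac = 0.05), seed = 42)
  n_ch <- sum(intens$meta$crosshyb)
  expect_lt(abs(n_ch - 50), 3 * sqrt(1000 * 0.05 * 0.95) + 1)
  # every designed cross-hybridizer exceeds the hamster thresholds
  th <- calling_thresholds()
  ham <- intens$intensities[intens$intensities$sample == "hamster", ]
  ch <- ham[ham$marker %in% intens$meta$marker[intens$meta$crosshyb], ]
  expect_true(all(ch$x > th$hamster_x_max | ch$y > th$hamster_y_max))
})

test_that("all-absent truth lands every RH signal in the low cluster", {
  g <- tiny_genome(n_markers = 5)
  truth <- tidyr::expand_grid(marker = g$marker,
                              clone = sprintf("c%02d", 1:20))
  truth$call <- 0L
  intens <- simulate_intensities(truth, seed = 43)
  th <- calling_thresholds()
  rh <- intens$intensities[!intens$intensities$sample %in%
                             c("hamster", "genomic"), ]
  expect_true(all(rh$x < th$absent_x_max & rh$y < th$absent_y_max))
  expect_true(all(intens$intensities$x >= 0 & intens$intensities$y >= 0))
})

test_that("half-sib simulation keeps exact meiosis bookkeeping", {
  g <- tiny_genome(n_markers = 8)
  gmap <- even_genetic_map(g, total_cm = 0)
  fam <- simulate_halfsib_families(g, gmap, n_families = 2, n_meioses = 4,
                                   seed = 51)
  expect_equal(fam$n_meioses, 4L)
  expect_equal(nrow(fam$truth$crossovers), 0L)
  off <- unique(fam$genotypes$individual[fam$genotypes$role == "offspring"])
  expect_length(off, 4L)

  expect_error(
    simulate_halfsib_families(g, gmap, n_families = 2,
                              offspring_per_family = 1, seed = 5),
    "at least 2"
  )
})

test_that("total true crossovers follow the Poisson expectation", {
  g <- tiny_genome(n_markers = 20, spacing_kb = 500)
  gmap <- even_genetic_map(g, total_cm = 100)
  fam <- simulate_halfsib_families(g, gmap, n_families = 263,
                                   n_meioses = 728, seed = 52)
  total <- sum(fam$truth$crossovers$n_events)
  expect_lt(abs(total - 728), 3 * sqrt(728))
})

test_that("assembly corruption logs every edit and stays a permutation", {
  g <- simulate_genome(1, chrom_kb = 10100, n_markers = 100)

  c0 <- corrupt_assembly_order(g, seed = 61)
  expect_identical(c0$order$marker, g$marker)
  expect_equal(nrow(c0$edits), 0L)

  c1 <- corrupt_assembly_order(g, n_single_misplacements = 1, seed = 62)
  expect_setequal(c1$order$marker, g$marker)
  moved <- strsplit(c1$edits$markers, ",")[[1]]
  expect_length(moved, 1L)
  others_before <- setdiff(g$marker, moved)
  others_after <- setdiff(c1$order$marker, moved)
  expect_identical(others_after, others_before)  # relative order unchanged
  expect_false(match(moved, c1$order$marker) == match(moved, g$marker))

  # relocating a ~10-marker segment breaks at most 3 adjacencies
  c2 <- corrupt_assembly_order(g, n_segment_relocations = 1,
                               segment_length_range_kb = c(901, 950),
                               seed = 63)
  seg <- strsplit(c2$edits$markers, ",")[[1]]
  expect_gte(length(seg), 9L)
  expect_lte(count_breakpoints(c2$order$marker, g$marker), 3L)

  # end placement moves a segment to the chromosome end
  c3 <- corrupt_assembly_order(g, n_end_placements = 1,
                               segment_length_range_kb = c(300, 500),
                               seed = 64)
  seg3 <- strsplit(c3$edits$markers, ",")[[1]]
  tailing <- utils::tail(c3$order$marker, length(seg3))
  expect_identical(tailing, seg3)

  expect_error(
    corrupt_assembly_order(g, n_segment_relocations = 1,
                           segment_length_range_kb = c(20000, 30000),
                           seed = 65),
    "exceeds the chromosome"
  )
})
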