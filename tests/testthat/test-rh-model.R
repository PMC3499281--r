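calls_from_matrix <- function(mat, panel = "RH1") {
  tibble::tibble(
    marker = rep(colnames(mat), each = nrow(mat)),
    panel = panel,
    clone = rep(sprintf("c%03d", seq_len(nrow(mat))), ncol(mat)),
    call = as.integer(mat)
  )
}

test_that("two_point reproduces closed-form results", {
  # identical vectors, 45 present of 90: theta -> 0, lod = 90 log10(2)
  v <- c(rep(1L, 45), rep(0L, 45))
  mat <- cbind(m1 = v, m2 = v)
  tp <- two_point(calls_from_matrix(mat))
  expect_lt(tp$theta_hat, 1e-4)
  expect_equal(tp$r_hat, 0.5, tolerance = 1e-4)
  expect_equal(tp$lod, -(45 * log10(0.5) + 45 * log10(0.5)),
               tolerance = 1e-3)
  expect_equal(tp$lod, 27.09, tolerance = 1e-2)

  # counts exactly at independence: theta -> 1, lod = 0
  r <- 0.5; n <- 400
  m1 <- c(rep(1L, 200), rep(0L, 200))
  m2 <- c(rep(1L, 100), rep(0L, 100), rep(1L, 100), rep(0L, 100))
  tp0 <- two_point(calls_from_matrix(cbind(a = m1, b = m2)))
  expect_gt(tp0$theta_hat, 0.999)
  expect_lt(tp0$lod, 1e-6)
})

test_that("two_point maximum matches a brute-force grid search", {
  set.seed(101)
  g <- simulate_genome(1, chrom_kb = 300, n_markers = 2)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 200, retention = 0.3),
                           keep_fragments = FALSE, seed = 102)
  tp <- two_point(sim$calls)
  ll_grid <- function(th, r) {
    p11 <- r * (1 - th) + r^2 * th
    p10 <- r * th * (1 - r)
    p00 <- (1 - r) * (1 - th) + (1 - r)^2 * th
    tp$n11 * log(p11) + (tp$n10 + tp$n01) * log(p10) + tp$n00 * log(p00)
  }
  grid <- expand.grid(th = seq(0.005, 0.995, by = 0.005),
                      r = seq(0.005, 0.995, by = 0.005))
  best <- max(mapply(ll_grid, grid$th, grid$r))
  expect_gte(tp$loglik + 1e-6, best)
})

test_that("two_point recovers simulation parameters", {
  g <- simulate_genome(1, chrom_kb = 271.82, n_markers = 2)
  # spacing = 90.6 Kb at 8.6 Kb/cR gives theta = 0.10
  d_cr <- diff(g$pos_kb) / 8.6
  expect_equal(1 - exp(-d_cr / 100), 0.1, tolerance = 1e-3)
  est <- sapply(1:3, function(i) {
    sim <- simulate_rh_panel(
      g, panel_config(n_clones = 10000, kb_per_cr = 8.6, retention = 0.3),
      keep_fragments = FALSE, seed = 110 + i)
    tp <- two_point(sim$calls)
    c(tp$theta_hat, tp$r_hat)
  })
  expect_lt(abs(mean(est[1, ]) - 0.10), 0.01)
  expect_lt(abs(mean(est[2, ]) - 0.30), 0.01)
})

test_that("errors: no overlapping clones and insufficient overlap", {
  calls <- tibble::tibble(
    marker = rep(c("a", "b"), each = 4),
    panel = "RH1",
    clone = c(paste0("c", 1:4), paste0("c", 5:8)),
    call = c(1L, 0L, 1L, 0L, NA, NA, NA, NA)
  )
  expect_error(two_point(calls), "no overlap")
})

test_that("multipoint likelihood agrees with path-enumeration oracle", {
  set.seed(120)
  for (rep in 1:3) {
    m <- sample(3:6, 1)
    n <- 12
    mat <- matrix(sample(c(0L, 1L, NA), m * n, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), n, m)
    theta <- runif(m - 1, 0.05, 0.6)
    r <- runif(1, 0.2, 0.5)
    ll_cpp <- rhmapper:::cpp_rh_loglik(mat, theta, r, 0)
    ll_oracle <- oracle_loglik(mat, theta, r)
    expect_equal(ll_cpp, ll_oracle, tolerance = 1e-10)
    # exact reversal symmetry of the chain
    ll_rev <- rhmapper:::cpp_rh_loglik(mat[, m:1, drop = FALSE],
                                       rev(theta), r, 0)
    expect_equal(ll_cpp, ll_rev, tolerance = 1e-9)
  }
})

test_that("EM increases the likelihood above naive initial values", {
  g <- tiny_genome(n_markers = 5, spacing_kb = 120)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 90), seed = 121)
  fit <- multipoint_loglik(sim$calls, g$marker, panel = "RH1")
  expect_true(fit$converged)
  mat <- rhmapper:::calls_matrix(sim$calls, g$marker)
  ll_init <- rhmapper:::cpp_rh_loglik(mat, rep(0.2, 4), 0.3, 0)
  expect_gte(fit$loglik, ll_init)
})

test_that("two-marker multipoint equals the two-point likelihood", {
  g <- simulate_genome(1, chrom_kb = 300, n_markers = 2)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 150),
                           keep_fragments = FALSE, seed = 122)
  tp <- two_point(sim$calls)
  mp <- multipoint_loglik(sim$calls, g$marker, panel = "RH1")
  expect_equal(mp$loglik, tp$loglik, tolerance = 1e-4)
  expect_equal(mp$theta, tp$theta_hat, tolerance = 1e-3)
  expect_equal(mp$r, tp$r_hat, tolerance = 1e-3)
})

test_that("fitted multipoint likelihood is reversal-symmetric", {
  g <- tiny_genome(n_markers = 6, spacing_kb = 150)
  sim <- simulate_rh_panel(g, panel_config(n_clones = 60), seed = 123)
  f1 <- multipoint_loglik(sim$calls, g$marker, panel = "RH1")
  f2 <- multipoint_loglik(sim$calls, rev(g$marker), panel = "RH1")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$theta, rev(f2$theta), tolerance = 1e-4)
  expect_error(multipoint_loglik(sim$calls, c(g$marker, "nope")),
               "permutation")
})

test_that("centiRay conversion and breakpoint counting are exact", {
  expect_equal(-100 * log(1 - 0.1), 10.536, tolerance = 1e-3)
  ref <- paste0("m", 1:10)
  expect_equal(count_breakpoints(ref, ref), 0L)
  # one interior marker moved elsewhere breaks 3 adjacencies
  moved <- c("m1", "m2", "m3", "m5", "m6", "m7", "m4", "m8", "m9", "m10")
  expect_equal(count_breakpoints(moved, ref), 3L)
  expect_error(count_breakpoints(c("m1", "zz"), ref), "zz")
})

test_that("LOD-6 linkage grouping separates distant clusters", {
  # two clusters on one chromosome: dense within, a huge gap between
  g <- simulate_genome(1, chrom_kb = 50000, n_markers = 24)
  pos <- c(seq(100, 1200, by = 100), seq(45000, 46100, by = 100))
  g$pos_kb <- pos
  calls <- two_panel_calls(g, n_clones = 90, seed = 130)
  grp <- build_linkage_groups(calls, min_lod = 6, min_size = 10)
  expect_equal(grp$n_groups, 2L)
  got <- grp$groups
  g1 <- got$marker[got$group == got$group[match(g$marker[1], got$marker)]]
  expect_setequal(g1, g$marker[1:12])

  # a small mutually linked cluster (size <= 10) is discarded
  g_small <- simulate_genome(1, chrom_kb = 600, n_markers = 5)
  calls_small <- two_panel_calls(g_small, n_clones = 90, seed = 131)
  grp_small <- build_linkage_groups(calls_small)
  expect_equal(grp_small$n_groups, 0L)
  expect_setequal(grp_small$unlinked$marker, g_small$marker)
  expect_true(all(grp_small$unlinked$reason == "small_group"))

  # empty input
  empty <- build_linkage_groups(calls[0, ])
  expect_equal(empty$n_groups, 0L)
})

test_that("comparative score combines likelihoods and breakpoint penalty", {
  g <- tiny_genome(n_markers = 5, spacing_kb = 200)
  calls <- two_panel_calls(g, n_clones = 40, seed = 140)
  cs_ref <- comparative_score(calls, g$marker, g$marker, lambda = 3 * log(10))
  expect_equal(cs_ref$breakpoints, 0L)

  scr <- c(g$marker[c(1, 3, 4, 2, 5)])
  cs0 <- comparative_score(calls, scr, g$marker, lambda = 0)
  expect_equal(cs0$score, sum(cs0$loglik_by_panel))
  cs1 <- comparative_score(calls, scr, g$marker, lambda = 2)
  expect_equal(cs1$score, sum(cs1$loglik_by_panel) - 2 * cs1$breakpoints)
  expect_equal(cs1$breakpoints, 3L)
})

test_that("order_search attains the exhaustive optimum on 6 markers", {
  g <- tiny_genome(n_markers = 6, spacing_kb = 250)
  calls <- two_panel_calls(g, n_clones = 90, seed = 150)
  lam <- 3 * log(10)
  perms <- all_perms(6)
  scores <- vapply(perms, function(p) {
    comparative_score(calls, g$marker[p], g$marker, lambda = lam,
                      max_iter = 100)$score
  }, numeric(1))
  best <- max(scores)

  scrambled <- g$marker[c(4, 1, 6, 3, 2, 5)]
  map <- order_search(calls, g$marker, initial = scrambled, lambda = lam)
  expect_equal(attr(map, "score"), best, tolerance = 1e-4)
  best_perm <- perms[[which.max(scores)]]
  expect_true(perm_key(match(map$marker, g$marker)) == perm_key(best_perm))
})

test_that("search keeps a perfect initial order and a dominant prior", {
  g <- tiny_genome(n_markers = 6, spacing_kb = 300)
  calls <- two_panel_calls(g, n_clones = 90, seed = 151)
  map <- order_search(calls, g$marker, lambda = 3 * log(10))
  expect_identical(map$marker, g$marker)

  # with a dominant prior the reference order wins regardless of the data
  fake_ref <- g$marker[c(3, 6, 1, 4, 2, 5)]
  map_prior <- order_search(calls, fake_ref, lambda = 1e3)
  expect_identical(map_prior$marker, fake_ref)
})

test_that("map positions accumulate interval distances per panel", {
  g <- tiny_genome(n_markers = 5, spacing_kb = 200)
  calls <- two_panel_calls(g, n_clones = 90, seed = 152)
  map <- order_search(calls, g$marker)
  expect_true(all(diff(map$pos_cr_rh1) >= 0))
  expect_true(all(diff(map$pos_cr_rh2) >= 0))
  fit <- multipoint_loglik(calls, map$marker, panel = "RH1")
  expect_equal(map$pos_cr_rh1, cumsum(c(0, fit$d_cr)), tolerance = 1e-8)
  gl <- glance(map)
  expect_equal(gl$n_markers, 5L)
})
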