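# shared fixtures and independent oracles

# a small genome with evenly spaced markers
tiny_genome <- function(n_markers = 5, spacing_kb = 100, n_chrom = 1) {
  simulate_genome(n_chromosomes = n_chrom,
                  chrom_kb = spacing_kb * (n_markers + 1),
                  n_markers = n_markers)
}

# two-panel calls for a genome at the pig panel resolutions
two_panel_calls <- function(genome, n_clones = 90, retention = 0.3,
                            seed = 1) {
  s1 <- simulate_rh_panel(
    genome, panel_config(n_clones, 8.6, retention), panel = "RH1",
    keep_fragments = FALSE, seed = seed)
  s2 <- simulate_rh_panel(
    genome, panel_config(n_clones, 5.3, retention), panel = "RH2",
    keep_fragments = FALSE, seed = seed + 1000)
  dplyr::bind_rows(s1$calls, s2$calls)
}

# brute-force multipoint log-likelihood by enumerating all 2^m hidden
# retention paths per clone (independent of the C++ forward algorithm)
oracle_loglik <- function(mat, theta, r, eps = 0) {
  m <- ncol(mat)
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  path_prob <- apply(states, 1, function(s) {
    p <- if (s[1] == 1) r else 1 - r
    for (k in seq_len(m - 1)) {
      th <- theta[k]
      p <- p * if (s[k] == s[k + 1]) {
        (1 - th) + th * (if (s[k + 1] == 1) r else 1 - r)
      } else {
        th * (if (s[k + 1] == 1) r else 1 - r)
      }
    }
    p
  })
  ll <- 0
  for (ci in seq_len(nrow(mat))) {
    obs <- mat[ci, ]
    lik <- sum(path_prob * apply(states, 1, function(s) {
      pr <- 1
      for (k in seq_len(m)) {
        if (is.na(obs[k])) next
        pr <- pr * if (obs[k] == s[k]) 1 - eps else eps
      }
      pr
    }))
    ll <- ll + log(lik)
  }
  ll
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# canonical key of an order up to reversal
perm_key <- function(p) {
  a <- paste(p, collapse = ".")
  b <- paste(rev(p), collapse = ".")
  if (a < b) a else b
}
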