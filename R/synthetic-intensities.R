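#' Intensity model for simulated two-channel SNP-array signals
#'
#' Present and absent calls are emitted from two bivariate log-normal
#' clusters (heavy-tailed positive intensities), each SNP carrying a
#' multiplicative log-normal shift shared by all its samples. Draws are
#' truncated to the calling region of their cluster, so that with
#' `overlap = 0` the fixed thresholds recover the truth exactly; a
#' configurable `overlap` fraction of calls is instead emitted in the
#' intermediate zone between the absent and present cutoffs and will be
#' called missing. A configurable fraction of SNPs cross-hybridizes with
#' the hamster genomic background and is guaranteed to exceed the hamster
#' control thresholds.
#'
#' @param present_mean,absent_mean Arithmetic mean `c(x=, y=)` intensities
#'   of the two clusters, in arbitrary fluorescence units.
#' @param sdlog Log-scale standard deviation of the clusters.
#' @param snp_shift_sdlog Log-scale SD of the per-SNP multiplicative shift.
#' @param overlap Fraction of (SNP, clone) calls emitted in the
#'   intermediate (missing) intensity zone.
#' @param crosshyb_frac Fraction of SNPs that cross-hybridize in hamster.
#' @param genomic_negative_frac,genomic_dubious_frac Fractions of SNPs
#'   whose genomic control is negative (absent-like) or dubious
#'   (intermediate).
#' @return A list of class `rh_intensity_model`.
#' @export
intensity_model <- function(present_mean = c(x = 6000, y = 12000),
                            absent_mean = c(x = 500, y = 800),
                            sdlog = 0.35, snp_shift_sdlog = 0.08,
                            overlap = 0, crosshyb_frac = 0,
                            genomic_negative_frac = 0,
                            genomic_dubious_frac = 0) {
  for (nm in c("present_mean", "absent_mean")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0)) {
      abort(sprintf("`%s` must be two positive numbers c(x=, y=).", nm))
    }
  }
  if (sdlog < 0 || snp_shift_sdlog < 0) {
    abort("`sdlog` and `snp_shift_sdlog` must be non-negative.")
  }
  assert_prob(overlap, "overlap", open_right = TRUE)
  assert_prob(crosshyb_frac, "crosshyb_frac", open_right = TRUE)
  assert_prob(genomic_negative_frac, "genomic_negative_frac", open_right = TRUE)
  assert_prob(genomic_dubious_frac, "genomic_dubious_frac", open_right = TRUE)
  structure(
    list(present_mean = present_mean, absent_mean = absent_mean,
         sdlog = sdlog, snp_shift_sdlog = snp_shift_sdlog, overlap = overlap,
         crosshyb_frac = crosshyb_frac,
         genomic_negative_frac = genomic_negative_frac,
         genomic_dubious_frac = genomic_dubious_frac),
    class = "rh_intensity_model"
  )
}

# log-normal draw with a given arithmetic mean, rejected into a region
rlnorm_trunc <- function(n, mean, sdlog, accept, max_tries = 200L) {
  mu <- log(mean) - sdlog^2 / 2
  x <- rlnorm(n, mu, sdlog)
  bad <- which(!accept(x))
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    x[bad] <- rlnorm(length(bad), mu, sdlog)
    bad <- bad[!accept(x[bad])]
    tries <- tries + 1L
  }
  x
}

#' Simulate raw X/Y array intensities from true retention states
#'
#' Given true presence/absence calls (e.g. `true_calls` from
#' [simulate_rh_panel()], possibly both panels bound together), emits one
#' X/Y intensity pair per (SNP, clone) plus one hamster control sample and
#' one genomic control sample, following the configured
#' [intensity_model()]. The designed cross-hybridizing SNPs and genomic
#' control statuses are recorded for test assertions, as are the cluster
#' means.
#'
#' @param truth Tibble with columns `marker`, `clone`, `call` (1/0).
#' @param model An [intensity_model()].
#' @param thresholds A [calling_thresholds()] object defining the calling
#'   regions the clusters are truncated to.
#' @param hamster_id,genomic_id Sample identifiers of the two controls.
#' @param seed Optional integer seed.
#' @return A list of class `rh_intensity_sim` with elements `intensities`
#'   (tibble `marker`, `sample`, `x`, `y`), `meta` (per-SNP cluster means,
#'   cross-hybridization flag, designed genomic status), `controls`,
#'   `model`, `seed`.
#' @export
simulate_intensities <- function(truth, model = intensity_model(),
                                 thresholds = calling_thresholds(),
                                 hamster_id = "hamster",
                                 genomic_id = "genomic", seed = NULL) {
  assert_columns(truth, c("marker", "clone", "call"), "`truth`")
  if (nrow(truth) == 0L) abort("`truth` is empty.")
  if (any(is.na(truth$call))) {
    abort("`truth` must contain error-free 0/1 calls (no NA).")
  }
  th <- thresholds
  markers <- unique(truth$marker)
  nm <- length(markers)

  in_present <- function(x, y) x > th$present_x_min | y > th$present_y_min
  in_absent <- function(x, y) x < th$absent_x_max & y < th$absent_y_max
  in_hamster_ok <- function(x, y) x < th$hamster_x_max & y < th$hamster_y_max

  with_seed_(seed, {
    shift <- exp(rnorm(nm, 0, model$snp_shift_sdlog))
    names(shift) <- markers
    crosshyb <- markers[runif(nm) < model$crosshyb_frac]
    u <- runif(nm)
    genomic_status <- rep("positive", nm)
    genomic_status[u < model$genomic_negative_frac] <- "negative"
    genomic_status[u >= model$genomic_negative_frac &
                   u < model$genomic_negative_frac +
                       model$genomic_dubious_frac] <- "dubious"
    names(genomic_status) <- markers

    draw_cluster <- function(mk, cluster) {
      n <- length(mk)
      s <- shift[mk]
      px <- model$present_mean[["x"]] * s
      py <- model$present_mean[["y"]] * s
      ax <- model$absent_mean[["x"]] * s
      ay <- model$absent_mean[["y"]] * s
      out <- matrix(0, n, 2)
      if (cluster == "present") {
        # truncation to the present region is a joint condition on (x, y);
        # draw y first, then x conditional on the region being reachable
        y <- rlnorm(n, log(py) - model$sdlog^2 / 2, model$sdlog)
        x <- rlnorm(n, log(px) - model$sdlog^2 / 2, model$sdlog)
        bad <- which(!in_present(x, y))
        tries <- 0L
        while (length(bad) > 0L && tries < 200L) {
          y[bad] <- rlnorm(length(bad), log(py[bad]) - model$sdlog^2 / 2,
                           model$sdlog)
          x[bad] <- rlnorm(length(bad), log(px[bad]) - model$sdlog^2 / 2,
                           model$sdlog)
          bad <- bad[!in_present(x[bad], y[bad])]
          tries <- tries + 1L
        }
        if (length(bad) > 0L) {
          x[bad] <- th$present_x_min * 1.05
          y[bad] <- th$present_y_min * 1.05
        }
        out[, 1] <- x; out[, 2] <- y
      } else if (cluster == "absent") {
        mu_x <- log(ax) - model$sdlog^2 / 2
        mu_y <- log(ay) - model$sdlog^2 / 2
        x <- rlnorm(n, mu_x, model$sdlog)
        y <- rlnorm(n, mu_y, model$sdlog)
        bad <- which(!in_absent(x, y))
        tries <- 0L
        while (length(bad) > 0L && tries < 200L) {
          x[bad] <- rlnorm(length(bad), mu_x[bad], model$sdlog)
          y[bad] <- rlnorm(length(bad), mu_y[bad], model$sdlog)
          bad <- bad[!in_absent(x[bad], y[bad])]
          tries <- tries + 1L
        }
        if (length(bad) > 0L) {
          x[bad] <- th$absent_x_max * 0.5
          y[bad] <- th$absent_y_max * 0.5
        }
        out[, 1] <- x; out[, 2] <- y
      } else { # intermediate zone: called missing by construction
        out[, 1] <- runif(n, th$absent_x_max, th$present_x_min)
        out[, 2] <- runif(n, th$absent_y_max, th$present_y_min)
      }
      out
    }

    # RH clone signals
    cl <- ifelse(truth$call == 1L, "present", "absent")
    if (model$overlap > 0) {
      cl[runif(nrow(truth)) < model$overlap] <- "intermediate"
    }
    xy <- matrix(0, nrow(truth), 2)
    for (g in unique(cl)) {
      idx <- which(cl == g)
      xy[idx, ] <- draw_cluster(truth$marker[idx], g)
    }
    rh <- tibble(marker = truth$marker, sample = truth$clone,
                 x = xy[, 1], y = xy[, 2])

    # hamster control: background for ordinary SNPs, present-like signal
    # for designed cross-hybridizers (guaranteed above the thresholds)
    ham_ok <- setdiff(markers, crosshyb)
    mu_bx <- log(model$absent_mean[["x"]] * 0.5) - model$sdlog^2 / 2
    mu_by <- log(model$absent_mean[["y"]] * 0.5) - model$sdlog^2 / 2
    hx <- rlnorm(length(ham_ok), mu_bx, model$sdlog)
    hy <- rlnorm(length(ham_ok), mu_by, model$sdlog)
    bad <- which(!in_hamster_ok(hx, hy))
    tries <- 0L
    while (length(bad) > 0L && tries < 200L) {
      hx[bad] <- rlnorm(length(bad), mu_bx, model$sdlog)
      hy[bad] <- rlnorm(length(bad), mu_by, model$sdlog)
      bad <- bad[!in_hamster_ok(hx[bad], hy[bad])]
      tries <- tries + 1L
    }
    if (length(bad) > 0L) {
      hx[bad] <- th$hamster_x_max * 0.4
      hy[bad] <- th$hamster_y_max * 0.4
    }
    ham <- bind_rows(
      tibble(marker = ham_ok, sample = hamster_id, x = hx, y = hy),
      if (length(crosshyb) > 0) {
        xyc <- draw_cluster(crosshyb, "present")
        tibble(marker = crosshyb, sample = hamster_id,
               x = pmax(xyc[, 1], th$hamster_x_max * 1.2),
               y = xyc[, 2])
      }
    )

    # genomic control
    gen <- purrr::map(c("positive", "negative", "dubious"), function(st) {
      mk <- markers[genomic_status == st]
      if (length(mk) == 0L) return(NULL)
      xyg <- draw_cluster(mk, switch(st, positive = "present",
                                     negative = "absent",
                                     dubious = "intermediate"))
      tibble(marker = mk, sample = genomic_id, x = xyg[, 1], y = xyg[, 2])
    }) |> purrr::compact() |> purrr::list_rbind()

    meta <- tibble(
      marker = markers,
      shift = unname(shift),
      present_x = model$present_mean[["x"]] * unname(shift),
      present_y = model$present_mean[["y"]] * unname(shift),
      absent_x = model$absent_mean[["x"]] * unname(shift),
      absent_y = model$absent_mean[["y"]] * unname(shift),
      crosshyb = markers %in% crosshyb,
      genomic_status = unname(genomic_status)
    )

    structure(
      list(
        intensities = bind_rows(rh, ham, gen),
        meta = meta,
        controls = c(hamster = hamster_id, genomic = genomic_id),
        model = model, seed = seed
      ),
      class = "rh_intensity_sim"
    )
  })
}

#' @export
tidy.rh_intensity_sim <- function(x, ...) x$intensities

#' @export
print.rh_intensity_sim <- function(x, ...) {
  cat(sprintf(
    "<rh_intensity_sim> %d SNPs x %d samples (%d cross-hybridizing)\n",
    length(unique(x$intensities$marker)),
    length(unique(x$intensities$sample)), sum(x$meta$crosshyb)
  ))
  invisible(x)
}
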