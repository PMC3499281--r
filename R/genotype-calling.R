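#' Fixed thresholds for presence/absence genotype calling
#'
#' The calling procedure for RH genotypes works on raw two-channel
#' intensities: a signal is called absent when both channels are low,
#' present when either channel is high, and missing in between. SNPs are
#' discarded when the hamster (negative) control shows signal, or when the
#' mean signal over RH clones is too weak to discriminate presence from
#' absence. All comparisons are strict (`<`, `>`): values equal to a
#' cutoff fall into the missing zone.
#'
#' @param hamster_x_max,hamster_y_max A SNP is discarded when the hamster
#'   control exceeds either value (cross-hybridization).
#' @param rh_mean_x_min,rh_mean_y_min A SNP is discarded when its mean
#'   intensity over RH clones falls below either value (no discrimination
#'   power).
#' @param absent_x_max,absent_y_max A call is absent when x and y are both
#'   below these.
#' @param present_x_min,present_y_min A call is present when x or y is
#'   above these.
#' @param max_missing Maximum tolerated number of missing calls per SNP
#'   over `panel_size` clones ("more than `max_missing`" is discarded);
#'   scaled proportionally (rounded up) for panels of other sizes.
#' @param panel_size Clone count the `max_missing` cutoff refers to.
#' @return A list of class `rh_calling_thresholds`.
#' @export
calling_thresholds <- function(hamster_x_max = 500, hamster_y_max = 1000,
                               rh_mean_x_min = 1500, rh_mean_y_min = 3000,
                               absent_x_max = 1000, absent_y_max = 1300,
                               present_x_min = 1500, present_y_min = 2000,
                               max_missing = 10, panel_size = 180) {
  if (absent_x_max >= present_x_min || absent_y_max >= present_y_min) {
    abort("Absent cutoffs must lie strictly below present cutoffs.")
  }
  vals <- c(hamster_x_max, hamster_y_max, rh_mean_x_min, rh_mean_y_min,
            absent_x_max, absent_y_max, present_x_min, present_y_min)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All intensity thresholds must be finite and non-negative.")
  }
  max_missing <- assert_count(max_missing, "max_missing")
  panel_size <- assert_count(panel_size, "panel_size", min = 1L)
  structure(
    list(hamster_x_max = hamster_x_max, hamster_y_max = hamster_y_max,
         rh_mean_x_min = rh_mean_x_min, rh_mean_y_min = rh_mean_y_min,
         absent_x_max = absent_x_max, absent_y_max = absent_y_max,
         present_x_min = present_x_min, present_y_min = present_y_min,
         max_missing = max_missing, panel_size = panel_size),
    class = "rh_calling_thresholds"
  )
}

#' Call a presence/absence genotype from a two-channel intensity
#'
#' Deterministic partition of the intensity plane: absent iff
#' `x < absent_x_max` and `y < absent_y_max`; present iff
#' `x > present_x_min` or `y > present_y_min`; missing otherwise.
#' Vectorized over `x` and `y`.
#'
#' @param x,y Non-negative intensities (arbitrary fluorescence units).
#' @param thresholds A [calling_thresholds()] object.
#' @return Character vector in `c("present", "absent", "missing")`.
#' @export
#' @examples
#' call_genotype(c(900, 1600, 1200), c(1200, 0, 1500))
call_genotype <- function(x, y, thresholds = calling_thresholds()) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    abort("Intensities must be finite and non-negative.")
  }
  th <- thresholds
  out <- rep("missing", length(x))
  out[x < th$absent_x_max & y < th$absent_y_max] <- "absent"
  out[x > th$present_x_min | y > th$present_y_min] <- "present"
  out
}

#' Filter SNPs on control samples
#'
#' Rejects a SNP when the hamster negative control shows signal above the
#' hamster thresholds (`hamster_crosshyb`) or when its mean intensity over
#' RH clones is below the discrimination thresholds (`low_signal`). Extra
#' control samples with the same id are averaged.
#'
#' @param intensities Tibble `marker`, `sample`, `x`, `y` including the
#'   hamster control sample and at least one RH clone per SNP.
#' @param thresholds A [calling_thresholds()] object.
#' @param hamster_id,genomic_id Sample ids of the controls; the genomic
#'   control is excluded from the RH-clone mean.
#' @return Tibble `marker`, `retained`, `reason` (`NA` when retained).
#' @export
filter_snps_by_controls <- function(intensities,
                                    thresholds = calling_thresholds(),
                                    hamster_id = "hamster",
                                    genomic_id = "genomic") {
  assert_columns(intensities, c("marker", "sample", "x", "y"),
                 "`intensities`")
  th <- thresholds
  ham <- intensities |>
    filter(.data$sample == hamster_id) |>
    group_by(.data$marker) |>
    summarise(ham_x = mean(.data$x), ham_y = mean(.data$y), .groups = "drop")
  missing_ham <- setdiff(unique(intensities$marker), ham$marker)
  if (length(missing_ham) > 0L) {
    abort(sprintf(
      "No hamster control sample ('%s') for %d SNP(s): %s%s.",
      hamster_id, length(missing_ham),
      paste(head(missing_ham, 5), collapse = ", "),
      if (length(missing_ham) > 5) ", ..." else ""
    ))
  }
  rh_mean <- intensities |>
    filter(!.data$sample %in% c(hamster_id, genomic_id)) |>
    group_by(.data$marker) |>
    summarise(mean_x = mean(.data$x), mean_y = mean(.data$y),
              .groups = "drop")
  if (nrow(rh_mean) == 0L) abort("No RH clone samples found.")

  ham |>
    left_join(rh_mean, by = "marker") |>
    mutate(
      reason = dplyr::case_when(
        .data$ham_x > th$hamster_x_max | .data$ham_y > th$hamster_y_max ~
          "hamster_crosshyb",
        .data$mean_x < th$rh_mean_x_min | .data$mean_y < th$rh_mean_y_min ~
          "low_signal",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason)
    ) |>
    select("marker", "retained", "reason")
}

#' Build RH presence/absence vectors from raw intensities
#'
#' Full calling pipeline: control-based SNP filters
#' ([filter_snps_by_controls()]), per-call thresholding
#' ([call_genotype()]), elimination of SNPs whose genomic control is
#' negative or dubious, and elimination of SNPs with too many missing
#' calls. The missing-call cutoff is `max_missing` over `panel_size`
#' clones; for panels of a different size it scales as
#' `ceiling(max_missing / panel_size * n_clones)` and the scaling is
#' recorded in the report.
#'
#' @inheritParams filter_snps_by_controls
#' @param genomic_status Optional per-SNP genomic-control status tibble
#'   (`marker`, `status` in positive/negative/dubious). By default the
#'   status is derived from the genomic control sample's own call
#'   (present = positive, absent = negative, missing = dubious).
#' @param clone_panels Optional tibble `clone`, `panel` splitting RH
#'   clones into panels; by default all clones form panel `"RH1"`.
#' @return A list of class `rh_call_set`: `calls` (tibble `marker`,
#'   `panel`, `clone`, `call` 1/0/NA, only retained SNPs), `report` (one
#'   row per SNP with `retained` and `reason`), `summary` (counts per
#'   reason), `missing_cutoff`.
#' @export
build_rh_vectors <- function(intensities, thresholds = calling_thresholds(),
                             hamster_id = "hamster", genomic_id = "genomic",
                             genomic_status = NULL, clone_panels = NULL) {
  th <- thresholds
  ctrl <- filter_snps_by_controls(intensities, th, hamster_id, genomic_id)

  rh <- intensities |>
    filter(!.data$sample %in% c(hamster_id, genomic_id))
  n_clones <- length(unique(rh$sample))
  if (n_clones != th$panel_size) {
    warn(sprintf(
      "Clone count (%d) differs from thresholds panel_size (%d); the missing-call cutoff is scaled proportionally.",
      n_clones, th$panel_size
    ))
  }
  cutoff <- if (n_clones == th$panel_size) th$max_missing else
    as.integer(ceiling(th$max_missing / th$panel_size * n_clones))

  if (is.null(genomic_status)) {
    genomic_status <- intensities |>
      filter(.data$sample == genomic_id) |>
      group_by(.data$marker) |>
      summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
      mutate(status = dplyr::recode(call_genotype(.data$x, .data$y, th),
                                    present = "positive",
                                    absent = "negative",
                                    missing = "dubious")) |>
      select("marker", "status")
  } else {
    assert_columns(genomic_status, c("marker", "status"), "`genomic_status`")
  }

  calls <- rh |>
    mutate(call_chr = call_genotype(.data$x, .data$y, th),
           call = dplyr::case_when(.data$call_chr == "present" ~ 1L,
                                   .data$call_chr == "absent" ~ 0L,
                                   TRUE ~ NA_integer_)) |>
    rename(clone = "sample") |>
    select("marker", "clone", "call")

  n_missing <- calls |>
    group_by(.data$marker) |>
    summarise(n_missing = sum(is.na(.data$call)), .groups = "drop")

  report <- ctrl |>
    left_join(genomic_status, by = "marker") |>
    left_join(n_missing, by = "marker") |>
    mutate(
      reason = dplyr::case_when(
        !is.na(.data$reason) ~ .data$reason,
        .data$status %in% "negative" ~ "genomic_negative",
        .data$status %in% "dubious" ~ "genomic_dubious",
        .data$n_missing > cutoff ~ "too_many_missing",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason)
    ) |>
    select("marker", "retained", "reason", "n_missing")

  kept <- report$marker[report$retained]
  calls <- calls |> filter(.data$marker %in% kept)
  if (is.null(clone_panels)) {
    calls$panel <- "RH1"
  } else {
    assert_columns(clone_panels, c("clone", "panel"), "`clone_panels`")
    calls <- calls |> left_join(clone_panels, by = "clone")
    if (any(is.na(calls$panel))) {
      abort("`clone_panels` does not cover all clones.")
    }
  }
  calls <- calls |> select("marker", "panel", "clone", "call")

  structure(
    list(
      calls = calls,
      report = report,
      summary = report |>
        mutate(reason = if_else(.data$retained, "retained", .data$reason)) |>
        count(.data$reason, name = "n_snps"),
      missing_cutoff = cutoff,
      n_clones = n_clones
    ),
    class = "rh_call_set"
  )
}

#' @export
tidy.rh_call_set <- function(x, ...) x$calls

#' @export
glance.rh_call_set <- function(x, ...) {
  tibble(
    n_snps_in = nrow(x$report),
    n_snps_retained = sum(x$report$retained),
    n_clones = x$n_clones,
    missing_cutoff = x$missing_cutoff
  )
}

#' @export
print.rh_call_set <- function(x, ...) {
  cat(sprintf("<rh_call_set> %d/%d SNPs retained over %d clones\n",
              sum(x$report$retained), nrow(x$report), x$n_clones))
  print(x$summary)
  invisible(x)
}
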