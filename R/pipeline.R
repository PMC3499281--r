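#' Configuration for the end-to-end synthetic RH mapping pipeline
#'
#' Bundles every tunable of [run_rh_pipeline()] with defaults emulating
#' the two-panel pig design at desk scale: two 90-clone panels at 8.6
#' and 5.3 Kb/cR, retention 0.3, fixed calling thresholds, LOD-6 linkage
#' groups, a comparative search against a corrupted assembly prior,
#' 5000-iteration MCMC with 1000 burn-in for robust maps, 263 half-sib
#' families totalling 728 meioses for genetic validation, and hold-out
#' placement of a fraction of mapped SNPs.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chromosomes,chrom_kb,n_markers Genome layout.
#' @param panels An [rh_panels()] tibble (one row per panel).
#' @param intensity An [intensity_model()].
#' @param thresholds A [calling_thresholds()].
#' @param corruption List of arguments to [corrupt_assembly_order()]
#'   describing how the draft assembly differs from the truth.
#' @param lambda Breakpoint penalty of the comparative criterion.
#' @param min_lod,min_group_size Linkage-group construction parameters.
#' @param mcmc List with `n_iter`, `burnin`, `eta`.
#' @param families List with `n_families`, `n_meioses`, `total_cm`.
#' @param placement List with `holdout_frac`, `threshold`, `n_rep`.
#' @param out_dir Optional directory; when given, every stage writes its
#'   TSV outputs there.
#' @return A list of class `rh_pipeline_config`.
#' @export
rh_pipeline_config <- function(seed = 1,
                               n_chromosomes = 2, chrom_kb = 2000,
                               n_markers = 40,
                               panels = rh_panels(),
                               intensity = intensity_model(
                                 overlap = 0.01, crosshyb_frac = 0.03,
                                 genomic_negative_frac = 0.01,
                                 genomic_dubious_frac = 0.01),
                               thresholds = calling_thresholds(),
                               corruption = list(
                                 n_single_misplacements = 1,
                                 n_segment_relocations = 1,
                                 segment_length_range_kb = c(300, 600),
                                 n_end_placements = 0),
                               lambda = 3 * log(10),
                               min_lod = 6, min_group_size = 10,
                               mcmc = list(n_iter = 5000, burnin = 1000,
                                           eta = 0.95),
                               families = list(n_families = 263,
                                               n_meioses = 728,
                                               total_cm = 70),
                               placement = list(holdout_frac = 0.1,
                                                threshold = 7,
                                                n_rep = 200),
                               out_dir = NULL) {
  structure(
    list(seed = seed, n_chromosomes = n_chromosomes, chrom_kb = chrom_kb,
         n_markers = n_markers, panels = panels, intensity = intensity,
         thresholds = thresholds, corruption = corruption, lambda = lambda,
         min_lod = min_lod, min_group_size = min_group_size, mcmc = mcmc,
         families = families, placement = placement, out_dir = out_dir),
    class = "rh_pipeline_config"
  )
}

#' Run the full synthetic RH mapping pipeline
#'
#' Executes the stages in order on simulated data with known ground
#' truth: simulate genome and panels, simulate intensities, call
#' genotypes, build linkage groups, build comparative maps against a
#' corrupted assembly prior, extract robust maps by MCMC, validate the
#' orders with half-sib genetic data, and re-place held-out SNPs. A
#' machine-readable report records marker counts at each stage per
#' chromosome; the run is fully reproducible from the master seed.
#'
#' @param config An [rh_pipeline_config()].
#' @return A list of class `rh_pipeline_result` with elements `report`,
#'   `genome`, `reference` (corrupted assembly order), `call_set`,
#'   `groups`, `maps`, `robust`, `validation`, `placements`,
#'   `placement_eval` and `config`.
#' @export
run_rh_pipeline <- function(config = rh_pipeline_config()) {
  if (!inherits(config, "rh_pipeline_config")) {
    abort("`config` must come from rh_pipeline_config().")
  }
  seed <- config$seed
  report <- list()
  note <- function(stage, chrom, n) {
    report[[length(report) + 1L]] <<- tibble(stage = stage, chrom = chrom,
                                             n_markers = as.integer(n))
  }

  # 1. genome and true marker order
  genome <- simulate_genome(config$n_chromosomes, config$chrom_kb,
                            config$n_markers, seed = derive_seed(seed, 1))
  for (ch in unique(genome$chrom)) {
    note("simulated", ch, sum(genome$chrom == ch))
  }

  # 2. RH panels (true retention states)
  sims <- purrr::map(seq_len(nrow(config$panels)), function(i) {
    p <- config$panels[i, ]
    simulate_rh_panel(
      genome,
      panel_config(n_clones = p$n_clones, kb_per_cr = p$kb_per_cr,
                   retention = p$retention),
      panel = p$panel, keep_fragments = FALSE,
      seed = derive_seed(seed, 1 + i)
    )
  })
  truth_calls <- purrr::list_rbind(purrr::map(sims, "true_calls"))

  # 3. intensities over the combined clone set, then genotype calling
  intens <- simulate_intensities(truth_calls, config$intensity,
                                 config$thresholds,
                                 seed = derive_seed(seed, 10))
  clone_panels <- truth_calls |> distinct(.data$clone, .data$panel)
  call_set <- build_rh_vectors(intens$intensities, config$thresholds,
                               clone_panels = clone_panels)
  calls <- call_set$calls
  for (ch in unique(genome$chrom)) {
    mk <- genome$marker[genome$chrom == ch]
    note("called", ch, length(intersect(unique(calls$marker), mk)))
  }

  # 4. corrupted assembly order = the mapping prior
  corrupted <- corrupt_assembly_order(
    genome,
    n_single_misplacements = config$corruption$n_single_misplacements,
    n_segment_relocations = config$corruption$n_segment_relocations,
    segment_length_range_kb = config$corruption$segment_length_range_kb,
    n_end_placements = config$corruption$n_end_placements %||% 0,
    seed = derive_seed(seed, 20)
  )
  reference <- corrupted$order

  # 5. per chromosome: linkage groups, comparative map, robust map
  maps <- list(); robust <- list(); groups <- list()
  for (ch in unique(genome$chrom)) {
    mk <- genome$marker[genome$chrom == ch]
    ch_calls <- calls |> filter(.data$marker %in% mk)
    grp <- build_linkage_groups(ch_calls, min_lod = config$min_lod,
                                min_size = config$min_group_size)
    groups[[ch]] <- grp
    linked <- grp$groups$marker
    note("linked", ch, length(linked))
    if (length(linked) < 2L) next
    ref_ch <- reference |> filter(.data$chrom == ch,
                                  .data$marker %in% linked)
    map <- order_search(ch_calls |> filter(.data$marker %in% linked),
                        ref_ch, lambda = config$lambda)
    map$chrom <- ch
    maps[[ch]] <- map
    note("mapped", ch, nrow(map))

    samp <- mcmc_orders(ch_calls |> filter(.data$marker %in% linked),
                        ref_ch, initial = map$marker,
                        lambda = config$lambda,
                        n_iter = config$mcmc$n_iter,
                        burnin = config$mcmc$burnin,
                        seed = derive_seed(seed, 30 + match(ch, unique(genome$chrom))))
    rob <- extract_robust(samp, eta = config$mcmc$eta, calls = ch_calls)
    rob$map$chrom <- ch
    robust[[ch]] <- rob
    note("robust", ch, nrow(rob$map))
  }

  report_tbl <- purrr::list_rbind(report)

  # 6. genetic validation: robust-map order versus the corrupted assembly
  gen_map <- even_genetic_map(genome, config$families$total_cm)
  fams <- simulate_halfsib_families(
    genome, gen_map, n_families = config$families$n_families,
    n_meioses = config$families$n_meioses,
    seed = derive_seed(seed, 40)
  )
  validation <- NULL
  if (length(robust) > 0) {
    rh_order <- purrr::list_rbind(purrr::map(robust, function(r) {
      r$map[, c("chrom", "marker")]
    }))
    asm_order <- reference |>
      filter(.data$marker %in% rh_order$marker) |>
      select("chrom", "marker")
    validation <- compare_orders(fams$genotypes, asm_order, rh_order,
                                 labels = c("assembly", "rh_map"))
  }

  # 7. placement of held-out SNPs against the built maps
  placements <- NULL; placement_eval <- NULL
  if (length(maps) > 0) {
    full_map <- purrr::list_rbind(purrr::map(maps, as_tibble))
    full_map <- full_map |>
      mutate(ref_bp = round(genome$pos_kb[match(.data$marker,
                                                genome$marker)] * 1000))
    hold <- with_seed_(derive_seed(seed, 50), {
      sample(full_map$marker,
             max(2, round(nrow(full_map) * config$placement$holdout_frac)))
    })
    mapped_map <- full_map |> filter(!.data$marker %in% hold)
    usnp_calls <- calls |> filter(.data$marker %in% hold)
    mapped_calls <- calls |> filter(.data$marker %in% mapped_map$marker)
    low <- config$panels$panel[which.max(config$panels$kb_per_cr)]
    high <- config$panels$panel[which.min(config$panels$kb_per_cr)]
    placements <- place_usnps(
      usnp_calls, mapped_calls, mapped_map,
      low_panel = low, high_panel = high,
      pos_col = paste0("pos_cr_", tolower(high)),
      threshold = config$placement$threshold,
      chrom_lengths = genome_lengths(genome) * 1000,
      spline_min_points = config$placement$spline_min_points %||% 10
    )
    truth_pos <- tibble(
      usnp = hold,
      true_chrom = genome$chrom[match(hold, genome$marker)],
      true_bp = round(genome$pos_kb[match(hold, genome$marker)] * 1000)
    )
    placement_eval <- placements |>
      left_join(truth_pos, by = "usnp") |>
      mutate(
        wrong_chrom = !is.na(.data$chrom) & .data$chrom != .data$true_chrom,
        abs_error_bp = if_else(.data$chrom == .data$true_chrom,
                               abs(.data$bp_position - .data$true_bp),
                               NA_real_)
      )
  }

  out <- structure(
    list(report = report_tbl, genome = genome, reference = reference,
         corruption_edits = corrupted$edits, call_set = call_set,
         groups = groups, maps = maps, robust = robust,
         families = fams, validation = validation,
         placements = placements, placement_eval = placement_eval,
         config = config),
    class = "rh_pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- config
    write_rh_vectors(calls, file.path(config$out_dir, "rh_vectors.tsv"),
                     seed = seed, config = cfg)
    write_intensities(intens$intensities,
                      file.path(config$out_dir, "intensities.tsv"),
                      seed = seed, config = cfg)
    write_families_ped(fams$genotypes,
                       file.path(config$out_dir, "families.ped"),
                       seed = seed, config = cfg)
    if (length(maps) > 0) {
      write_map(purrr::list_rbind(purrr::map(maps, as_tibble)),
                file.path(config$out_dir, "maps.tsv"),
                seed = seed, config = cfg)
    }
    if (length(robust) > 0) {
      write_map(purrr::list_rbind(purrr::map(robust, function(r)
        as_tibble(r$map))),
        file.path(config$out_dir, "robust_maps.tsv"),
        seed = seed, config = cfg)
    }
    readr::write_lines(file_header(seed, cfg),
                       file.path(config$out_dir, "report.tsv"))
    readr::write_tsv(report_tbl, file.path(config$out_dir, "report.tsv"),
                     append = TRUE, col_names = TRUE)
  }

  out
}

#' @export
print.rh_pipeline_result <- function(x, ...) {
  cat("<rh_pipeline_result>\n")
  print(tidyr::pivot_wider(x$report, names_from = "stage",
                           values_from = "n_markers"))
  invisible(x)
}

#' @export
glance.rh_pipeline_result <- function(x, ...) {
  tibble(
    n_simulated = sum(x$report$n_markers[x$report$stage == "simulated"]),
    n_called = sum(x$report$n_markers[x$report$stage == "called"]),
    n_linked = sum(x$report$n_markers[x$report$stage == "linked"]),
    n_mapped = sum(x$report$n_markers[x$report$stage == "mapped"]),
    n_robust = sum(x$report$n_markers[x$report$stage == "robust"])
  )
}
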