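# comment header written at the top of every emitted file
file_header <- function(seed = NULL, config = NULL) {
  c(
    sprintf("# rhmapper %s", pkg_version()),
    sprintf("# seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else hash(config))
  )
}

#' Write RH vectors to a TSV file
#'
#' Layout: one row per SNP, one column per clone, cells in 1/0/NA;
#' preceded by a comment header carrying the tool version, seed and
#' configuration hash.
#'
#' @param calls Long calls tibble (`marker`, `panel`, `clone`, `call`).
#' @param path Output path.
#' @param seed,config Recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_rh_vectors <- function(calls, path, seed = NULL, config = NULL) {
  mat <- calls_matrix(calls)
  lines <- c(
    file_header(seed, config),
    paste(c("marker", colnames(t(mat))), collapse = "\t")
  )
  # rows = markers, columns = clones
  tmat <- t(mat)
  body <- vapply(seq_len(nrow(tmat)), function(i) {
    paste(c(rownames(tmat)[i],
            ifelse(is.na(tmat[i, ]), "NA", as.character(tmat[i, ]))),
          collapse = "\t")
  }, character(1))
  readr::write_lines(c(lines, body), path)
  invisible(path)
}

#' Read RH vectors from a TSV file
#'
#' Inverse of [write_rh_vectors()]; tolerates comment lines (`#`). Cells
#' must be `1`, `0` or `NA` — anything else is an error reporting the
#' offending line number. An empty file yields an empty tibble with a
#' warning.
#'
#' @param path Input path.
#' @param panel Panel id attached to the calls.
#' @return Long calls tibble (`marker`, `panel`, `clone`, `call`).
#' @export
read_rh_vectors <- function(path, panel = "RH1") {
  raw <- readr::read_lines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  if (sum(keep) == 0L) {
    warn(sprintf("'%s' contains no data; returning an empty call set.",
                 path))
    return(tibble(marker = character(), panel = character(),
                  clone = character(), call = integer()))
  }
  line_no <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  header <- rows[[1]]
  clones <- header[-1]
  out <- purrr::map(seq_along(rows)[-1], function(i) {
    f <- rows[[i]]
    if (length(f) != length(header)) {
      abort(sprintf("Line %d of '%s': expected %d fields, found %d.",
                    line_no[i], path, length(header), length(f)))
    }
    vals <- f[-1]
    bad <- which(!vals %in% c("0", "1", "NA"))
    if (length(bad) > 0L) {
      abort(sprintf("Line %d of '%s': invalid call token '%s'.",
                    line_no[i], path, vals[bad[1]]))
    }
    tibble(marker = f[1], panel = panel, clone = clones,
           call = suppressWarnings(as.integer(vals)))
  }) |> purrr::list_rbind()
  out
}

#' Write per-sample intensities to TSV
#' @param intensities Tibble `marker`, `sample`, `x`, `y`.
#' @inheritParams write_rh_vectors
#' @return `path`, invisibly.
#' @export
write_intensities <- function(intensities, path, seed = NULL,
                              config = NULL) {
  assert_columns(intensities, c("marker", "sample", "x", "y"),
                 "`intensities`")
  readr::write_lines(file_header(seed, config), path)
  readr::write_tsv(intensities, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read per-sample intensities from TSV
#' @param path Input path.
#' @return Tibble `marker`, `sample`, `x`, `y`.
#' @export
read_intensities <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    marker = readr::col_character(),
                    sample = readr::col_character(),
                    x = readr::col_double(), y = readr::col_double()
                  ))
}

#' Write a map table to TSV
#' @param map An `rh_map`-like tibble.
#' @inheritParams write_rh_vectors
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, seed = NULL, config = NULL) {
  readr::write_lines(file_header(seed, config), path)
  readr::write_tsv(as_tibble(map), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a map table from TSV
#' @param path Input path.
#' @return An `rh_map` tibble.
#' @export
read_map <- function(path) {
  as_rh_map(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}

#' Write half-sib family genotypes in a PED-like layout
#'
#' Whitespace-separated table: `family individual father mother sex`
#' followed by two allele columns per marker (suffixes `_1`, `_2`);
#' mothers are always `0` (ungenotyped dams), sires have father `0`.
#' A header line names the columns; missing token is `NA`.
#'
#' @param genotypes Long genotype tibble from
#'   [simulate_halfsib_families()].
#' @inheritParams write_rh_vectors
#' @return `path`, invisibly.
#' @export
write_families_ped <- function(genotypes, path, seed = NULL,
                               config = NULL) {
  assert_columns(genotypes,
                 c("family", "individual", "father", "marker", "a1", "a2"),
                 "`genotypes`")
  markers <- unique(genotypes$marker)
  wide1 <- genotypes |>
    select("family", "individual", "father", "marker", "a1") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "a1",
                       names_glue = "{marker}_1")
  wide2 <- genotypes |>
    select("individual", "marker", "a2") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "a2",
                       names_glue = "{marker}_2")
  wide <- wide1 |> left_join(wide2, by = "individual")
  ord <- c("family", "individual", "father",
           as.vector(rbind(paste0(markers, "_1"), paste0(markers, "_2"))))
  wide <- wide[, ord]
  wide$mother <- "0"
  wide$sex <- 1L
  wide <- wide[, c("family", "individual", "father", "mother", "sex",
                   setdiff(ord, c("family", "individual", "father")))]
  readr::write_lines(file_header(seed, config), path)
  readr::write_delim(wide, path, delim = " ", append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Read half-sib family genotypes from the PED-like layout
#' @param path Input path.
#' @return Long genotype tibble (`family`, `individual`, `father`,
#'   `role`, `marker`, `a1`, `a2`).
#' @export
read_families_ped <- function(path) {
  wide <- readr::read_delim(path, delim = " ", comment = "#",
                            show_col_types = FALSE)
  fixed <- c("family", "individual", "father", "mother", "sex")
  gcols <- setdiff(names(wide), fixed)
  m1 <- grep("_1$", gcols, value = TRUE)
  long <- purrr::map(m1, function(c1) {
    mk <- sub("_1$", "", c1)
    tibble(
      family = wide$family, individual = wide$individual,
      father = as.character(wide$father),
      marker = mk,
      a1 = as.integer(wide[[c1]]), a2 = as.integer(wide[[paste0(mk, "_2")]])
    )
  }) |> purrr::list_rbind()
  long$role <- if_else(long$father == "0", "sire", "offspring")
  long
}

#' Export placements as a BED track
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive
#' `bp_position` becomes `[bp_position - 1, bp_position)` for point
#' features, or the spanned interval for scaffolds.
#'
#' @param x An `rh_placements` or `rh_scaffold_placements` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path) {
  if (inherits(x, "rh_scaffold_placements")) {
    d <- x |> filter(!is.na(.data$chrom))
    bed <- tibble(chrom = d$chrom,
                  start = as.integer(d$bp_start - 1),
                  end = as.integer(d$bp_end),
                  name = d$scaffold)
  } else {
    d <- x |> filter(!is.na(.data$bp_position))
    bed <- tibble(chrom = d$chrom,
                  start = as.integer(d$bp_position - 1),
                  end = as.integer(d$bp_position),
                  name = d$usnp)
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
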