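# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global stream untouched
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# derive a reproducible sub-seed (kept below 2^31) from a master seed
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1000L + as.integer(k)) %% 2147483647L
}

assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be a single probability in %s0, 1%s; got %s.",
      name, if (open_left) "(" else "[", if (open_right) ")" else "]",
      format(x)
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d; got %s.",
                  name, min, format(x)))
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# pivot a long calls tibble (marker, clone, call) into a clones x markers
# integer matrix in the given marker order, with a stable clone order
calls_matrix <- function(calls, markers = NULL, panel = NULL) {
  assert_columns(calls, c("marker", "clone", "call"), "`calls`")
  if (!is.null(panel) && "panel" %in% names(calls)) {
    calls <- calls[calls$panel %in% panel, , drop = FALSE]
  }
  markers <- markers %||% unique(calls$marker)
  calls <- calls[calls$marker %in% markers, , drop = FALSE]
  clones <- sort(unique(calls$clone))
  m <- matrix(NA_integer_, nrow = length(clones), ncol = length(markers),
              dimnames = list(clones, markers))
  i <- match(calls$clone, clones)
  j <- match(calls$marker, markers)
  m[cbind(i, j)] <- as.integer(calls$call)
  m
}

# markers typed on a given panel (at least one non-missing call)
typed_markers <- function(calls, panel = NULL) {
  if (!is.null(panel) && "panel" %in% names(calls)) {
    calls <- calls[calls$panel %in% panel, , drop = FALSE]
  }
  unique(calls$marker[!is.na(calls$call)])
}

# normalise a reference order: accepts a character vector or a tibble with
# a `marker` column (and optionally `chrom`, `pos_kb`/`ref_bp`)
as_reference <- function(reference) {
  if (is.character(reference)) {
    return(tibble(marker = reference, ref_index = seq_along(reference)))
  }
  assert_columns(reference, "marker", "`reference`")
  ref <- as_tibble(reference)
  ref$ref_index <- seq_len(nrow(ref))
  if (!"ref_bp" %in% names(ref) && "pos_kb" %in% names(ref)) {
    ref$ref_bp <- round(ref$pos_kb * 1000)
  }
  ref
}

pkg_version <- function() {
  as.character(utils::packageVersion("rhmapper"))
}
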