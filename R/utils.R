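#' Normalize gene/protein identifiers
#'
#' Case-folds to upper case and strips surrounding whitespace. No synonym
#' expansion is attempted; an optional two-column mapping table (see
#' [read_id_map()]) can be applied first.
#'
#' @param x character vector of identifiers.
#' @param id_map optional named character vector mapping normalized symbols to
#'   replacement identifiers (applied before case-folding the result).
#' @return character vector of normalized identifiers.
#' @export
normalize_id <- function(x, id_map = NULL) {
  out <- toupper(trimws(as.character(x)))
  if (!is.null(id_map)) {
    hit <- match(out, names(id_map))
    out[!is.na(hit)] <- toupper(id_map[hit[!is.na(hit)]])
  }
  out
}

# Deterministic per-stage seed derived from a master seed and a stage label.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
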