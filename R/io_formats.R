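#' Construct an expression matrix for a paired three-timepoint design
#'
#' The pipeline's raw input: a genes x samples matrix of nonnegative
#' abundances (FPKM-scale) where each sample is one rat at one of the three
#' timepoints CON (before self-administration), MASA (after
#' self-administration) and WD (after withdrawal). The design must be
#' balanced: every rat present at all three timepoints.
#'
#' @param values numeric matrix, rownames = gene IDs, colnames =
#'   `<TIMEPOINT>_<rat>` (e.g. `CON_1`, `MASA_1`, `WD_1`).
#' @return an object of class `expr_matrix`: a list with `values` (the
#'   matrix, columns ordered CON/MASA/WD within rat order), `rats` (integer
#'   rat IDs) and `timepoints` (always `c("CON","MASA","WD")`).
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0)
    stopf("duplicate gene ID(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(values))
    stopf("missing expression values are not allowed")
  if (any(values < 0))
    stopf("negative expression values are not allowed")
  key <- parse_sample_key(colnames(values))
  if (anyDuplicated(paste(key$timepoint, key$rat)))
    stopf("duplicate sample column for a (rat, timepoint) pair")
  rats <- sort(unique(key$rat))
  for (r in rats) {
    have <- key$timepoint[key$rat == r]
    miss <- setdiff(TIMEPOINTS, have)
    if (length(miss) > 0)
      stopf("unbalanced design: rat %d is missing timepoint(s) %s",
            r, paste(miss, collapse = ", "))
  }
  ord <- order(match(key$timepoint, TIMEPOINTS), key$rat)
  values <- values[, ord, drop = FALSE]
  structure(list(values = values, rats = rats, timepoints = TIMEPOINTS),
            class = "expr_matrix")
}

TIMEPOINTS <- c("CON", "MASA", "WD")

parse_sample_key <- function(cols) {
  m <- regmatches(cols, regexec("^(CON|MASA|WD)_([0-9]+)$", cols))
  bad <- cols[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0)
    stopf("sample column(s) not of the form <TIMEPOINT>_<rat>: %s",
          paste(bad, collapse = ", "))
  data.frame(sample = cols,
             timepoint = vapply(m, `[`, "", 2L),
             rat = as.integer(vapply(m, `[`, "", 3L)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d rats x 3 timepoints)\n",
              nrow(x$values), ncol(x$values), length(x$rats)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Columns of the matrix belonging to one timepoint, in rat order.
tp_values <- function(em, tp) {
  key <- parse_sample_key(colnames(em$values))
  em$values[, key$timepoint == tp, drop = FALSE][, order(key$rat[key$timepoint == tp]), drop = FALSE]
}

#' Read a gene expression table
#'
#' Reads a TSV with a gene-ID column (first column) and one column per sample
#' named `<TIMEPOINT>_<rat>`. Validates that IDs are unique, values are
#' nonnegative and complete, and the design is balanced.
#'
#' @param path file path.
#' @return an [expr_matrix()].
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression table needs a gene column and sample columns")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric expression value in %s", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  expr_matrix(mat)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; values are printed with full
#' precision so a write/read round trip is exact.
#'
#' @param em an [expr_matrix()].
#' @param path output file path.
#' @export
write_expression_table <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values),
                   apply(em$values, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(em$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style interaction table
#'
#' Expects a whitespace- or tab-separated file with header columns
#' `protein1`, `protein2`, `combined_score` (score on the conventional
#' 0--1000 scale). Self-pairs are dropped, reciprocal duplicate rows are
#' collapsed to one undirected edge keeping the maximum score, and only
#' edges with `combined_score >= score_min` are returned. The threshold is
#' inclusive: 400 is the conventional medium-confidence cutoff and an edge
#' scoring exactly 400 qualifies.
#'
#' @param path file path.
#' @param score_min minimum combined score retained (default 400).
#' @param id_map optional named character vector applied by [normalize_id()].
#' @return data.frame with columns `node_a`, `node_b`, `combined_score`;
#'   one row per undirected edge, `node_a < node_b` lexicographically.
#' @export
read_string_links <- function(path, score_min = 400, id_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stopf("empty interaction file: %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  need <- c("protein1", "protein2", "combined_score")
  idx <- match(need, header)
  if (anyNA(idx))
    stopf("interaction file must have header columns %s", paste(need, collapse = ", "))
  rows <- fields[-1]
  a <- character(length(rows)); b <- character(length(rows)); s <- integer(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(header))
      stopf("malformed interaction row at line %d: expected %d fields, got %d",
            i + 1L, length(header), length(f))
    sc <- suppressWarnings(as.numeric(f[idx[3]]))
    if (is.na(sc) || sc != round(sc))
      stopf("malformed combined_score at line %d: '%s'", i + 1L, f[idx[3]])
    if (sc < 0 || sc > 1000)
      stopf("combined_score out of [0, 1000] at line %d: %s", i + 1L, f[idx[3]])
    a[i] <- f[idx[1]]; b[i] <- f[idx[2]]; s[i] <- as.integer(sc)
  }
  a <- normalize_id(a, id_map); b <- normalize_id(b, id_map)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      combined_score = integer(), stringsAsFactors = FALSE))
  key <- paste(lo, hi, sep = "\r")
  smax <- tapply(s, key, max)
  pair <- strsplit(names(smax), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(pair, `[`, "", 1L),
                    node_b = vapply(pair, `[`, "", 2L),
                    combined_score = as.integer(smax),
                    stringsAsFactors = FALSE)
  out <- out[out$combined_score >= score_min, , drop = FALSE]
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction edge table
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `combined_score`.
#' @param path output file path.
#' @export
write_string_links <- function(edges, path) {
  df <- data.frame(protein1 = edges$node_a, protein2 = edges$node_b,
                   combined_score = edges$combined_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curated gene set
#'
#' One symbol per line, optionally followed by an evidence-source tag
#' (e.g. LT, mouse, human, HT). Symbols are case-normalized and
#' deduplicated; per-source occurrence counts are tallied (a symbol may
#' carry several sources across lines).
#'
#' @param path file path.
#' @param id_map optional named character vector applied by [normalize_id()].
#' @return object of class `curated_gene_set`: list with `symbols`
#'   (character, unique, normalized) and `source_counts` (named integer).
#' @export
read_gene_set <- function(path, id_map = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stopf("empty curated gene set: %s (enrichment would be undefined)", path)
  fields <- strsplit(lines, "[ \t]+")
  sym <- normalize_id(vapply(fields, `[`, "", 1L), id_map)
  src <- vapply(fields, function(f) if (length(f) > 1) f[2] else NA_character_, "")
  counts <- table(src[!is.na(src)])
  curated_gene_set(unique(sym),
                   stats::setNames(as.integer(counts), names(counts)))
}

#' @rdname read_gene_set
#' @param symbols character vector of (normalized) symbols.
#' @param source_counts named nonnegative integer vector of evidence-source
#'   tallies.
#' @export
curated_gene_set <- function(symbols, source_counts = integer(0)) {
  symbols <- unique(normalize_id(symbols))
  if (length(symbols) == 0) stopf("curated gene set may not be empty")
  if (length(source_counts) > 0 && any(source_counts < 0))
    stopf("source counts must be nonnegative")
  structure(list(symbols = symbols, source_counts = source_counts),
            class = "curated_gene_set")
}

#' @export
print.curated_gene_set <- function(x, ...) {
  cat(sprintf("curated_gene_set: %d symbols", length(x$symbols)))
  if (length(x$source_counts) > 0)
    cat(" [", paste(names(x$source_counts), x$source_counts,
                    sep = ":", collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a symbol-to-protein-ID mapping table
#'
#' Two-column TSV (symbol, protein_id) used to translate expression-table
#' gene symbols to the identifier space of the interaction table.
#'
#' @param path file path.
#' @return named character vector: `names` are normalized symbols, values
#'   the mapped identifiers, suitable for the `id_map` arguments.
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("ID map needs two columns (symbol, protein_id)")
  stats::setNames(as.character(df[[2]]), normalize_id(df[[1]]))
}

#' Write the ranked candidate table
#'
#' Writes the top-centrality candidate report as a TSV with columns
#' `rank`, `gene`, `bc`, `curated_flag`, `group`, `norm_masa`, `norm_wd`.
#' Betweenness is printed to 4 decimals, the precision the candidate
#' tables in this field are reported at.
#'
#' @param candidates data.frame as produced by [select_candidates()].
#' @param path output file path.
#' @export
write_candidate_table <- function(candidates, path) {
  need <- c("rank", "gene", "bc", "curated_flag", "group", "norm_masa", "norm_wd")
  miss <- setdiff(need, names(candidates))
  if (length(miss) > 0)
    stopf("candidate table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(candidates) == 0 || anyNA(candidates$rank) ||
      !identical(sort(as.integer(candidates$rank)), seq_len(nrow(candidates))))
    stopf("candidates must carry contiguous ranks starting at 1")
  df <- candidates[order(candidates$rank), need]
  df$bc <- sprintf("%.4f", df$bc)
  df$curated_flag <- as.integer(df$curated_flag)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#'
#' @param path file path.
#' @return data.frame with the candidate columns; `curated_flag` is logical.
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$curated_flag <- as.logical(df$curated_flag)
  df$group <- as.character(df$group)
  df
}
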