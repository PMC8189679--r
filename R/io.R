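#' @importFrom readr read_tsv write_tsv cols col_character col_double
NULL

# Read a TSV whose first column holds row ids and remaining columns are
# numeric. Non-numeric cells and duplicate ids are rejected with the
# offending entity named.
read_id_matrix <- function(path, what = "gene") {
  raw <- suppressWarnings(
    read_tsv(path, col_types = cols(.default = col_character()),
             progress = FALSE)
  )
  if (ncol(raw) < 2) abort_input("%s: need an id column plus data columns", path)
  ids <- raw[[1]]
  if (anyNA(ids)) abort_input("%s: missing %s id", path, what)
  if (anyDuplicated(ids))
    abort_input("%s: duplicated %s id: %s", path, what, ids[duplicated(ids)][1])
  samples <- names(raw)[-1]
  if (anyDuplicated(samples))
    abort_input("%s: duplicated column id: %s", path,
                samples[duplicated(samples)][1])
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(ids, samples))
  bad <- which(is.na(vals) & !is.na(as.matrix(raw[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_input("%s: non-numeric value '%s' at %s '%s', column '%s'",
                path, as.matrix(raw[-1])[bad[1, , drop = FALSE]],
                what, ids[bad[1, 1]], samples[bad[1, 2]])
  if (anyNA(vals))
    abort_input("%s: missing value at %s '%s'", path, what,
                ids[which(is.na(vals), arr.ind = TRUE)[1, 1]])
  vals
}

write_id_matrix <- function(x, path, id_col) {
  df <- tibble::as_tibble(x, rownames = id_col)
  write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Format: header `gene<TAB>sample1<TAB>...`, one row per gene, log2 values,
#' tab-separated with '.' decimal. Duplicate identifiers, missing or
#' non-numeric cells are rejected with an error naming the entity.
#'
#' @param path File path.
#' @return `read_expression_matrix` returns a validated genes x samples
#'   numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  expression_matrix(read_id_matrix(path, "gene"))
}

#' @rdname read_expression_matrix
#' @param x Genes x samples numeric matrix.
#' @export
write_expression_matrix <- function(x, path) {
  write_id_matrix(expression_matrix(x), path, "gene")
}

#' Read / write a TFs x samples activity matrix TSV
#'
#' Same layout as the expression format with a `tf` id column.
#'
#' @param path File path.
#' @return A TFs x samples numeric matrix.
#' @export
read_activity_matrix <- function(path) {
  check_activity_matrix(read_id_matrix(path, "tf"))
}

#' @rdname read_activity_matrix
#' @param x TFs x samples numeric matrix.
#' @export
write_activity_matrix <- function(x, path) {
  write_id_matrix(check_activity_matrix(x), path, "tf")
}

#' Read / write a ranked edge list TSV
#'
#' Format: header `tf<TAB>target<TAB>score`. Edges are re-sorted by
#' descending score on read; equal scores keep file order.
#'
#' @param path File path.
#' @param allow_self Keep self edges (tf == target)?
#' @return A `ranked_edges` tibble.
#' @export
read_ranked_edges <- function(path, allow_self = FALSE) {
  df <- read_tsv(path, col_types = cols(tf = col_character(),
                                        target = col_character(),
                                        score = col_double()),
                 progress = FALSE)
  ranked_edges(df, allow_self = allow_self)
}

#' @rdname read_ranked_edges
#' @param x A `ranked_edges` tibble.
#' @export
write_ranked_edges <- function(x, path) {
  write_tsv(x[, c("tf", "target", "score")], path, progress = FALSE)
  invisible(path)
}

#' Read / write a perturbation key TSV
#'
#' Format: header `sample<TAB>tf<TAB>direction` with direction one of
#' `deletion`, `overexpression`, `none`; `none` rows are unperturbed
#' samples.
#'
#' @param path File path.
#' @return A `perturbation_key` tibble.
#' @export
read_perturbation_key <- function(path) {
  df <- read_tsv(path, col_types = cols(sample = col_character(),
                                        tf = col_character(),
                                        direction = col_character()),
                 progress = FALSE)
  perturbation_key(df)
}

#' @rdname read_perturbation_key
#' @param x A `perturbation_key` tibble.
#' @export
write_perturbation_key <- function(x, path) {
  out <- x[, c("sample", "tf", "direction")]
  out$tf[is.na(out$tf)] <- ""
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a network map TSV (`tf<TAB>target`)
#'
#' @param path File path.
#' @param validate Enforce finished-network invariants on read?
#' @return A `tf_network` tibble.
#' @export
read_network <- function(path, validate = TRUE) {
  df <- read_tsv(path, col_types = cols(tf = col_character(),
                                        target = col_character()),
                 progress = FALSE)
  tf_network(df, validate = validate)
}

#' @rdname read_network
#' @param x A `tf_network` tibble.
#' @export
write_network <- function(x, path) {
  write_tsv(x[, c("tf", "target")], path, progress = FALSE)
  invisible(path)
}

#' Read / write sign constraints TSV (`tf<TAB>target<TAB>sign`)
#'
#' @param path File path.
#' @return A `sign_constraints` tibble.
#' @export
read_sign_constraints <- function(path) {
  df <- read_tsv(path, col_types = cols(tf = col_character(),
                                        target = col_character(),
                                        sign = col_double()),
                 progress = FALSE)
  sign_constraints(df)
}

#' @rdname read_sign_constraints
#' @param x A `sign_constraints` tibble.
#' @export
write_sign_constraints <- function(x, path) {
  write_tsv(x[, c("tf", "target", "sign")], path, progress = FALSE)
  invisible(path)
}

#' Read / write a control-strength matrix (cs TSV + baselines TSV)
#'
#' The CS matrix is stored wide (`gene` id column, one column per TF); the
#' baselines as a two-column `gene<TAB>baseline` TSV.
#'
#' @param cs_path,baselines_path File paths.
#' @return A `cs_matrix`.
#' @export
read_cs_matrix <- function(cs_path, baselines_path) {
  cs <- read_id_matrix(cs_path, "gene")
  b <- read_tsv(baselines_path,
                col_types = cols(gene = col_character(),
                                 baseline = col_double()),
                progress = FALSE)
  cs_matrix(cs, stats::setNames(b$baseline, b$gene))
}

#' @rdname read_cs_matrix
#' @param x A `cs_matrix`.
#' @export
write_cs_matrix <- function(x, cs_path, baselines_path) {
  write_id_matrix(x$cs, cs_path, "gene")
  write_tsv(tibble(gene = names(x$baselines), baseline = unname(x$baselines)),
            baselines_path, progress = FALSE)
  invisible(cs_path)
}
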