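#' Read a feature table from TSV or BIOM
#'
#' TSV tables carry a header row of taxon identifiers and sample
#' identifiers in the first column (or the transpose with
#' `orientation = "taxa_rows"` — no auto-guessing is attempted). BIOM
#' tables (read through the biomformat package) follow the BIOM convention
#' of taxa as observations (rows) and samples as columns.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV input: `"samples_rows"` (default) if rows are
#'   samples, `"taxa_rows"` if rows are taxa.
#' @param kind forwarded to [abundance_table()]; `NULL` detects counts as
#'   all-integer tables.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, format = c("tsv", "biom"),
                           orientation = c("samples_rows", "taxa_rows"),
                           kind = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM tables requires the biomformat package")
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    m <- t(m)  # biom convention: observations (taxa) x samples
    return(abundance_table(m, kind = kind))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  if (orientation == "taxa_rows") m <- t(m)
  abundance_table(m, kind = kind)
}

#' Write a feature table as TSV
#'
#' Values are written at full precision (17 significant digits) so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param tab an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tab, path) {
  stopifnot(inherits(tab, "abundance_table"))
  v <- tab$values
  df <- data.frame(sample_id = rownames(v),
                   format(v, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' Expects a TSV with columns `sample_id`, `group`, `hfc_baseline`,
#' `hfc_followup` and optionally `hfc_change` (hepatic fat content, %).
#' When `hfc_change` is absent it is computed as followup minus baseline,
#' in percentage points.
#'
#' @param path metadata TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "hfc_baseline", "hfc_followup")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!"hfc_change" %in% names(df))
    df$hfc_change <- df$hfc_followup - df$hfc_baseline
  df
}

#' Write cohort metadata as TSV
#' @param meta data.frame as returned by [read_metadata()] or
#'   [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square correlation matrix as TSV
#' @param mat square numeric matrix with identifiers on both dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network's edges as TSV
#'
#' Writes one row per edge with both endpoints, the edge weight and its
#' sign. Works for single-sample networks and group-level co-occurrence
#' networks.
#'
#' @param net an `ssn` or `micro_network` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#' @param net an `ssn` or `micro_network` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
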