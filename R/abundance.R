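#' Construct an abundance table
#'
#' An abundance table holds a samples-by-taxa matrix of non-negative
#' abundances, either raw counts or relative abundances (rows summing to 1).
#' It is the basic container consumed by [sparcc()], [sparcc_decompose()]
#' and the co-abundance-group machinery.
#'
#' @param values numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are used as sample and taxon identifiers; defaults
#'   (`S1..`, `T1..`) are assigned when missing.
#' @param kind `"counts"` or `"relative"`. If `NULL`, tables whose entries
#'   are all whole numbers are treated as counts, otherwise as relative.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix), `kind`, and accessors via `$`.
#' @examples
#' tab <- abundance_table(matrix(1:6, 2, 3))
#' n_samples(tab); n_taxa(tab)
#' @export
abundance_table <- function(values, kind = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("T", seq_len(ncol(values)))
  if (is.null(kind)) {
    kind <- if (all(values == round(values))) "counts" else "relative"
  }
  kind <- match.arg(kind, c("counts", "relative"))
  tab <- structure(list(values = values, kind = kind), class = "abundance_table")
  validate_abundance_table(tab)
  tab
}

validate_abundance_table <- function(tab) {
  v <- tab$values
  if (nrow(v) < 1L) stop("abundance table needs at least one sample")
  if (ncol(v) < 1L) stop("abundance table needs at least one taxon")
  if (anyNA(v)) stop("abundance table contains missing values")
  if (any(v < 0)) stop("abundance table contains negative values")
  if (anyDuplicated(rownames(v))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(v))) stop("duplicate taxon identifiers")
  if (tab$kind == "relative") {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative abundance rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  invisible(tab)
}

#' @rdname abundance_table
#' @param x,tab an `abundance_table`.
#' @export
n_samples <- function(tab) nrow(tab$values)

#' @rdname abundance_table
#' @export
n_taxa <- function(tab) ncol(tab$values)

#' @rdname abundance_table
#' @export
sample_ids <- function(tab) rownames(tab$values)

#' @rdname abundance_table
#' @export
taxon_ids <- function(tab) colnames(tab$values)

#' @rdname abundance_table
#' @param ... ignored.
#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              n_samples(x), n_taxa(x), x$kind))
  invisible(x)
}

#' Convert an abundance table to relative abundances
#'
#' Adds a pseudocount to every cell (the customary way to remove zeros
#' before taking log-ratios) and renormalizes each sample to sum to 1.
#' The default pseudocount of 0.5 follows common SparCC practice for count
#' tables; set it to 0 for tables that are already strictly positive.
#'
#' @param tab an [abundance_table()].
#' @param pseudocount non-negative scalar added to every cell before
#'   row normalization. Default 0.5.
#' @return An `abundance_table` with `kind = "relative"`.
#' @examples
#' tab <- abundance_table(matrix(c(0, 10, 5, 5), 2, 2, byrow = TRUE))
#' to_relative(tab, pseudocount = 0.5)$values
#' @export
to_relative <- function(tab, pseudocount = 0.5) {
  stopifnot(inherits(tab, "abundance_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  v <- tab$values + pseudocount
  rs <- rowSums(v)
  if (any(rs == 0)) {
    bad <- rownames(v)[rs == 0]
    stop("rows sum to zero after pseudocount: ", paste(bad, collapse = ", "))
  }
  abundance_table(v / rs, kind = "relative")
}

#' Filter taxa by prevalence
#'
#' Retains taxa observed (strictly positive, before any pseudocount) in at
#' least `ceiling(min_prevalence * S)` of the S samples. The default of 20%
#' is the conventional cutoff for selecting "key" taxa ahead of correlation
#' analysis.
#'
#' @param tab an [abundance_table()].
#' @param min_prevalence fraction of samples in (0, 1] a taxon must appear
#'   in. Default 0.2.
#' @return A filtered `abundance_table` with column order preserved.
#' @export
prevalence_filter <- function(tab, min_prevalence = 0.2) {
  stopifnot(inherits(tab, "abundance_table"))
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]")
  need <- ceiling(min_prevalence * n_samples(tab))
  keep <- colSums(tab$values > 0) >= need
  if (sum(keep) < 2L)
    stop("fewer than 2 taxa pass the prevalence filter; correlation undefined")
  abundance_table(tab$values[, keep, drop = FALSE], kind = tab$kind)
}
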