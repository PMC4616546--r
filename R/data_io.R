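# Tabular input/output and reference-gene normalization.
#
# Matrices are plain numeric matrices with gene (or probe) ids as rownames
# and sample ids as colnames; validators enforce the container contracts so
# downstream stages can assume them.

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an expression matrix
#'
#' Checks the contract every screen input must satisfy: a dense numeric
#' matrix, all values finite and non-negative, unique gene ids as rownames
#' and unique sample ids as colnames. Id matching everywhere in the package
#' is exact and case-sensitive.
#'
#' @param m Numeric matrix (genes x samples).
#' @param what Label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry gene ids as rownames and sample ids as colnames")
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup) > 0)
    stop("duplicate gene id(s) in ", what, ": ",
         paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup) > 0)
    stop("duplicate sample id(s) in ", what, ": ",
         paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite value in ", what, " at gene '", rownames(m)[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "'")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative value (", m[bad[1, , drop = FALSE]], ") in ", what,
         " at gene '", rownames(m)[bad[1, 1]], "', sample '",
         colnames(m)[bad[1, 2]], "'")
  invisible(m)
}

read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected id column plus >=1 sample column in ", path)
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  dimnames(vals) <- list(ids, colnames(raw))
  attr(vals, "raw") <- raw
  vals
}

#' Read a gene x sample expression matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' The separator is auto-detected from the file extension (`.csv` comma,
#' anything else tab) and can be overridden. Values are opaque non-negative
#' abundances (RSEM/RPKM-style); no unit conversion is applied.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Optional field separator overriding extension detection.
#' @return A validated numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  vals <- read_delim_matrix(path, sep)
  raw <- attr(vals, "raw"); attr(vals, "raw") <- NULL
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric expression value '", raw[bad[1, , drop = FALSE]],
         "' at gene '", rownames(vals)[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "' in ", path)
  validate_expression_matrix(vals)
  msg("read expression matrix: %d genes x %d samples", nrow(vals), ncol(vals))
  vals
}

#' Read a sample annotation table
#'
#' Two-column table mapping `sample_id` to `subtype`. Sample ids must be
#' unique and at least two subtype labels must be present (a screen needs a
#' target and at least one background class).
#'
#' @param path Path to a CSV/TSV file with columns `sample_id,subtype`.
#' @param sep Optional separator override.
#' @return A data.frame with character columns `sample_id` and `subtype`.
#' @export
read_annotation <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "subtype") %in% colnames(df)))
    stop("annotation must have columns 'sample_id' and 'subtype'; found: ",
         paste(colnames(df), collapse = ", "))
  df <- df[, c("sample_id", "subtype")]
  validate_annotation(df)
  df
}

#' @rdname read_annotation
#' @param ann Annotation data.frame to validate in place of reading a file.
#' @export
validate_annotation <- function(ann) {
  dup <- ann$sample_id[duplicated(ann$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample id(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  if (length(unique(ann$subtype)) < 2)
    stop("annotation must contain at least 2 subtype labels")
  invisible(ann)
}

#' Read a CpG probe x sample beta-value matrix
#'
#' Beta values measure the methylated fraction at a CpG site and must lie in
#' \[0, 1\]. Empty cells and the literal string `NA` are treated as missing.
#'
#' @inheritParams read_expression
#' @return Numeric matrix with probe rownames, sample colnames, and `NA`
#'   for missing entries.
#' @export
read_methylation <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  vals <- read_delim_matrix(path, sep)
  raw <- attr(vals, "raw"); attr(vals, "raw") <- NULL
  not_missing <- !(is.na(raw) | raw == "" | raw == "NA")
  bad <- which(is.na(vals) & not_missing, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric beta value '", raw[bad[1, , drop = FALSE]],
         "' at probe '", rownames(vals)[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "'")
  bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta value out of [0,1] (", vals[bad[1, , drop = FALSE]],
         ") at probe '", rownames(vals)[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "'")
  dup <- rownames(vals)[duplicated(rownames(vals))]
  if (length(dup) > 0)
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  msg("read methylation table: %d probes x %d samples (%d missing values)",
      nrow(vals), ncol(vals), sum(is.na(vals)))
  vals
}

#' Write a result table or matrix with a provenance comment
#'
#' Writes CSV or TSV (chosen by extension) preceded by a single `#`-prefixed
#' provenance line recording the package version and any parameters given.
#' The provenance line carries no timestamp, so repeated runs with the same
#' inputs produce byte-identical files; all package readers skip `#` lines.
#'
#' @param x A data.frame, or a matrix written with its rownames as a leading
#'   `id` column.
#' @param path Output path (`.csv` or `.tsv`).
#' @param params Optional named list of parameters recorded in the
#'   provenance line.
#' @param id_col Name of the leading id column used when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, params = NULL, id_col = "id") {
  sep <- detect_sep(path, NULL)
  if (is.matrix(x)) {
    x <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
    colnames(x)[1] <- id_col
  }
  prov <- sprintf("# markerscreen %s",
                  as.character(utils::packageVersion("markerscreen")))
  if (length(params) > 0)
    prov <- paste0(prov, " | ", paste(names(params), unlist(params),
                                      sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Normalize expression by a housekeeping reference gene
#'
#' Divides every gene's value by the reference gene's value in the same
#' sample, the normalization used throughout the screen (the cohorts this
#' design follows used TBP). Samples in which the reference gene reads zero
#' cannot be normalized and are dropped with a warning naming them; this
#' keeps downstream percentile summaries finite.
#'
#' @param m Expression matrix (see [validate_expression_matrix()]).
#' @param reference_gene Gene id of the reference row (default `"TBP"`).
#' @return Matrix of the same gene set over the retained samples, with
#'   attribute `reference_gene`. The reference gene's own row is identically
#'   1.
#' @examples
#' m <- matrix(c(10, 4, 2, 2), 2, dimnames = list(c("G1", "TBP"), c("s1", "s2")))
#' normalize_by_reference(m, "TBP")
#' @export
normalize_by_reference <- function(m, reference_gene = "TBP") {
  validate_expression_matrix(m)
  if (!reference_gene %in% rownames(m))
    stop("reference gene '", reference_gene, "' not present in matrix")
  ref <- m[reference_gene, ]
  drop <- colnames(m)[ref == 0]
  if (length(drop) == ncol(m))
    stop("reference gene '", reference_gene, "' is zero in every sample; ",
         "cannot normalize")
  if (length(drop) > 0) {
    warning("dropping ", length(drop), " sample(s) with zero reference ",
            "value: ", paste(drop, collapse = ", "))
    m <- m[, ref > 0, drop = FALSE]
    ref <- ref[ref > 0]
  }
  nm <- sweep(m, 2, ref, "/")
  attr(nm, "reference_gene") <- reference_gene
  nm
}
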