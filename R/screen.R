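# The marker screen: per-subtype median / upper-percentile summaries of
# reference-normalized expression and the two-condition threshold filter
# selecting genes high in the target subtype and near-absent elsewhere.

#' Screen criteria
#'
#' Bundles the thresholds of the two-condition filter: condition 1 keeps
#' genes whose median normalized expression in the target subtype is
#' strictly above `median_min`; condition 2 keeps genes whose `percentile`-th
#' normalized expression in *every* background subtype is strictly below
#' `background_q_max`. Defaults are the published operating point for the
#' chromophobe renal cell carcinoma screen (median > 8, 95th percentile
#' < 0.15, TBP reference); both thresholds are tunable and carry no
#' particular justification beyond that screen.
#'
#' @param target_subtype Label of the subtype whose markers are sought.
#' @param median_min Condition-1 threshold (strict `>`), default 8.
#' @param background_q_max Condition-2 threshold (strict `<`), default 0.15.
#' @param percentile Background percentile in (0, 100], default 95.
#' @param reference_gene Housekeeping gene for normalization, default "TBP".
#' @param method Percentile interpolation method, see [expr_percentile()].
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(target_subtype, median_min = 8,
                            background_q_max = 0.15, percentile = 95,
                            reference_gene = "TBP",
                            method = c("linear", "nearest-rank")) {
  method <- match.arg(method)
  stopifnot(length(target_subtype) == 1, is.character(target_subtype),
            median_min > 0, background_q_max >= 0,
            percentile > 0, percentile <= 100)
  structure(list(target_subtype = target_subtype, median_min = median_min,
                 background_q_max = background_q_max, percentile = percentile,
                 reference_gene = reference_gene, method = method),
            class = "screen_criteria")
}

#' Percentile of a numeric sample
#'
#' With `method = "linear"` (the default), interpolates linearly between the
#' closest order statistics: for sorted values x(1..n) the q-th percentile
#' sits at position p = 1 + (q/100)(n-1). This is the common default in
#' scientific software (base R's quantile type 7). `"nearest-rank"` returns
#' the order statistic at rank ceiling(n q/100); genes whose percentile sits
#' exactly at a screen threshold can flip between the two conventions, which
#' is why the method travels with the criteria.
#'
#' @param values Non-empty numeric vector, all finite.
#' @param q Percentile in (0, 100].
#' @param method `"linear"` or `"nearest-rank"`.
#' @return The percentile as a single number.
#' @examples
#' expr_percentile(1:100, 95)            # 95.05
#' expr_percentile(1:100, 95, "nearest-rank")  # 95
#' @export
expr_percentile <- function(values, q, method = c("linear", "nearest-rank")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("cannot take a percentile of an empty set")
  if (!all(is.finite(values))) stop("percentile input must be finite")
  stopifnot(q > 0, q <= 100)
  if (method == "linear") {
    unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
  } else {
    sort(values)[max(1L, ceiling(length(values) * q / 100))]
  }
}

#' Summarize normalized expression by subtype
#'
#' Computes, for every gene and every subtype, the median and the q-th
#' percentile of normalized expression over that subtype's samples only.
#' Samples present in the matrix but absent from the annotation are excluded
#' (their count is logged); annotated samples missing from the matrix are
#' ignored. Each subtype must retain at least `min_samples` samples —
#' order-statistic summaries on smaller groups are too unstable to screen on.
#'
#' @param nm Normalized expression matrix from [normalize_by_reference()]
#'   (any non-negative gene x sample matrix is accepted).
#' @param ann Annotation data.frame (`sample_id`, `subtype`).
#' @param q Percentile to summarize (default 95).
#' @param min_samples Minimum samples per subtype (default 3).
#' @param method Percentile interpolation method.
#' @return An object of class `subtype_summary`: list with gene x subtype
#'   matrices `medians` and `percentiles`, named vector `n_samples`, and the
#'   `q` and `method` used.
#' @export
summarize_by_subtype <- function(nm, ann, q = 95, min_samples = 3,
                                 method = c("linear", "nearest-rank")) {
  method <- match.arg(method)
  validate_annotation(ann)
  unannotated <- setdiff(colnames(nm), ann$sample_id)
  if (length(unannotated) > 0)
    msg("excluding %d sample(s) absent from the annotation",
        length(unannotated))
  subtypes <- sort(unique(ann$subtype))
  groups <- lapply(subtypes, function(st) {
    intersect(ann$sample_id[ann$subtype == st], colnames(nm))
  })
  names(groups) <- subtypes
  n_samples <- vapply(groups, length, integer(1))
  too_small <- names(n_samples)[n_samples < min_samples]
  if (length(too_small) > 0)
    stop("subtype(s) below min_samples (", min_samples, "): ",
         paste(too_small, collapse = ", "))
  medians <- vapply(groups, function(ss) {
    apply(nm[, ss, drop = FALSE], 1, stats::median)
  }, numeric(nrow(nm)))
  percentiles <- vapply(groups, function(ss) {
    apply(nm[, ss, drop = FALSE], 1, expr_percentile, q = q, method = method)
  }, numeric(nrow(nm)))
  dimnames(medians) <- dimnames(percentiles) <- list(rownames(nm), subtypes)
  subtype_summary(medians, percentiles, n_samples, q, method)
}

#' Construct a subtype summary from precomputed matrices
#'
#' Lower-level constructor used by [summarize_by_subtype()] and available
#' directly when summaries come from elsewhere (e.g. published per-subtype
#' tallies). Validates finiteness, non-negativity, and that medians do not
#' exceed the percentile values whenever q >= 50.
#'
#' @param medians,percentiles Gene x subtype numeric matrices with matching
#'   dimnames.
#' @param n_samples Named integer vector of per-subtype sample counts.
#' @param q Percentile the `percentiles` matrix holds.
#' @param method Interpolation method used.
#' @return An object of class `subtype_summary`.
#' @export
subtype_summary <- function(medians, percentiles, n_samples, q,
                            method = "linear") {
  stopifnot(is.matrix(medians), is.matrix(percentiles),
            identical(dim(medians), dim(percentiles)),
            identical(dimnames(medians), dimnames(percentiles)),
            all(colnames(medians) %in% names(n_samples)))
  if (!all(is.finite(medians)) || any(medians < 0) ||
      !all(is.finite(percentiles)) || any(percentiles < 0))
    stop("summaries must be finite and non-negative")
  if (q >= 50 && any(medians > percentiles + 1e-12))
    stop("median exceeds the ", q, "th percentile for some gene; ",
         "summaries are inconsistent")
  structure(list(medians = medians, percentiles = percentiles,
                 n_samples = n_samples[colnames(medians)], q = q,
                 method = method),
            class = "subtype_summary")
}

check_screen_inputs <- function(s, criteria) {
  stopifnot(inherits(s, "subtype_summary"), inherits(criteria, "screen_criteria"))
  if (!isTRUE(all.equal(s$q, criteria$percentile)))
    stop("summary holds the ", s$q, "th percentile but criteria ask for the ",
         criteria$percentile, "th; recompute the summary")
  if (!criteria$target_subtype %in% colnames(s$medians))
    stop("target subtype '", criteria$target_subtype,
         "' absent from summary (has: ",
         paste(colnames(s$medians), collapse = ", "), ")")
  backgrounds <- setdiff(colnames(s$medians), criteria$target_subtype)
  if (length(backgrounds) == 0)
    stop("screen needs at least one background subtype")
  backgrounds
}

#' Apply the two-condition marker screen
#'
#' A gene is a hit iff its target-subtype median is strictly greater than
#' `median_min` (condition 1) and its background percentile is strictly less
#' than `background_q_max` in every background subtype separately
#' (condition 2). Both comparisons are strict, following the operating
#' point's wording ("more than" / "less than").
#'
#' @param s A `subtype_summary`.
#' @param criteria A `screen_criteria`; its `percentile` must match `s$q`.
#' @return A data.frame with one row per gene: `gene_id`, `target_median`,
#'   one `q<q>_<subtype>` column per background, logical `cond1`,
#'   `cond2_<subtype>` flags, and `hit`. Rows are ordered by target median
#'   descending, ties broken by gene id, so reports are deterministic.
#' @export
apply_screen <- function(s, criteria) {
  backgrounds <- check_screen_inputs(s, criteria)
  target <- criteria$target_subtype
  target_median <- s$medians[, target]
  cond1 <- target_median > criteria$median_min
  qcols <- s$percentiles[, backgrounds, drop = FALSE]
  cond2 <- qcols < criteria$background_q_max
  hit <- cond1 & apply(cond2, 1, all)
  out <- data.frame(gene_id = rownames(s$medians),
                    target_median = unname(target_median),
                    stringsAsFactors = FALSE)
  qname <- sprintf("q%g_%s", s$q, backgrounds)
  out[qname] <- unname(as.data.frame(qcols))
  out$cond1 <- unname(cond1)
  out[sprintf("cond2_%s", backgrounds)] <- unname(as.data.frame(cond2))
  out$hit <- unname(hit)
  out <- out[order(-out$target_median, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-condition gene counts and fractions
#'
#' Reports how many genes clear condition 1 and, per background subtype,
#' condition 2, together with the fraction of all screened genes each count
#' represents (also formatted as a percentage rounded half-up to one
#' decimal, the convention used when such tallies are printed).
#'
#' @inheritParams apply_screen
#' @return A data.frame with columns `condition`, `subtype`, `count`,
#'   `total`, `fraction`, `percent`.
#' @examples
#' # 3333 of 20531 genes passing condition 1 is printed as 16.2%
#' @export
condition_counts <- function(s, criteria) {
  backgrounds <- check_screen_inputs(s, criteria)
  total <- nrow(s$medians)
  cond1_n <- sum(s$medians[, criteria$target_subtype] > criteria$median_min)
  cond2_n <- vapply(backgrounds, function(b) {
    sum(s$percentiles[, b] < criteria$background_q_max)
  }, integer(1))
  out <- data.frame(
    condition = c("cond1_median", rep("cond2_percentile", length(backgrounds))),
    subtype = c(criteria$target_subtype, backgrounds),
    count = c(cond1_n, unname(cond2_n)),
    total = total,
    stringsAsFactors = FALSE)
  out$fraction <- out$count / out$total
  out$percent <- round_half_up(100 * out$fraction, 1)
  out
}
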