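# Ordinal immunohistochemistry grading, positivity rules, and diagnostic
# sensitivity/specificity.
#
# Each stained specimen is graded on two axes: staining intensity
# (negative / weak / strong) and the proportion of positive tumor cells
# (none <1%, partial 1-90%, diffuse >=90%). A positivity rule is an explicit
# set of accepted (intensity, proportion) pairs, so criteria like "strong
# diffuse only" versus "strong diffuse or any weak staining" are
# configuration, not code.

IHC_INTENSITY <- c("negative", "weak", "strong")
IHC_PROPORTION <- c("none", "partial", "diffuse")

#' Validate immunohistochemistry records
#'
#' A record describes one case x marker stain: `case_id`, `tumor_type`,
#' `marker`, `intensity` in negative/weak/strong, and `proportion` in
#' none/partial/diffuse. Negative intensity and zero extent imply each other
#' (a graded stain must cover some cells and vice versa).
#'
#' @param records Data.frame with the five columns above.
#' @return `records`, invisibly, if valid.
#' @export
validate_ihc_records <- function(records) {
  need <- c("case_id", "tumor_type", "marker", "intensity", "proportion")
  missing_cols <- setdiff(need, colnames(records))
  if (length(missing_cols) > 0)
    stop("IHC table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(records$intensity), IHC_INTENSITY)
  if (length(bad) > 0)
    stop("unknown intensity value(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(IHC_INTENSITY, collapse = ", "))
  bad <- setdiff(unique(records$proportion), IHC_PROPORTION)
  if (length(bad) > 0)
    stop("unknown proportion value(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(IHC_PROPORTION, collapse = ", "))
  inconsistent <- xor(records$intensity == "negative",
                      records$proportion == "none")
  if (any(inconsistent))
    stop("inconsistent grade for case(s) ",
         paste(unique(records$case_id[inconsistent]), collapse = ", "),
         ": intensity 'negative' and proportion 'none' must co-occur")
  invisible(records)
}

#' Read an immunohistochemistry grading table
#'
#' @param path CSV/TSV with columns
#'   `case_id,tumor_type,marker,intensity,proportion`.
#' @param sep Optional separator override.
#' @return Validated data.frame of records.
#' @export
read_ihc <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  validate_ihc_records(df)
  df
}

#' Define a positivity rule
#'
#' @param name Rule name, or one of the presets `"strict"` (strong diffuse
#'   staining only) and `"lenient"` (strong diffuse plus weak staining of any
#'   extent). Strong partial staining is accepted by neither preset; pass an
#'   explicit `accepted` set to include it.
#' @param accepted Two-column data.frame (`intensity`, `proportion`) of
#'   accepted grade pairs; required unless `name` is a preset. Pairs
#'   involving `negative` or `none` are rejected — an absent stain can never
#'   count as positive.
#' @return An object of class `positivity_rule`.
#' @examples
#' positivity_rule("strict")
#' positivity_rule("lenient")
#' @export
positivity_rule <- function(name, accepted = NULL) {
  if (is.null(accepted)) {
    accepted <- switch(name,
      strict = data.frame(intensity = "strong", proportion = "diffuse",
                          stringsAsFactors = FALSE),
      lenient = data.frame(
        intensity = c("strong", "weak", "weak"),
        proportion = c("diffuse", "partial", "diffuse"),
        stringsAsFactors = FALSE),
      stop("no preset rule named '", name,
           "'; supply an explicit accepted set"))
  }
  stopifnot(is.data.frame(accepted),
            all(c("intensity", "proportion") %in% colnames(accepted)))
  if (any(accepted$intensity == "negative" | accepted$proportion == "none"))
    stop("a positivity rule cannot accept 'negative' intensity or 'none' ",
         "proportion")
  bad <- !(accepted$intensity %in% IHC_INTENSITY) |
    !(accepted$proportion %in% IHC_PROPORTION)
  if (any(bad))
    stop("unknown grade pair in rule; intensities: ",
         paste(IHC_INTENSITY, collapse = "/"), ", proportions: ",
         paste(IHC_PROPORTION, collapse = "/"))
  structure(list(name = name,
                 accepted = accepted[, c("intensity", "proportion")]),
            class = "positivity_rule")
}

#' Call each record positive or negative under a rule
#'
#' @param records Validated IHC records (one or more rows).
#' @param rule A [positivity_rule()].
#' @return Logical vector, one call per record.
#' @export
call_positivity <- function(records, rule) {
  stopifnot(inherits(rule, "positivity_rule"))
  validate_ihc_records(records)
  key <- paste(records$intensity, records$proportion, sep = ":")
  accepted <- paste(rule$accepted$intensity, rule$accepted$proportion,
                    sep = ":")
  key %in% accepted
}

#' Tabulate diagnostic confusion counts for one marker
#'
#' Counts, over the cases stained for `marker`, true/false positives and
#' negatives for diagnosing `target_type`: tp = target-type cases called
#' positive, fn = target-type cases called negative, fp/tn likewise over
#' the non-target cases. Restrict the comparison set with `types` when some
#' tumor types (e.g. a benign mimic evaluated only for its positivity rate)
#' should not enter specificity.
#'
#' @param records IHC records.
#' @param marker Marker label to tabulate.
#' @param target_type Tumor type the marker is meant to diagnose.
#' @param rule A [positivity_rule()].
#' @param types Optional character vector restricting which tumor types are
#'   tabulated (default: all present).
#' @return An object of class `confusion_counts`: list with integers `tp`,
#'   `fp`, `tn`, `fn` plus the `marker`, `target_type` and `rule` name.
#' @export
tabulate_ihc <- function(records, marker, target_type, rule, types = NULL) {
  validate_ihc_records(records)
  rec <- records[records$marker == marker, , drop = FALSE]
  if (!is.null(types))
    rec <- rec[rec$tumor_type %in% types, , drop = FALSE]
  dup <- rec$case_id[duplicated(rec$case_id)]
  if (length(dup) > 0)
    stop("duplicate (case_id, marker) pair(s) for marker '", marker, "': ",
         paste(unique(dup), collapse = ", "))
  pos <- if (nrow(rec) > 0) call_positivity(rec, rule) else logical(0)
  is_target <- rec$tumor_type == target_type
  structure(list(tp = sum(is_target & pos), fn = sum(is_target & !pos),
                 fp = sum(!is_target & pos), tn = sum(!is_target & !pos),
                 marker = marker, target_type = target_type,
                 rule = rule$name),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' For published 2x2 tallies that arrive as counts rather than per-case
#' records.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param marker,target_type,rule Labels carried through to the metrics.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn, marker = NA_character_,
                             target_type = NA_character_,
                             rule = NA_character_) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 marker = marker, target_type = target_type, rule = rule),
            class = "confusion_counts")
}

#' Diagnostic sensitivity and specificity with Wilson intervals
#'
#' Sensitivity = tp/(tp+fn) over target-type cases; specificity = tn/(tn+fp)
#' over the comparison cases. Both margins must be non-empty — with no
#' target cases or no comparison cases the corresponding metric is
#' undefined (use [positivity_rate()] for a single-type positivity
#' fraction). Point estimates are kept as exact ratios; the `*_pct` columns
#' round half-up to one decimal, the convention diagnostic percentages are
#' printed with. 95% intervals use the Wilson score method, which behaves
#' sensibly at observed rates of 0% and 100%.
#'
#' @param counts A `confusion_counts` object.
#' @param conf Confidence level (default 0.95).
#' @return A one-row data.frame: marker, target_type, rule, the four counts,
#'   `sensitivity`, `sens_pct`, `sens_lo`, `sens_hi`, `specificity`,
#'   `spec_pct`, `spec_lo`, `spec_hi`.
#' @examples
#' diagnostic_metrics(confusion_counts(tp = 23, fn = 0, fp = 9, tn = 154))
#' @export
diagnostic_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_target <- counts$tp + counts$fn
  n_other <- counts$tn + counts$fp
  if (n_target == 0)
    stop("no target-type cases: sensitivity undefined")
  if (n_other == 0)
    stop("no comparison cases: specificity undefined")
  sens <- counts$tp / n_target
  spec <- counts$tn / n_other
  sci <- wilson_ci(counts$tp, n_target, conf)
  pci <- wilson_ci(counts$tn, n_other, conf)
  data.frame(marker = counts$marker, target_type = counts$target_type,
             rule = counts$rule, tp = counts$tp, fn = counts$fn,
             fp = counts$fp, tn = counts$tn,
             sensitivity = sens, sens_pct = round_half_up(100 * sens, 1),
             sens_lo = unname(sci["lower"]), sens_hi = unname(sci["upper"]),
             specificity = spec, spec_pct = round_half_up(100 * spec, 1),
             spec_lo = unname(pci["lower"]), spec_hi = unname(pci["upper"]),
             stringsAsFactors = FALSE)
}

#' Positivity rate of a marker within one tumor type
#'
#' The fraction of cases of `tumor_type` called positive under `rule` — the
#' quantity reported for tumor types that are not part of a target/background
#' contrast (e.g. a benign mimic of the target subtype).
#'
#' @param records IHC records.
#' @param marker Marker label.
#' @param tumor_type Tumor type to rate.
#' @param rule A [positivity_rule()].
#' @param conf Confidence level for the Wilson interval.
#' @return One-row data.frame: marker, tumor_type, rule, `positive`, `n`,
#'   `rate`, `rate_pct` (half-up, 1 decimal), `rate_lo`, `rate_hi`.
#' @export
positivity_rate <- function(records, marker, tumor_type, rule, conf = 0.95) {
  validate_ihc_records(records)
  rec <- records[records$marker == marker &
                   records$tumor_type == tumor_type, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no records for marker '", marker, "' in tumor type '",
         tumor_type, "'")
  k <- sum(call_positivity(rec, rule))
  n <- nrow(rec)
  ci <- wilson_ci(k, n, conf)
  data.frame(marker = marker, tumor_type = tumor_type, rule = rule$name,
             positive = k, n = n, rate = k / n,
             rate_pct = round_half_up(100 * k / n, 1),
             rate_lo = unname(ci["lower"]), rate_hi = unname(ci["upper"]),
             stringsAsFactors = FALSE)
}
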