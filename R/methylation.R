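# CpG-level methylation association: per-probe comparison of beta values
# across subtypes (Kruskal-Wallis, hypomethylation flag on the median gap)
# and Spearman rank correlation of beta with normalized expression.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with the chi-square approximation on k-1 degrees of
#' freedom, via [stats::kruskal.test()]. The fully degenerate case — every
#' pooled observation identical, where the tie correction term is 0/0 — is
#' resolved to H = 0, p = 1 with a warning, since no rank separation exists.
#'
#' @param groups List of >= 2 non-empty numeric vectors, total length >= 3.
#' @return List with `H`, `p`, and `df`.
#' @export
kw_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total")
  if (!all(is.finite(x))) stop("observations must be finite")
  if (length(unique(x)) == 1) {
    warning("all observations identical; tie correction degenerate, ",
            "returning H = 0, p = 1")
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = max(kt$p.value, .Machine$double.xmin),
       df = unname(kt$parameter))
}

#' Spearman rank correlation with midrank ties
#'
#' Pearson correlation of midranks (average ranks over ties), with the
#' p-value from the t-distribution approximation — appropriate for the
#' heavily tied beta-value data this package targets. A constant vector has
#' no rank ordering: rho is returned as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 4; finite values.
#' @return List with `rho`, `p`, and `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("observations must be finite (drop missing pairs first)")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate),
       p = min(max(ct$p.value, .Machine$double.xmin), 1),
       n = length(x))
}

#' Associate CpG methylation with subtype and expression
#'
#' For every probe in `probe_gene_map`, computes on the sample intersection
#' of the three inputs: per-subtype median beta; `delta_median`, the
#' minimum over background subtypes of (background median - target median),
#' so the hypomethylation flag requires the target subtype to sit below
#' *every* background by strictly more than `delta_threshold`; the
#' Kruskal-Wallis statistic across subtypes; and the Spearman correlation of
#' beta with the linked gene's normalized expression, both pooled over all
#' samples and within each subtype (published analyses differ on which is
#' quoted, so both are reported). Missing beta values are excluded pairwise.
#'
#' @param meth Probe x sample beta matrix (values in \[0,1\], `NA` missing).
#' @param nm Normalized expression matrix sharing sample ids.
#' @param ann Annotation data.frame (`sample_id`, `subtype`).
#' @param probe_gene_map Data.frame with columns `probe_id`, `gene_id`.
#' @param target_subtype Subtype expected to be hypomethylated.
#' @param delta_threshold Median-gap threshold for the flag (default 0.25).
#' @return Data.frame with one row per probe: `probe_id`, `gene_id`,
#'   `median_beta_<subtype>` columns, `delta_median`, `hypo_flag`, `kw_H`,
#'   `kw_p`, `rho`, `rho_p` (pooled), and `rho_<subtype>` columns.
#' @export
associate_methylation <- function(meth, nm, ann, probe_gene_map,
                                  target_subtype, delta_threshold = 0.25) {
  validate_annotation(ann)
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_gene_map)))
  samples <- Reduce(intersect, list(colnames(meth), colnames(nm),
                                    ann$sample_id))
  if (length(samples) == 0)
    stop("no samples shared between methylation, expression, and annotation")
  msg("methylation association on %d shared samples", length(samples))
  if (!target_subtype %in% ann$subtype)
    stop("target subtype '", target_subtype, "' absent from annotation")
  missing_probes <- setdiff(probe_gene_map$probe_id, rownames(meth))
  if (length(missing_probes) > 0)
    stop("probe(s) absent from beta table: ",
         paste(missing_probes, collapse = ", "))
  missing_genes <- setdiff(probe_gene_map$gene_id, rownames(nm))
  if (length(missing_genes) > 0)
    stop("mapped gene(s) absent from expression: ",
         paste(missing_genes, collapse = ", "))
  subtype_of <- stats::setNames(ann$subtype, ann$sample_id)[samples]
  subtypes <- sort(unique(ann$subtype))
  backgrounds <- setdiff(subtypes, target_subtype)

  rows <- lapply(seq_len(nrow(probe_gene_map)), function(i) {
    probe <- probe_gene_map$probe_id[i]
    gene <- probe_gene_map$gene_id[i]
    beta <- meth[probe, samples]
    expr <- nm[gene, samples]
    med <- vapply(subtypes, function(st) {
      stats::median(beta[subtype_of == st], na.rm = TRUE)
    }, numeric(1))
    delta <- min(med[backgrounds] - med[target_subtype])
    groups <- lapply(subtypes, function(st) {
      v <- beta[subtype_of == st]
      v[!is.na(v)]
    })
    kw <- kw_test(groups)
    ok <- !is.na(beta)
    sp <- spearman_test(beta[ok], expr[ok])
    rho_by <- vapply(subtypes, function(st) {
      sel <- ok & subtype_of == st
      if (sum(sel) < 4) return(NA_real_)
      suppressWarnings(spearman_test(beta[sel], expr[sel])$rho)
    }, numeric(1))
    row <- data.frame(probe_id = probe, gene_id = gene,
                      stringsAsFactors = FALSE)
    row[sprintf("median_beta_%s", subtypes)] <- as.list(unname(med))
    row$delta_median <- delta
    row$hypo_flag <- delta > delta_threshold
    row$kw_H <- kw$H
    row$kw_p <- kw$p
    row$rho <- sp$rho
    row$rho_p <- sp$p
    row[sprintf("rho_%s", subtypes)] <- as.list(unname(rho_by))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
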