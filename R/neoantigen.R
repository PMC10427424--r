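#' Classify neoantigens by mutation persistence
#'
#' A neoantigen inherits its class from the presence of its source
#' mutation across treatment: `clearance` when the mutation is found only
#' in the pre-treatment tumor (eliminated under therapy), `novel` when
#' only post-treatment, `persistent` when present at both timepoints.
#'
#' @param mutations data frame with columns `mutation` (key), logical
#'   `pre` and `post` presence flags.
#' @return the input with an added `class` column.
#' @export
classify_neoantigens <- function(mutations) {
  stopifnot(all(c("mutation", "pre", "post") %in% names(mutations)))
  if (any(!mutations$pre & !mutations$post))
    stop("every mutation must be present at at least one timepoint")
  mutations$class <- ifelse(mutations$pre & mutations$post, "persistent",
                     ifelse(mutations$pre, "clearance", "novel"))
  mutations
}

#' Filter neoantigens on predicted MHC affinity
#'
#' Retains candidates with predicted affinity strictly below the
#' threshold (default < 500 nM; smaller nM = stronger binding).
#'
#' @param neoantigens data frame with an `affinity_nM` column.
#' @param threshold_nM affinity cutoff in nM (strict `<`).
#' @return the retained rows.
#' @export
filter_binders <- function(neoantigens, threshold_nM = 500) {
  stopifnot("affinity_nM" %in% names(neoantigens))
  if (any(neoantigens$affinity_nM <= 0)) stop("affinities must be positive")
  neoantigens[neoantigens$affinity_nM < threshold_nM, , drop = FALSE]
}

#' Filter TCR-neoantigen pairs on percentile rank
#'
#' Retains the top-binding pairs: percentile rank `<= top_percent`
#' (smaller rank = stronger predicted TCR-pMHC binding; the boundary is
#' inclusive).
#'
#' @param pairs data frame with a `rank` column of percentile ranks in
#'   `(0, 100]`.
#' @param top_percent rank cutoff (default 2.0).
#' @return the retained rows. Idempotent.
#' @export
filter_tcr_pairs <- function(pairs, top_percent = 2.0) {
  stopifnot("rank" %in% names(pairs))
  if (nrow(pairs) && (any(pairs$rank <= 0) || any(pairs$rank > 100)))
    stop("percentile ranks must lie in (0, 100]")
  pairs[pairs$rank <= top_percent, , drop = FALSE]
}

#' Count high-affinity ITCs per patient
#'
#' Given filtered TCR-neoantigen pairs, counts the distinct ITC
#' clonotypes with at least one retained pair, and the breakdown of
#' recognized neoantigen classes.
#'
#' @param pairs data frame with columns `clonotype`, `peptide` and
#'   optionally `class` (neoantigen class).
#' @param itcs character vector of ITC clonotype keys; pairs whose
#'   clonotype is not an ITC are ignored.
#' @return list with `n_itcs` (distinct high-affinity ITC clonotypes) and
#'   `class_counts` (named vector of distinct neoantigens recognized per
#'   class, when `class` is present).
#' @export
count_high_affinity_itcs <- function(pairs, itcs) {
  stopifnot(all(c("clonotype", "peptide") %in% names(pairs)))
  hit <- pairs[pairs$clonotype %in% itcs, , drop = FALSE]
  out <- list(n_itcs = length(unique(hit$clonotype)))
  if ("class" %in% names(pairs)) {
    out$class_counts <- vapply(
      c("clearance", "novel", "persistent"),
      function(cl) length(unique(hit$peptide[hit$class == cl])), numeric(1))
  }
  out
}

#' Pearson correlation with pathological response
#'
#' Two-sided Pearson correlation between a per-patient quantity (for
#' example the number of high-affinity ITCs) and the percent residual
#' viable tumor, with a t-distributed p-value on n - 2 degrees of
#' freedom.
#'
#' @param values numeric per-patient values.
#' @param residual_tumor_percent numeric per-patient residual tumor
#'   percentages.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_with_response <- function(values, residual_tumor_percent) {
  stopifnot(length(values) == length(residual_tumor_percent))
  if (length(values) < 3) stop("need at least 3 patients")
  if (stats::sd(values) == 0 || stats::sd(residual_tumor_percent) == 0)
    stop("correlation undefined: zero variance input")
  ct <- stats::cor.test(values, residual_tumor_percent,
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(values))
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutation count per megabase of the assayed exome
#' (default panel 33.86 Mb).
#'
#' @param n_nonsynonymous non-negative mutation count.
#' @param panel_mb assayed panel size in Mb.
#' @return mutations per Mb.
#' @export
tmb <- function(n_nonsynonymous, panel_mb = 33.86) {
  if (any(n_nonsynonymous < 0)) stop("mutation count must be non-negative")
  n_nonsynonymous / panel_mb
}
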