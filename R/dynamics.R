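#' Identify intratumoral T cell clonotypes (ITCs)
#'
#' ITCs are clonotypes shared between the pre-treatment and post-treatment
#' tumor repertoires of the same patient.
#'
#' @param pre_tumor,post_tumor productive-filtered `clonotype_table`s from
#'   the same patient, using the same clonotype key definition.
#' @return character vector of shared clonotype keys.
#' @export
identify_itcs <- function(pre_tumor, post_tumor) {
  check_same_patient(pre_tumor, post_tumor)
  intersect(clone_keys(pre_tumor), clone_keys(post_tumor))
}

check_same_patient <- function(a, b) {
  stopifnot(inherits(a, "clonotype_table"), inherits(b, "clonotype_table"))
  pa <- attr(a, "patient"); pb <- attr(b, "patient")
  if (!is.na(pa) && !is.na(pb) && pa != pb)
    stop(sprintf("tables come from different patients ('%s' vs '%s')", pa, pb))
  if (attr(a, "key") != attr(b, "key"))
    stop("tables use different clonotype key definitions")
  invisible(TRUE)
}

#' Clonal space of a clone set
#'
#' The summed frequency of the member clones relative to the total T cell
#' repertoire of `table`. Keys absent from the table contribute 0.
#'
#' @param keys character vector of clonotype keys.
#' @param table a `clonotype_table`.
#' @return a proportion in `[0, 1]`.
#' @export
clonal_space <- function(keys, table) {
  stopifnot(inherits(table, "clonotype_table"))
  sum(table$freq[clone_keys(table) %in% keys])
}

#' Clonotype fraction of a clone set
#'
#' The number of member clonotypes present in `table` divided by the
#' table's richness.
#'
#' @inheritParams clonal_space
#' @return a proportion in `[0, 1]`.
#' @export
clonotype_fraction <- function(keys, table) {
  stopifnot(inherits(table, "clonotype_table"))
  length(intersect(keys, clone_keys(table))) / richness(table)
}

#' Build pre/post clone pairs for dynamics classification
#'
#' Aligns two repertoires on the clonotype key and records the count and
#' repertoire total on each side. Clones absent from one side get count 0.
#'
#' @param pre,post `clonotype_table`s (same patient and key definition).
#' @return data frame with columns `key`, `count_pre`, `total_pre`,
#'   `count_post`, `total_post`, `freq_pre`, `freq_post`.
#' @export
make_clone_pairs <- function(pre, post) {
  check_same_patient(pre, post)
  kp <- clone_keys(pre); kq <- clone_keys(post)
  keys <- union(kp, kq)
  cp <- pre$count[match(keys, kp)]; cp[is.na(cp)] <- 0
  cq <- post$count[match(keys, kq)]; cq[is.na(cq)] <- 0
  tp <- sum(pre$count); tq <- sum(post$count)
  data.frame(key = keys, count_pre = cp, total_pre = tp,
             count_post = cq, total_post = tq,
             freq_pre = cp / tp, freq_post = cq / tq,
             stringsAsFactors = FALSE)
}

#' Classify clonal expansion and contraction
#'
#' Each clone pair is categorized by the direction of its frequency change
#' (`expanded`, `contracted`, `unchanged`; `new` when absent pre-treatment,
#' `lost` when absent post-treatment). For ITCs (nonzero on both sides) a
#' two-sided Fisher's exact test on the 2x2 table
#' `[[count_pre, total_pre - count_pre], [count_post, total_post - count_post]]`
#' flags differentially expanded/contracted clones at `p < alpha`. `new`
#' and `lost` clones are tracked as their own categories and are not
#' Fisher-tested.
#'
#' @param pairs data frame as returned by [make_clone_pairs()].
#' @param alpha per-clone significance level (unadjusted, default 0.05).
#' @param adjust `"none"` (default, per-clone p < alpha as in the trial
#'   analysis) or `"BH"` for Benjamini-Hochberg adjustment across the
#'   tested clones.
#' @return the input with added columns `category`, `p_value` (NA for
#'   new/lost) and logical `differential`.
#' @export
classify_dynamics <- function(pairs, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  req <- c("key", "count_pre", "total_pre", "count_post", "total_post")
  stopifnot(all(req %in% names(pairs)))
  if (any(pairs$count_pre < 0) || any(pairs$count_post < 0))
    stop("counts must be non-negative")
  if (any(pairs$count_pre > pairs$total_pre) ||
      any(pairs$count_post > pairs$total_post))
    stop("counts exceed repertoire totals")

  fp <- pairs$count_pre / pairs$total_pre
  fq <- pairs$count_post / pairs$total_post
  category <- ifelse(pairs$count_pre == 0, "new",
              ifelse(pairs$count_post == 0, "lost",
              ifelse(fq > fp, "expanded",
              ifelse(fq < fp, "contracted", "unchanged"))))

  p <- rep(NA_real_, nrow(pairs))
  itc <- pairs$count_pre > 0 & pairs$count_post > 0
  if (any(itc)) {
    p[itc] <- vapply(which(itc), function(i) {
      m <- matrix(c(pairs$count_pre[i],
                    pairs$total_pre[i] - pairs$count_pre[i],
                    pairs$count_post[i],
                    pairs$total_post[i] - pairs$count_post[i]),
                  nrow = 2, byrow = TRUE)
      stats::fisher.test(m)$p.value
    }, numeric(1))
  }
  padj <- p
  if (adjust == "BH") padj[itc] <- stats::p.adjust(p[itc], method = "BH")
  out <- pairs
  out$category <- category
  out$p_value <- p
  out$differential <- !is.na(padj) & padj < alpha &
    category %in% c("expanded", "contracted")
  out
}

#' Decade frequency-rank bins
#'
#' Assigns each clone to the frequency decade `10^0, 10^-1, ..., 10^-6`
#' containing its frequency (label `10^floor(log10(f))`, clamped to the
#' `10^-6` bin below that frequency).
#'
#' @param table a `clonotype_table` with frequencies in `(0, 1]`.
#' @return named integer vector of clone counts per decade bin (all seven
#'   bins present; bins sum to richness).
#' @export
frequency_rank_bins <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  f <- table$freq
  if (any(f <= 0) || any(f > 1)) stop("frequencies must lie in (0, 1]")
  k <- pmax(pmin(floor(log10(f)), 0), -6)
  labs <- paste0("10^", 0:-6)
  counts <- table(factor(paste0("10^", k), levels = labs))
  out <- as.integer(counts)
  names(out) <- labs
  out
}

#' Circulating ITCs across a longitudinal blood series
#'
#' For each blood timepoint, the ITC clonotypes detected in blood, their
#' number and their clonal space within the blood repertoire.
#'
#' @param itcs character vector of ITC clonotype keys.
#' @param blood_series list of blood `clonotype_table`s ordered by
#'   timepoint.
#' @return data frame with one row per timepoint: `timepoint`,
#'   `n_circulating`, `clonal_space`.
#' @export
circulating_itcs <- function(itcs, blood_series) {
  if (length(blood_series) == 0) stop("blood series is empty")
  rows <- lapply(seq_along(blood_series), function(i) {
    tab <- blood_series[[i]]
    stopifnot(inherits(tab, "clonotype_table"))
    tp <- attr(tab, "timepoint")
    if (is.na(tp)) tp <- as.character(i)
    data.frame(timepoint = tp,
               n_circulating = length(intersect(itcs, clone_keys(tab))),
               clonal_space = clonal_space(itcs, tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary of circulating-ITC dynamics
#'
#' Mean and standard error of the mean of the circulating-ITC clonal space
#' at each timepoint across patients.
#'
#' @param per_patient list of data frames from [circulating_itcs()], one
#'   per patient (same timepoints).
#' @return data frame `timepoint`, `mean_space`, `sem_space`, `n`.
#' @export
summarize_circulating <- function(per_patient) {
  stopifnot(length(per_patient) >= 1)
  tp <- per_patient[[1]]$timepoint
  mat <- vapply(per_patient, function(d) d$clonal_space[match(tp, d$timepoint)],
                numeric(length(tp)))
  mat <- matrix(mat, nrow = length(tp))
  n <- ncol(mat)
  data.frame(timepoint = tp,
             mean_space = rowMeans(mat),
             sem_space = apply(mat, 1, stats::sd) / sqrt(n),
             n = n, stringsAsFactors = FALSE)
}

#' Circulating subsets of classified ITCs
#'
#' Intersects each dynamic category (differential expanded, differential
#' contracted, new) with the clonotypes detected in blood at each
#' timepoint.
#'
#' @param classified output of [classify_dynamics()].
#' @param blood_series list of blood `clonotype_table`s ordered by
#'   timepoint.
#' @return data frame with `timepoint`, `subset`, `n`, `clonal_space`
#'   (space measured in the blood repertoire).
#' @export
subset_circulating <- function(classified, blood_series) {
  sets <- list(
    expanded = classified$key[classified$category == "expanded" &
                                classified$differential],
    contracted = classified$key[classified$category == "contracted" &
                                  classified$differential],
    new = classified$key[classified$category == "new"])
  rows <- list()
  for (i in seq_along(blood_series)) {
    tab <- blood_series[[i]]
    tp <- attr(tab, "timepoint")
    if (is.na(tp)) tp <- as.character(i)
    bk <- clone_keys(tab)
    for (s in names(sets)) {
      keys <- intersect(sets[[s]], bk)
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = tp, subset = s, n = length(keys),
        clonal_space = clonal_space(keys, tab), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Post-treatment clonal flow summary
#'
#' Attributes every post-treatment tumor clonotype to one of four sources
#' (`expanded` ITC, `contracted` ITC, `unchanged` ITC, `new` infiltrating
#' clonotype) and reports the fraction of clonotypes and of clonal space in
#' each source, plus the fraction of each source's clonotypes also detected
#' in peripheral blood.
#'
#' @param post_tumor post-treatment tumor `clonotype_table`.
#' @param classified output of [classify_dynamics()] covering all
#'   post-treatment clonotypes.
#' @param blood_tables optional list of blood `clonotype_table`s; detection
#'   is the union over the series.
#' @return data frame with one row per category: `category`,
#'   `clonotype_fraction`, `clonal_space`, `blood_detected_fraction`.
#'   Fractions over categories sum to 1.
#' @export
flow_summary <- function(post_tumor, classified, blood_tables = list()) {
  stopifnot(inherits(post_tumor, "clonotype_table"))
  keys <- clone_keys(post_tumor)
  idx <- match(keys, classified$key)
  if (anyNA(idx))
    stop("classification does not cover all post-treatment clonotypes")
  cat4 <- classified$category[idx]
  if (any(cat4 == "lost"))
    stop("'lost' clones cannot appear in the post-treatment table")
  blood_keys <- unique(unlist(lapply(blood_tables, clone_keys)))
  lv <- c("expanded", "contracted", "unchanged", "new")
  rows <- lapply(lv, function(cc) {
    k <- keys[cat4 == cc]
    data.frame(category = cc,
               clonotype_fraction = length(k) / length(keys),
               clonal_space = clonal_space(k, post_tumor),
               blood_detected_fraction =
                 if (length(k)) length(intersect(k, blood_keys)) / length(k)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
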