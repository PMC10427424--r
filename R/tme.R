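#' Default hallmark groups for TME subtype labeling
#'
#' Three marker groups used to name the clusters of hallmark ssGSEA
#' profiles: immune-enriched (interferon/inflammatory response),
#' tumor-proliferation (E2F, MYC, DNA repair, mTORC1), and
#' fibroblast-enriched (EMT, TGF-beta, KRAS, angiogenesis).
#'
#' @return named list of hallmark-name vectors (`IE`,
#'   `tumor_proliferation`, `fibroblast_enriched`).
#' @export
default_hallmark_groups <- function() {
  list(
    IE = c("HALLMARK_INTERFERON_GAMMA_RESPONSE",
           "HALLMARK_INTERFERON_ALPHA_RESPONSE",
           "HALLMARK_INFLAMMATORY_RESPONSE"),
    tumor_proliferation = c("HALLMARK_E2F_TARGETS", "HALLMARK_MYC_TARGETS_V1",
                            "HALLMARK_DNA_REPAIR",
                            "HALLMARK_MTORC1_SIGNALING"),
    fibroblast_enriched = c("HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION",
                            "HALLMARK_TGF_BETA_SIGNALING",
                            "HALLMARK_KRAS_SIGNALING_UP",
                            "HALLMARK_ANGIOGENESIS"))
}

#' Cluster samples on hallmark scores
#'
#' Rows (hallmarks) are z-scored, samples are clustered by agglomerative
#' hierarchical clustering with Euclidean distance and Ward linkage on
#' squared distances (`ward.D2`), and the tree is cut at `k` clusters.
#' Deterministic: no random initialization; permuting sample order leaves
#' the partition unchanged up to label renaming.
#'
#' @param scores hallmarks x samples score matrix.
#' @param k number of clusters (default 3).
#' @return integer vector of cluster ids named by sample.
#' @export
cluster_tme <- function(scores, k = 3) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) < k)
    stop("need at least k = ", k, " samples to cut ", k, " clusters")
  z <- t(apply(scores, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  hc <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Label clusters as TME subtypes
#'
#' Each cluster is labeled by the hallmark group with the highest mean
#' scaled score within the cluster. Ties are broken by the fixed priority
#' IE > tumor_proliferation > fibroblast_enriched (with a warning). Two
#' clusters may not share a label: conflicts are resolved by assigning the
#' weaker cluster its best unused group.
#'
#' @param clusters integer cluster ids per sample (from [cluster_tme()]).
#' @param scores hallmarks x samples scaled score matrix.
#' @param hallmark_groups named list of hallmark groups (default
#'   [default_hallmark_groups()]).
#' @return data frame with `sample`, `cluster`, `subtype`.
#' @export
label_clusters <- function(clusters, scores,
                           hallmark_groups = default_hallmark_groups()) {
  stopifnot(is.matrix(scores), length(clusters) == ncol(scores))
  for (g in names(hallmark_groups)) {
    if (!any(hallmark_groups[[g]] %in% rownames(scores)))
      stop("no hallmark of group '", g, "' is present in the score matrix")
  }
  ids <- sort(unique(clusters))
  priority <- names(hallmark_groups)
  # mean group score per cluster
  m <- sapply(ids, function(cl) {
    vapply(hallmark_groups, function(hs) {
      hs <- intersect(hs, rownames(scores))
      mean(scores[hs, clusters == cl, drop = FALSE])
    }, numeric(1))
  })
  m <- matrix(m, nrow = length(hallmark_groups),
              dimnames = list(priority, ids))
  label <- character(length(ids))
  # assign greedily by decreasing best score so conflicts go to the
  # stronger cluster; priority order breaks exact ties
  remaining <- priority
  open <- seq_along(ids)
  tied <- FALSE
  while (length(open)) {
    best <- vapply(open, function(i) max(m[remaining, i]), numeric(1))
    i <- open[which.max(best)]
    top <- m[remaining, i]
    if (sum(top == max(top)) > 1) tied <- TRUE
    g <- remaining[which.max(top)]
    label[i] <- g
    remaining <- setdiff(remaining, g)
    open <- setdiff(open, i)
    if (length(remaining) == 0 && length(open) > 0) {
      # more clusters than groups: reuse full priority list
      remaining <- priority
    }
  }
  if (tied)
    warning("tied cluster scores; resolved by group priority order")
  data.frame(sample = colnames(scores), cluster = clusters,
             subtype = label[match(clusters, ids)],
             stringsAsFactors = FALSE)
}

#' Subtype centroids from a labeled clustering
#'
#' @param scores hallmarks x samples scaled score matrix.
#' @param assignment data frame from [label_clusters()].
#' @return hallmarks x subtypes centroid matrix.
#' @export
tme_centroids <- function(scores, assignment) {
  subtypes <- unique(assignment$subtype)
  cen <- sapply(subtypes, function(s)
    rowMeans(scores[, assignment$subtype == s, drop = FALSE]))
  matrix(cen, nrow = nrow(scores),
         dimnames = list(rownames(scores), subtypes))
}

#' Assign a new sample to the nearest TME subtype centroid
#'
#' Nearest centroid by Euclidean distance on the scaled hallmark scores.
#' Equidistant samples are assigned deterministically by the priority
#' IE > tumor_proliferation > fibroblast_enriched and flagged with a
#' warning.
#'
#' @param sample_scores numeric vector of scaled hallmark scores, named
#'   like the centroid rows.
#' @param centroids hallmarks x subtypes matrix from [tme_centroids()].
#' @return the subtype label (character).
#' @export
assign_new_sample <- function(sample_scores, centroids) {
  if (length(sample_scores) != nrow(centroids))
    stop("sample score vector and centroids have different dimensions")
  if (!is.null(names(sample_scores)))
    sample_scores <- sample_scores[rownames(centroids)]
  d <- apply(centroids, 2, function(c) sqrt(sum((sample_scores - c)^2)))
  priority <- c("IE", "tumor_proliferation", "fibroblast_enriched")
  ord <- order(d, match(colnames(centroids), priority))
  if (sum(d == min(d)) > 1)
    warning("sample equidistant from centroids; tie broken by priority")
  colnames(centroids)[ord[1]]
}
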