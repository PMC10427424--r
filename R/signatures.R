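#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of uppercased gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    toupper(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (any(lengths(sets) == 0)) stop("GMT contains an empty gene set")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-symbol vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' Genes x samples of log2(FPKM + 1) values; first column holds gene
#' symbols (uppercased on load). Known typographical variants of gene
#' symbols are corrected via a small alias map (currently `CXLC9 ->
#' CXCL9`).
#'
#' @param path TSV file path.
#' @return numeric matrix with gene-symbol rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- normalize_gene_symbols(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  rownames(mat) <- genes
  mat
}

gene_symbol_aliases <- c(CXLC9 = "CXCL9")

normalize_gene_symbols <- function(x) {
  x <- toupper(x)
  hit <- x %in% names(gene_symbol_aliases)
  x[hit] <- gene_symbol_aliases[x[hit]]
  x
}

#' Built-in immune cell-score gene lists
#'
#' Marker gene lists for the mean-expression immune signatures: CD8
#' lineage, exhaustion (immune checkpoints), chemokine ligands, HLA class
#' II, and dendritic cells.
#'
#' @return named list of gene-symbol vectors.
#' @export
immune_score_gene_sets <- function() {
  list(
    cd8_lineage = c("CD2", "CD3D", "CD3E", "CD8A", "CD8B"),
    exhausted = c("CD274", "HAVCR2", "TNFRSF9", "CTLA4", "TOX"),
    chemokine = c("GZMB", "CXCL9", "CXCL10", "CCL5"),
    hla_ii = c("HLA-DRA", "HLA-DRB1", "HLA-DRB2", "HLA-DRB3", "HLA-DRB4",
               "HLA-DRB5", "HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DQB2",
               "HLA-DPA1", "HLA-DPB1"),
    dc = c("FLT3", "CLEC9A", "XCR1"))
}

#' Mean-expression signature score
#'
#' The arithmetic mean of log2(FPKM + 1) expression over the listed genes,
#' per sample. Genes absent from the matrix are dropped with a message;
#' if none are present an error lists the missing symbols.
#'
#' @param matrix genes x samples expression matrix (log2 scale).
#' @param gene_list character vector of gene symbols.
#' @return named numeric vector of per-sample scores.
#' @export
mean_signature_score <- function(matrix, gene_list) {
  gene_list <- normalize_gene_symbols(gene_list)
  present <- intersect(gene_list, rownames(matrix))
  if (length(present) == 0)
    stop("none of the signature genes are present: ",
         paste(gene_list, collapse = ", "))
  missing <- setdiff(gene_list, present)
  if (length(missing))
    message("signature genes absent from matrix: ",
            paste(missing, collapse = ", "))
  colMeans(matrix[present, , drop = FALSE])
}

#' Immune cytolytic activity
#'
#' The geometric mean of GZMA and PRF1 expression on the linear scale
#' (`2^log2val - 1`), reported on the linear scale.
#'
#' @param matrix genes x samples expression matrix (log2(FPKM + 1)).
#' @return named numeric vector of per-sample cytolytic activity.
#' @export
cytolytic_activity <- function(matrix) {
  for (g in c("GZMA", "PRF1"))
    if (!g %in% rownames(matrix)) stop("gene '", g, "' missing from matrix")
  lin <- 2^matrix[c("GZMA", "PRF1"), , drop = FALSE] - 1
  sqrt(lin["GZMA", ] * lin["PRF1", ])
}

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; ties get
#' their average rank). The enrichment score of a set is the sum over all
#' gene positions of the difference between the weighted in-set empirical
#' CDF (weights `rank^exponent`, normalized over set members, where the
#' most highly expressed gene has the largest rank) and the unweighted
#' out-of-set ECDF. With `normalize = TRUE` scores are divided by the
#' spread (max - min) over all sets and samples.
#'
#' @param matrix genes x samples expression matrix.
#' @param gene_sets named list of gene-symbol vectors (GMT-style).
#' @param weight_exponent rank-weight exponent (default 0.25).
#' @param normalize divide by the global score spread (default TRUE).
#' @return sets x samples numeric matrix of enrichment scores.
#' @export
ssgsea <- function(matrix, gene_sets, weight_exponent = 0.25,
                   normalize = TRUE) {
  stopifnot(is.matrix(matrix), length(gene_sets) >= 1)
  genes <- rownames(matrix)
  n <- length(genes)
  memb <- lapply(gene_sets, function(s) {
    m <- genes %in% normalize_gene_symbols(s)
    if (!any(m)) stop("gene set has no member present in the matrix")
    if (all(m)) stop("gene set covers every gene; out-of-set ECDF undefined")
    m
  })
  es <- matrix(0, length(gene_sets), ncol(matrix),
               dimnames = list(names(gene_sets), colnames(matrix)))
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    # descending order, ties broken by gene position for a stable walk
    ord <- order(-x, seq_len(n))
    r <- rank(x, ties.method = "average")   # largest expression -> rank n
    w <- r^weight_exponent
    for (s in seq_along(memb)) {
      m <- memb[[s]][ord]
      ws <- w[ord]
      win <- ifelse(m, ws, 0)
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!m) / sum(!m)
      es[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    spread <- max(es) - min(es)
    if (spread > 0) es <- es / spread
  }
  es
}

#' Scale hallmark scores to the [-2, 2] presentation range
#'
#' Z-scores each hallmark (row) across samples and clips to `[-2, 2]`.
#' Zero-variance rows become all zeros with a warning.
#'
#' @param scores sets x samples score matrix.
#' @return scaled matrix, same dimensions.
#' @export
scale_hallmark_scores <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) >= 2)
  out <- t(apply(scores, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }))
  if (any(apply(scores, 1, stats::sd) == 0))
    warning("zero-variance hallmark row(s) set to 0")
  dimnames(out) <- dimnames(scores)
  pmin(pmax(out, -2), 2)
}

#' Select IFN/EMT candidate genes
#'
#' Candidate features for the IFN/EMT signature: genes belonging to the
#' EMT, IFN-alpha or IFN-gamma gene sets whose group-mean log2 expression
#' differs by at least `min_log2_diff` (default 1, i.e. two-fold on the
#' linear scale; boundary inclusive) between well and poor responders.
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param labels per-sample factor/character with levels `well` and
#'   `poor` (order of `colnames(matrix)`).
#' @param gene_sets list of the three gene sets (any names; the union is
#'   used).
#' @param min_log2_diff inclusion threshold on `|mean(well) - mean(poor)|`.
#' @return character vector of candidate gene symbols.
#' @export
select_ifn_emt_candidates <- function(matrix, labels, gene_sets,
                                      min_log2_diff = 1) {
  labels <- as.character(labels)
  if (!all(c("well", "poor") %in% labels))
    stop("both 'well' and 'poor' labels must be present")
  pool <- intersect(unique(normalize_gene_symbols(unlist(gene_sets))),
                    rownames(matrix))
  if (length(pool) == 0) stop("no gene-set member present in the matrix")
  d <- abs(rowMeans(matrix[pool, labels == "well", drop = FALSE]) -
             rowMeans(matrix[pool, labels == "poor", drop = FALSE]))
  pool[d >= min_log2_diff]
}

#' Fit the IFN/EMT elastic-net signature
#'
#' Fits a gaussian elastic net of the binary response (well = 1, poor = 0)
#' on the candidate genes, minimizing
#' `(1/2n) RSS + lambda * (alpha*|beta|_1 + (1-alpha)/2*|beta|_2^2)`
#' with predictors standardized to unit (1/n) variance. Genes with
#' nonzero coefficients form the signature; the standardization parameters
#' are frozen into the model so later scoring reproduces the training
#' fit.
#'
#' @param matrix genes x samples log2 expression matrix restricted (or
#'   not) to candidate genes; rows named by gene.
#' @param labels per-sample `well`/`poor` labels.
#' @param genes genes to offer to the fit (default all rows of `matrix`).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param lambda penalty (default 0.24).
#' @return an object of class `signature_model` with elements `genes`,
#'   `coefficients`, `intercept`, `center`, `scale`, `alpha`, `lambda`.
#' @export
fit_ifn_emt_score <- function(matrix, labels, genes = rownames(matrix),
                              alpha = 0.5, lambda = 0.24) {
  labels <- as.character(labels)
  y <- as.numeric(labels == "well")
  if (length(unique(labels)) < 2) stop("both labels must be present")
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) < 2) stop("need at least 2 candidate genes")
  if (ncol(matrix) < 4) stop("need at least 4 samples")
  x <- t(matrix[genes, , drop = FALSE])
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(scl == 0)) {
    keep <- scl > 0
    x <- x[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
    genes <- genes[keep]
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  sol <- enet_coordinate_descent(xs, y, alpha, lambda)
  nz <- which(sol$beta != 0)
  if (length(nz) == 0)
    stop("no nonzero coefficients at lambda = ", lambda,
         "; lower lambda to obtain a non-empty model")
  structure(list(genes = genes[nz], coefficients = sol$beta[nz],
                 intercept = sol$intercept,
                 center = unname(ctr[nz]), scale = unname(scl[nz]),
                 alpha = alpha, lambda = lambda),
            class = "signature_model")
}

# Cyclic coordinate descent for the elastic net
#   (1/2n)||y - b0 - X beta||^2 + lambda [alpha |beta|_1
#                                         + (1-alpha)/2 |beta|_2^2]
# on predictors already centered and scaled to unit 1/n variance, so the
# single-coordinate update is the exact soft-threshold solution.
enet_coordinate_descent <- function(xs, y, alpha, lambda, tol = 1e-12,
                                    maxit = 100000L) {
  p <- ncol(xs)
  yc <- y - mean(y)
  beta <- rep(0, p)
  r <- yc
  denom <- 1 + lambda * (1 - alpha)
  thr <- lambda * alpha
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      z <- beta[j] + mean(xs[, j] * r)
      bnew <- sign(z) * max(abs(z) - thr, 0) / denom
      if (bnew != beta[j]) {
        r <- r - xs[, j] * (bnew - beta[j])
        delta <- max(delta, abs(bnew - beta[j]))
        beta[j] <- bnew
      }
    }
    if (delta < tol) break
  }
  list(intercept = mean(y), beta = beta)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("IFN/EMT signature model: %d genes (alpha=%g, lambda=%g)\n",
              length(x$genes), x$alpha, x$lambda))
  print(data.frame(gene = x$genes, coefficient = x$coefficients))
  invisible(x)
}

#' Apply a fitted signature model
#'
#' Scores samples as `intercept + sum_j beta_j * (x_j - center_j)/scale_j`
#' with the standardization parameters frozen at training time.
#'
#' @param matrix genes x samples log2 expression matrix containing all
#'   model genes.
#' @param model a `signature_model` from [fit_ifn_emt_score()].
#' @return named numeric vector of per-sample scores.
#' @export
apply_signature <- function(matrix, model) {
  stopifnot(inherits(model, "signature_model"))
  missing <- setdiff(model$genes, rownames(matrix))
  if (length(missing))
    stop("model genes absent from matrix: ", paste(missing, collapse = ", "))
  x <- matrix[model$genes, , drop = FALSE]
  xs <- (x - model$center) / model$scale
  model$intercept + colSums(xs * model$coefficients)
}

#' Serialize / restore a signature model as JSON
#'
#' @param model a `signature_model`.
#' @param path file path.
#' @return [write_signature_model()] returns `path` invisibly;
#'   [read_signature_model()] the restored `signature_model`.
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$genes <- as.character(obj$genes)
  structure(obj, class = "signature_model")
}
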