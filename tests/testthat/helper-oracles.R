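# Independent oracles used to cross-check the package implementations.
# Each is coded directly from the defining formula, not by calling the
# code path under test.

# Two-sided exact p for the 2x2 table [[a, b], [c, d]]: enumerate the
# hypergeometric support and sum the probabilities of all tables at most
# as likely as the observed one (standard tie rule with a tiny relative
# slack for floating point).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  dens <- stats::dhyper(lo:hi, m1, m2, k)
  p0 <- stats::dhyper(a, m1, m2, k)
  min(1, sum(dens[dens <= p0 * (1 + 1e-7)]))
}

# Brute-force single-sample enrichment running sum: walk the genes in
# decreasing expression order and accumulate the weighted in-set ECDF
# minus the out-of-set ECDF, position by position.
ssgsea_oracle <- function(x, set, tau) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(-x, seq_len(n))
  inset <- names(x) %in% set
  denom_in <- sum(r[inset]^tau)
  denom_out <- sum(!inset)
  cin <- 0; cout <- 0; es <- 0
  for (pos in ord) {
    if (inset[pos]) cin <- cin + r[pos]^tau else cout <- cout + 1
    es <- es + (cin / denom_in - cout / denom_out)
  }
  unname(es)
}

# Hand product-limit estimator at the event times.
km_oracle <- function(times, events) {
  tev <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(tev))
  for (i in seq_along(tev)) {
    n <- sum(times >= tev[i])
    d <- sum(times == tev[i] & events == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = tev, surv = surv)
}

# Proximal-gradient (ISTA) elastic net on pre-standardized predictors
# (columns with zero mean and unit 1/n variance), gaussian loss
# (1/2n)*RSS + lambda*(alpha*l1 + (1-alpha)/2*l2), intercept = mean(y).
# A different algorithm from the package's cyclic coordinate descent.
prox_grad_enet_oracle <- function(xs, y, alpha, lambda, tol = 1e-13,
                                  maxit = 200000) {
  n <- nrow(xs); p <- ncol(xs)
  yc <- y - mean(y)
  G <- crossprod(xs) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha)
  step <- 1 / L
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    grad <- -crossprod(xs, yc - xs %*% beta) / n + lambda * (1 - alpha) * beta
    z <- beta - step * as.numeric(grad)
    bnew <- sign(z) * pmax(abs(z) - step * lambda * alpha, 0)
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  list(intercept = mean(y), beta = as.numeric(beta))
}

# Adjusted Rand index between two partitions (Hubert & Arabie form).
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(sum(tab), 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small helpers to build clonotype tables in code.
make_table <- function(counts, cdr3aa = NULL, ...) {
  n <- length(counts)
  if (is.null(cdr3aa))
    cdr3aa <- sprintf("CASS%04dLGF", seq_len(n))
  clonotype_table(data.frame(count = counts, cdr3aa = cdr3aa,
                             stringsAsFactors = FALSE), ...)
}
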