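rand_expr <- function(ng, ns, seed = 1, gene_names = NULL) {
  set.seed(seed)
  m <- matrix(runif(ng * ns, 0, 10), ng, ns)
  rownames(m) <- if (is.null(gene_names)) sprintf("G%03d", seq_len(ng))
                 else gene_names
  colnames(m) <- sprintf("S%02d", seq_len(ns))
  m
}

test_that("mean signature scores average log2 expression over present genes", {
  m <- rand_expr(5, 3, gene_names = c("CD2", "CD3D", "CD8A", "GZMA", "X1"))
  expect_equal(mean_signature_score(m, "CD2"), m["CD2", ])
  m2 <- matrix(c(2, 4), 2, 1, dimnames = list(c("A", "B"), "S1"))
  expect_equal(unname(mean_signature_score(m2, c("A", "B"))), 3)
  # gene-order symmetry
  expect_equal(mean_signature_score(m, c("CD2", "CD3D", "CD8A")),
               mean_signature_score(m, c("CD8A", "CD2", "CD3D")))
  # missing genes are reported; all-missing errors with the symbols
  expect_message(mean_signature_score(m, c("CD2", "NOPE")), "NOPE")
  expect_error(mean_signature_score(m, c("NOPE1", "NOPE2")), "NOPE1")
  # CXLC9 alias maps onto CXCL9
  m3 <- matrix(5, 1, 1, dimnames = list("CXCL9", "S1"))
  expect_equal(unname(mean_signature_score(m3, "CXLC9")), 5)
})

test_that("mean signature operator is linear in the log values", {
  m <- rand_expr(6, 4, seed = 3)
  genes <- rownames(m)[1:3]
  expect_equal(mean_signature_score(2.5 * m, genes),
               2.5 * mean_signature_score(m, genes))
})

test_that("cytolytic activity is the linear-scale geometric mean", {
  # linear values (4, 16) -> 8; stored as log2(value + 1)
  m <- matrix(log2(c(4, 16) + 1), 2, 1,
              dimnames = list(c("GZMA", "PRF1"), "S1"))
  expect_equal(unname(cytolytic_activity(m)), 8)
  # idempotence on equal values
  m2 <- matrix(log2(c(7, 7) + 1), 2, 1,
               dimnames = list(c("GZMA", "PRF1"), "S1"))
  expect_equal(unname(cytolytic_activity(m2)), 7)
  # zero annihilates
  m3 <- matrix(log2(c(0, 100) + 1), 2, 1,
               dimnames = list(c("GZMA", "PRF1"), "S1"))
  expect_equal(unname(cytolytic_activity(m3)), 0)
  expect_error(cytolytic_activity(m3[1, , drop = FALSE]), "PRF1")
})

test_that("ssgsea matches the brute-force running-sum oracle on small cases", {
  set.seed(7)
  for (rep in 1:60) {
    ng <- sample(3:8, 1); ns <- sample(1:3, 1)
    tau <- sample(c(0, 0.25, 1), 1)
    m <- rand_expr(ng, ns, seed = rep)
    set_size <- sample(seq_len(ng - 1), 1)
    gs <- list(S = sample(rownames(m), set_size))
    es <- ssgsea(m, gs, weight_exponent = tau, normalize = FALSE)
    for (j in seq_len(ns)) {
      expect_equal(es[1, j], ssgsea_oracle(m[, j], gs$S, tau),
                   tolerance = 1e-9)
    }
  }
})

test_that("ssgsea is rank-based and deterministic", {
  m <- rand_expr(20, 2, seed = 9)
  m[, 2] <- m[, 1]                       # identical columns
  gs <- list(A = rownames(m)[1:5], B = rownames(m)[6:12])
  es <- ssgsea(m, gs, normalize = FALSE)
  expect_equal(es[, 1], es[, 2])
  # invariance under a strictly monotone transform of one sample
  m2 <- m
  m2[, 1] <- exp(m2[, 1] / 3) + 5
  es2 <- ssgsea(m2, gs, normalize = FALSE)
  expect_equal(es2[, 1], es[, 1])
  # a set covering every gene is rejected
  expect_error(ssgsea(m, list(ALL = rownames(m))), "every gene")
})

test_that("hallmark scaling z-scores rows and clips to [-2, 2]", {
  s <- matrix(c(1, 3, 5, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("h1", "h2"), c("a", "b")))
  expect_warning(z <- scale_hallmark_scores(s), "zero-variance")
  expect_equal(unname(z["h1", ]), (c(1, 3) - 2) / stats::sd(c(1, 3)))
  expect_equal(unname(z["h2", ]), c(0, 0))
  set.seed(4)
  big <- matrix(rnorm(50, sd = 40), 5, 10)
  zz <- scale_hallmark_scores(big)
  expect_true(all(zz >= -2 & zz <= 2))
})

test_that("IFN/EMT candidate selection applies the set and fold gates", {
  genes <- c("IN1", "IN2", "OUT1")
  m <- matrix(5, 3, 6, dimnames = list(genes, sprintf("S%d", 1:6)))
  labels <- rep(c("well", "poor"), each = 3)
  m["IN1", labels == "well"] <- 6        # diff exactly 1: boundary in
  m["IN2", labels == "well"] <- 5.5      # diff 0.5: out
  m["OUT1", labels == "well"] <- 9       # big diff but not in any set
  sets <- list(EMT = "IN1", IFN_A = "IN2", IFN_G = "ZZZ")
  expect_equal(select_ifn_emt_candidates(m, labels, sets), "IN1")
  expect_error(select_ifn_emt_candidates(m, rep("well", 6), sets),
               "poor")
})

test_that("one-predictor elastic net equals the soft-threshold closed form", {
  set.seed(11)
  lam <- 0.24; alph <- 0.5
  hits <- 0
  for (rep in 1:12) {
    n <- 24
    x <- rnorm(n) + rep(c(0.8, 0), each = n / 2)
    y <- rep(c(1, 0), each = n / 2)
    xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    b_ols <- mean(xs * (y - mean(y)))
    expected <- if (abs(b_ols) > lam * alph)
      (b_ols - lam * alph * sign(b_ols)) / (1 + lam * (1 - alph)) else 0
    # companion predictor constructed exactly orthogonal to x and y so it
    # cannot perturb the single-variable solution
    v <- rnorm(n); v <- v - mean(v)
    xc <- x - mean(x); yc <- y - mean(y)
    v <- v - xc * sum(v * xc) / sum(xc * xc)
    v <- v - yc * sum(v * yc) / sum(yc * yc)
    v <- v - mean(v)
    m <- matrix(c(x, v), 2, n, byrow = TRUE,
                dimnames = list(c("g1", "g2"), sprintf("s%d", 1:n)))
    if (expected == 0) {
      expect_error(fit_ifn_emt_score(m, ifelse(y == 1, "well", "poor"),
                                     lambda = lam, alpha = alph),
                   "lower lambda")
    } else {
      hits <- hits + 1
      mod <- fit_ifn_emt_score(m, ifelse(y == 1, "well", "poor"),
                               lambda = lam, alpha = alph)
      i <- match("g1", mod$genes)
      expect_false(is.na(i))
      expect_equal(mod$coefficients[i], expected, tolerance = 1e-6)
      expect_false("g2" %in% mod$genes)
    }
  }
  expect_gt(hits, 5)   # the active branch is actually exercised
})

test_that("multi-predictor fits match an independent proximal-gradient solver", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 30; p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- as.numeric(runif(n) > 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    ctr <- colMeans(X)
    scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
    xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    lam <- runif(1, 0.02, 0.3); alph <- runif(1)
    oracle <- prox_grad_enet_oracle(xs, y, alph, lam)
    m <- t(X)
    rownames(m) <- sprintf("g%02d", seq_len(p))
    colnames(m) <- sprintf("s%02d", seq_len(n))
    mod <- tryCatch(
      fit_ifn_emt_score(m, ifelse(y == 1, "well", "poor"),
                        alpha = alph, lambda = lam),
      error = function(e) NULL)
    beta_pkg <- rep(0, p)
    if (!is.null(mod))
      beta_pkg[match(mod$genes, rownames(m))] <- mod$coefficients
    keep <- abs(oracle$beta) > 0 | beta_pkg != 0
    expect_equal(beta_pkg, oracle$beta, tolerance = 1e-6)
    if (!is.null(mod))
      expect_equal(mod$intercept, oracle$intercept, tolerance = 1e-6)
  }
})

test_that("penalty limits behave: huge lambda empties, lambda 0 gives OLS", {
  set.seed(17)
  n <- 20
  m <- rand_expr(3, n, seed = 17)
  labels <- rep(c("well", "poor"), each = n / 2)
  expect_error(fit_ifn_emt_score(m, labels, lambda = 1e6),
               "lower lambda")
  # vanishing penalty reproduces ordinary least squares on the
  # standardized predictors
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.numeric(labels == "well")
  xs <- apply(X, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  b_ols <- unname(coef(stats::lm(y ~ xs)))
  m2 <- t(X)
  dimnames(m2) <- list(c("a", "b", "c"), sprintf("s%d", 1:n))
  mod <- fit_ifn_emt_score(m2, labels, lambda = 1e-8)
  beta_pkg <- rep(0, 3)
  beta_pkg[match(mod$genes, c("a", "b", "c"))] <- mod$coefficients
  expect_equal(beta_pkg, b_ols[-1], tolerance = 1e-4)
  expect_equal(mod$intercept, b_ols[1], tolerance = 1e-4)
})

test_that("signature application reproduces fit-time scores and separates groups", {
  set.seed(19)
  m <- rand_expr(10, 18, seed = 19)
  labels <- rep(c("well", "poor"), each = 9)
  m[1:3, labels == "well"] <- m[1:3, labels == "well"] + 4
  mod <- fit_ifn_emt_score(m, labels)
  sc <- apply_signature(m, mod)
  # consistency: refitting scores equal glmnet fitted values by construction
  expect_equal(length(sc), 18)
  expect_gt(mean(sc[labels == "well"]), mean(sc[labels == "poor"]))
  # missing model gene errors with the symbol
  expect_error(apply_signature(m[-match(mod$genes[1], rownames(m)), ],
                               mod), mod$genes[1])
  # serialization round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(mod, path)
  back <- read_signature_model(path)
  expect_equal(apply_signature(m, back), sc, tolerance = 1e-12)
})

test_that("planted two-group signature data yields discriminative scores", {
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(134 * 18, 5, 0.5), 134, 18,
                dimnames = list(sprintf("g%03d", 1:134),
                                sprintf("s%02d", 1:18)))
    lab <- rep(c("well", "poor"), each = 9)
    X[1:3, lab == "well"] <- X[1:3, lab == "well"] + 2
    mod <- fit_ifn_emt_score(X, lab)
    sc <- apply_signature(X, mod)
    # AUC by rank comparison
    mean(outer(sc[lab == "well"], sc[lab == "poor"], ">") +
           0.5 * outer(sc[lab == "well"], sc[lab == "poor"], "=="))
  })
  expect_gt(mean(aucs), 0.9)
})
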