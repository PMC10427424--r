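#' Classify pathological response
#'
#' Response classes by percent residual viable tumor in the resected
#' specimen: `pCR` (0%, no viable tumor), `MPR` (<= 10%, includes pCR),
#' `pPR` ((10, 33]) and `pNR` (> 33). Patients with <= 33% residual tumor
#' are well responders, > 33% poor responders.
#'
#' @param residual_percent numeric vector of percent residual viable
#'   tumor, in `[0, 100]`.
#' @return data frame with `residual_percent`, `class` (finest class:
#'   pCR/MPR/pPR/pNR), logical `mpr` (class within MPR, i.e. <= 10%) and
#'   `responder` (`well`/`poor`).
#' @export
classify_pathologic_response <- function(residual_percent) {
  if (any(residual_percent < 0) || any(residual_percent > 100))
    stop("residual tumor percent must lie in [0, 100]")
  cls <- ifelse(residual_percent == 0, "pCR",
         ifelse(residual_percent <= 10, "MPR",
         ifelse(residual_percent <= 33, "pPR", "pNR")))
  data.frame(residual_percent = residual_percent,
             class = factor(cls, levels = c("pCR", "MPR", "pPR", "pNR")),
             mpr = residual_percent <= 10,
             responder = factor(ifelse(residual_percent <= 33,
                                       "well", "poor"),
                                levels = c("well", "poor")),
             stringsAsFactors = FALSE)
}

#' PD-L1 combined positive score (CPS)
#'
#' The number of PD-L1-positive cells (tumor cells, macrophages and
#' lymphocytes) divided by the total number of tumor cells, multiplied by
#' 100 and capped at 100 (assay convention).
#'
#' @param pdl1_positive_cells non-negative count of PD-L1-positive cells.
#' @param tumor_cells total tumor cell count (>= 100 per assay
#'   convention).
#' @return CPS value in `[0, 100]`.
#' @export
cps <- function(pdl1_positive_cells, tumor_cells) {
  if (any(tumor_cells == 0)) stop("tumor cell count must be positive")
  if (any(tumor_cells < 100))
    warning("fewer than 100 tumor cells; CPS is unreliable below the assay minimum")
  if (any(pdl1_positive_cells < 0)) stop("counts must be non-negative")
  pmin(100 * pdl1_positive_cells / tumor_cells, 100)
}

#' Weighted Kaplan-Meier estimate
#'
#' Product-limit estimator with optional per-subject weights (weighted
#' risk and event counts; deaths precede censorings at tied times).
#' Greenwood standard errors give pointwise confidence intervals; the
#' summary reports survival at 12 and 24 months.
#'
#' @param times positive event/censoring times (months).
#' @param events logical or 0/1 event indicators.
#' @param weights optional positive weights (default 1).
#' @param conf_level confidence level for the Greenwood interval.
#' @return an object of class `km_fit`: data frame `curve` with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `se`, `lower`, `upper`, plus
#'   `surv_12` and `surv_24` summaries.
#' @export
km_estimate <- function(times, events, weights = NULL, conf_level = 0.95) {
  stopifnot(length(times) == length(events))
  if (any(times <= 0)) stop("times must be positive")
  events <- as.numeric(events)
  if (is.null(weights)) weights <- rep(1, length(times))
  if (any(weights <= 0)) stop("weights must be positive")
  if (all(events == 0)) warning("all observations censored")

  tev <- sort(unique(times[events == 1]))
  s <- 1; gw <- 0
  na <- rep(NA_real_, length(tev))
  curve <- data.frame(time = tev, n_risk = na, n_event = na,
                      surv = na, se = na, lower = na, upper = na)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_along(tev)) {
    t <- tev[i]
    n <- sum(weights[times >= t])
    d <- sum(weights[times == t & events == 1])
    s <- s * (1 - d / n)
    if (n - d > 0) gw <- gw + d / (n * (n - d)) else gw <- Inf
    se <- if (is.finite(gw)) s * sqrt(gw) else NA_real_
    curve$n_risk[i] <- n; curve$n_event[i] <- d
    curve$surv[i] <- s; curve$se[i] <- se
    curve$lower[i] <- max(0, s - z * se)
    curve$upper[i] <- min(1, s + z * se)
  }
  fit <- structure(list(curve = curve,
                        n = length(times),
                        surv_12 = km_survival_at_curve(curve, 12),
                        surv_24 = km_survival_at_curve(curve, 24)),
                   class = "km_fit")
  fit
}

km_survival_at_curve <- function(curve, t) {
  idx <- which(curve$time <= t)
  if (length(idx) == 0)
    return(list(time = t, surv = 1, lower = 1, upper = 1))
  i <- max(idx)
  list(time = t, surv = curve$surv[i],
       lower = curve$lower[i], upper = curve$upper[i])
}

#' Survival probability at a given time
#'
#' @param fit a `km_fit` from [km_estimate()].
#' @param t time (months).
#' @return the step-function survival estimate at `t`.
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  km_survival_at_curve(fit$curve, t)$surv
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n=%d, %d event times\n",
              x$n, nrow(x$curve)))
  cat(sprintf("  S(12m) = %.3f [%.3f, %.3f]; S(24m) = %.3f [%.3f, %.3f]\n",
              x$surv_12$surv, x$surv_12$lower, x$surv_12$upper,
              x$surv_24$surv, x$surv_24$lower, x$surv_24$upper))
  invisible(x)
}

#' Weighted log-rank test
#'
#' Standard log-rank chi-square test comparing two or more groups, with
#' optional per-subject weights (IPTW-weighted risk sets and event
#' counts). Two-sided p from the chi-square distribution on k - 1 degrees
#' of freedom.
#'
#' @param times positive event/censoring times.
#' @param events event indicators.
#' @param groups group labels (>= 2 groups, each nonempty).
#' @param weights optional positive weights.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrank <- function(times, events, groups, weights = NULL) {
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2) stop("log-rank requires at least two groups")
  events <- as.numeric(events)
  if (is.null(weights)) weights <- rep(1, length(times))
  tev <- sort(unique(times[events == 1]))
  m <- length(tev)
  gi <- as.integer(groups)
  # weighted number at risk just before each event time, overall and by
  # group: reverse cumulative sums over the event-time grid
  pos <- findInterval(times, tev)        # at risk for event times 1..pos
  risk_of <- function(w) {
    tab <- tapply(w, factor(pos, levels = 0:m), sum, default = 0)
    rev(cumsum(rev(tab[-1])))
  }
  n_at <- risk_of(weights)
  Ng <- vapply(seq_len(k), function(g)
    risk_of(weights * (gi == g)), numeric(m))
  Ng <- matrix(Ng, nrow = m)
  # weighted events at each event time
  ev_pos <- factor(ifelse(events == 1, match(times, tev), NA),
                   levels = seq_len(m))
  d_at <- as.numeric(tapply(weights * events, ev_pos, sum, default = 0))
  Dg <- vapply(seq_len(k), function(g)
    as.numeric(tapply(weights * events * (gi == g), ev_pos, sum,
                      default = 0)), numeric(m))
  Dg <- matrix(Dg, nrow = m)
  P <- Ng / n_at
  O <- colSums(Dg)
  E <- colSums(d_at * P)
  c0 <- ifelse(n_at > 1, d_at * (n_at - d_at) / (n_at - 1), 0)
  V <- diag(colSums(c0 * P), k) - t(P) %*% (c0 * P)
  u <- (O - E)[-k]
  Vi <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(u) %*% solve(Vi, u)),
                    error = function(e) NA_real_)
  list(chisq = chisq, df = k - 1,
       p_value = stats::pchisq(chisq, k - 1, lower.tail = FALSE))
}

#' Inverse probability of treatment weights
#'
#' Estimates propensity scores by multinomial logistic regression of the
#' treatment arm on the supplied categorical covariates (maximum
#' likelihood) and returns `1 / P(assigned arm | covariates)` per
#' patient; the stabilized variant multiplies by the marginal probability
#' of the assigned arm.
#'
#' @param data data frame containing the covariates and arm column.
#' @param covariates character vector of covariate column names
#'   (categorical).
#' @param arm name of the treatment-arm column.
#' @param stabilized multiply by marginal arm probabilities (default
#'   TRUE).
#' @return list with `weights` (numeric), `propensity` (matrix of arm
#'   probabilities) and `stabilized`.
#' @export
propensity_weights <- function(data, covariates, arm,
                               stabilized = TRUE) {
  stopifnot(all(c(covariates, arm) %in% names(data)))
  a <- factor(as.character(data[[arm]]))
  if (nlevels(a) < 2) stop("need at least two treatment arms")
  for (cv in covariates) {
    tab <- table(data[[cv]], a)
    bad <- rownames(tab)[rowSums(tab > 0) == 1]
    if (length(bad))
      stop(sprintf(
        "separation: level '%s' of covariate '%s' occurs in only one arm",
        bad[1], cv))
  }
  df <- data.frame(lapply(data[covariates], function(x)
    factor(as.character(x))))
  df$.arm <- a
  fit <- nnet::multinom(
    stats::as.formula(paste(".arm ~", paste(covariates, collapse = " + "))),
    data = df, trace = FALSE, maxit = 500)
  pr <- stats::predict(fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)   # binary case
  colnames(pr) <- levels(a)
  p_assigned <- pr[cbind(seq_len(nrow(pr)), as.integer(a))]
  w <- 1 / p_assigned
  if (stabilized) {
    marg <- as.numeric(table(a)[as.integer(a)]) / length(a)
    w <- w * marg
  }
  list(weights = w, propensity = pr, stabilized = stabilized)
}

#' Standardized mean difference
#'
#' `(mean_1 - mean_2) / sqrt((var_1 + var_2) / 2)` between two arms, with
#' weighted means and variances when weights are supplied. Categorical
#' covariates are expanded into binary level indicators and one SMD is
#' returned per level. Balance flag: `|SMD| < 0.25`.
#'
#' @param x numeric vector, or factor/character covariate.
#' @param arms two-level arm labels.
#' @param weights optional positive weights.
#' @return data frame with `level` (NA for numeric input), `smd`,
#'   `balanced`.
#' @export
standardized_mean_difference <- function(x, arms, weights = NULL) {
  arms <- factor(as.character(arms))
  if (nlevels(arms) != 2) stop("SMD is defined for exactly two arms")
  if (is.null(weights)) weights <- rep(1, length(arms))
  smd1 <- function(v) {
    g1 <- arms == levels(arms)[1]
    wm <- function(v, w) sum(w * v) / sum(w)
    wv <- function(v, w) {
      m <- wm(v, w)
      sum(w * (v - m)^2) / sum(w)
    }
    m1 <- wm(v[g1], weights[g1]); m2 <- wm(v[!g1], weights[!g1])
    v1 <- wv(v[g1], weights[g1]); v2 <- wv(v[!g1], weights[!g1])
    pooled <- sqrt((v1 + v2) / 2)
    if (pooled == 0) return(NA_real_)
    (m1 - m2) / pooled
  }
  if (is.numeric(x)) {
    s <- smd1(x)
    out <- data.frame(level = NA_character_, smd = s,
                      balanced = !is.na(s) & abs(s) < 0.25)
  } else {
    x <- factor(as.character(x))
    out <- do.call(rbind, lapply(levels(x), function(lv) {
      s <- smd1(as.numeric(x == lv))
      data.frame(level = lv, smd = s,
                 balanced = !is.na(s) & abs(s) < 0.25)
    }))
  }
  if (any(is.na(out$smd)))
    warning("zero pooled SD: SMD undefined for some level")
  out
}

#' Covariate balance table before and after weighting
#'
#' @param data data frame with covariates and arm.
#' @param covariates covariate column names.
#' @param arm arm column name.
#' @param weights IPTW weights (e.g. from [propensity_weights()]).
#' @return data frame of per-covariate-level SMDs, unweighted and
#'   weighted.
#' @export
balance_table <- function(data, covariates, arm, weights) {
  rows <- lapply(covariates, function(cv) {
    un <- standardized_mean_difference(data[[cv]], data[[arm]])
    wt <- standardized_mean_difference(data[[cv]], data[[arm]], weights)
    data.frame(covariate = cv, level = un$level,
               smd_unweighted = un$smd, smd_weighted = wt$smd,
               balanced = wt$balanced)
  })
  do.call(rbind, rows)
}

#' Simon two-stage design
#'
#' The trial's feasibility design: accrue `n1 = 6` patients; continue to
#' a total of `n_total = 27` only if at least `r1_go = 5` stage-1
#' successes; declare the regimen worthy if the total number of successes
#' exceeds `r_success - 1 = 23` (i.e. >= 24 of 27).
#'
#' @param n1 stage-1 sample size.
#' @param r1_go minimum stage-1 successes to continue.
#' @param n_total total sample size.
#' @param r_success minimum total successes for a positive trial.
#' @param alpha,beta nominal type-I and type-II error rates (metadata).
#' @return a `simon_design` list.
#' @export
simon_design <- function(n1 = 6, r1_go = 5, n_total = 27, r_success = 24,
                         alpha = 0.05, beta = 0.20) {
  stopifnot(n1 <= n_total, r1_go <= n1, r_success <= n_total)
  structure(list(n1 = n1, r1_go = r1_go, n_total = n_total,
                 r_success = r_success, alpha = alpha, beta = beta),
            class = "simon_design")
}

#' Operating characteristics of a Simon two-stage design
#'
#' Exact binomial probabilities: early stopping iff stage-1 successes
#' `< r1_go`; overall success iff the trial continues and total successes
#' reach `r_success`; expected sample size
#' `n1 + (n_total - n1) * P(continue)`.
#'
#' @param p true per-patient success probability in `[0, 1]`.
#' @param design a [simon_design()].
#' @return list with `p_stop_stage1`, `p_success`, `expected_n`.
#' @export
simon_oc <- function(p, design = simon_design()) {
  stopifnot(inherits(design, "simon_design"), p >= 0, p <= 1)
  n1 <- design$n1; n2 <- design$n_total - design$n1
  p_stop <- stats::pbinom(design$r1_go - 1, n1, p)
  s1 <- design$r1_go:n1
  p_succ <- sum(stats::dbinom(s1, n1, p) *
                  stats::pbinom(design$r_success - s1 - 1, n2, p,
                                lower.tail = FALSE))
  list(p_stop_stage1 = p_stop, p_success = p_succ,
       expected_n = n1 + n2 * (1 - p_stop))
}
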