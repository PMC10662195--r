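# Causal-effect estimators over a harmonized instrument set.
#
# All estimates are on the log-odds scale; `to_odds_ratio()` adds the
# exponentiated presentation columns. Conventions: normal reference for IVW
# and weighted-median p-values/CIs, t(J-2) for MR-Egger; random-effects IVW
# is multiplicative with the dispersion floored at 1.

Z975 <- stats::qnorm(0.975)  # 1.959964...

new_mr_estimate <- function(method, effects_model, b, se, pval, n_snp,
                            ci_ref = "normal", df = NA_real_) {
  if (ci_ref == "normal") {
    crit <- Z975
  } else {
    crit <- stats::qt(0.975, df = df)
  }
  est <- data.frame(
    method = method, effects_model = effects_model, n_snp = n_snp,
    b = b, se = se, ci_low = b - crit * se, ci_high = b + crit * se,
    pval = pval, ci_ref = ci_ref,
    stringsAsFactors = FALSE
  )
  to_odds_ratio(est)
}

#' Add odds-ratio presentation columns to an estimate table
#'
#' Exponentiates the log-odds estimate and its CI bounds into `or`,
#' `or_lci`, `or_uci`; the log-scale columns are unchanged.
#'
#' @param est data frame with columns `b`, `ci_low`, `ci_high` (one or more
#'   rows).
#' @return The same data frame with `or`, `or_lci`, `or_uci` columns.
#' @export
to_odds_ratio <- function(est) {
  est$or <- exp(est$b)
  est$or_lci <- exp(est$ci_low)
  est$or_uci <- exp(est$ci_high)
  est
}

#' Per-SNP Wald ratio estimate
#'
#' The single-instrument causal estimate: SNP-outcome effect divided by
#' SNP-exposure effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param inst one row of a `harmonized_set` (or any list with `beta_exp`,
#'   `beta_out`, `se_out`).
#' @return One-row estimate data frame (method `"wald"`).
#' @export
mr_wald_ratio <- function(inst) {
  if (inst$beta_exp == 0) {
    stop("degenerate instrument: zero exposure effect", call. = FALSE)
  }
  b <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("wald", "n/a", b, se, p, 1L)
}

ivw_weights <- function(set) set$beta_exp^2 / set$se_out^2

#' Inverse-variance weighted (IVW) causal estimate
#'
#' The inverse-variance weighted average of the per-SNP Wald ratios, with
#' weights `beta_exp^2 / se_out^2` — algebraically identical to weighted
#' least-squares regression of `beta_out` on `beta_exp` through the origin
#' with weights `1 / se_out^2`. Fixed-effect SE is `1 / sqrt(sum(w))`;
#' multiplicative random-effect SE scales it by
#' `max(1, sqrt(Q / (J - 1)))` with Q Cochran's heterogeneity statistic,
#' so the random-effects SE is never smaller than the fixed one.
#' `effects_model = "auto"` selects random effects when the Q test has
#' p < 0.05, the usual heterogeneity-triggered switch.
#'
#' @param set a `harmonized_set` with J >= 1 instruments (J >= 2 for
#'   random/auto to estimate dispersion).
#' @param effects_model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return One-row estimate data frame (method `"ivw"`).
#' @export
mr_ivw <- function(set, effects_model = c("auto", "fixed", "random")) {
  effects_model <- match.arg(effects_model)
  J <- nrow(set)
  if (J == 0) stop("empty instrument set", call. = FALSE)
  w <- ivw_weights(set)
  theta <- set$wald_ratio
  b <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (J == 1) {
    if (effects_model == "random") {
      warning("single instrument: falling back to fixed-effect IVW",
              call. = FALSE)
    }
    model <- "fixed"
    se <- se_fixed
  } else {
    Q <- sum(w * (theta - b)^2)
    q_p <- stats::pchisq(Q, df = J - 1, lower.tail = FALSE)
    model <- switch(effects_model,
                    auto = if (q_p < 0.05) "random" else "fixed",
                    fixed = "fixed",
                    random = "random")
    se <- if (model == "random") {
      se_fixed * max(1, sqrt(Q / (J - 1)))
    } else {
      se_fixed
    }
  }
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("ivw", model, b, se, p, J)
}

# Orient instruments so every exposure effect is non-negative (negate both
# betas where needed); MR-Egger's intercept is only interpretable in this
# orientation.
orient_positive <- function(set) {
  flip <- set$beta_exp < 0
  set$beta_exp[flip] <- -set$beta_exp[flip]
  set$beta_out[flip] <- -set$beta_out[flip]
  set
}

#' MR-Egger regression: causal slope and pleiotropy intercept
#'
#' Weighted linear regression of the (positively oriented) outcome effects
#' on the exposure effects with an unconstrained intercept and weights
#' `1 / se_out^2`. Under the InSIDE assumption the slope is the causal
#' effect and the intercept estimates the average directional pleiotropic
#' effect; a nonzero intercept is evidence of directional pleiotropy.
#' Standard errors use multiplicative overdispersion with the residual
#' scale floored at 1; p-values and CIs use a t reference with J - 2
#' degrees of freedom.
#'
#' @param set a `harmonized_set` with J >= 3 instruments.
#' @return List with `estimate` (one-row estimate data frame, method
#'   `"egger"`) and `pleiotropy` (data frame `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 3) {
    stop("MR-Egger requires at least 3 instruments (have ", J, ")",
         call. = FALSE)
  }
  o <- orient_positive(as.data.frame(set))
  x <- o$beta_exp
  y <- o$beta_out
  w <- 1 / o$se_out^2
  if (stats::var(x) == 0) {
    stop("collinear instruments: all exposure effects identical after ",
         "orientation", call. = FALSE)
  }
  # explicit weighted least squares with intercept
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (J - 2)
  scale2 <- max(1, sigma2)  # dispersion floored at 1
  se_slope <- sqrt(scale2 / sxx)
  se_int <- sqrt(scale2 * (1 / sw + xbar^2 / sxx))
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2)
  list(
    estimate = new_mr_estimate("egger", "n/a", slope, se_slope, p_slope, J,
                               ci_ref = sprintf("t(%d)", J - 2), df = J - 2),
    pleiotropy = data.frame(intercept = intercept, se = se_int, pval = p_int)
  )
}

# Interpolated 50% weighted quantile of the ordered Wald ratios: with
# normalized weights w and order statistics theta_(1) <= ... <= theta_(J),
# the weighted empirical quantile function is linear between the points
# S_j = cumsum(w)_j - w_j / 2; the estimate is its value at 0.5.
weighted_median_estimate <- function(theta, weights) {
  o <- order(theta)
  theta <- theta[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate with parametric-bootstrap SE
#'
#' The 50% weighted quantile of the ordered per-SNP Wald ratios, with
#' inverse-variance weights `1 / wald_se^2`. Consistent when at least half
#' of the total weight comes from valid instruments. The SE is the standard
#' deviation of the estimate over `n_boot` parametric-bootstrap replicates:
#' each replicate redraws `beta_exp ~ N(beta_exp, se_exp^2)` and
#' `beta_out ~ N(beta_out, se_out^2)` and recomputes ratios, weights and
#' the weighted median. The p-value uses a normal reference. Fully
#' deterministic given `(n_boot, seed)`.
#'
#' @param set a `harmonized_set` with J >= 3 instruments.
#' @param n_boot bootstrap replicates, >= 100 (default 1000).
#' @param seed integer RNG seed (required).
#' @return One-row estimate data frame (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed) {
  J <- nrow(set)
  if (J < 3) {
    stop("weighted median requires at least 3 instruments (have ", J, ")",
         call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("weighted median requires an explicit seed", call. = FALSE)
  }
  stopifnot(n_boot >= 100)
  b <- weighted_median_estimate(set$wald_ratio, 1 / set$wald_se^2)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, set$beta_exp, set$se_exp)
      by <- stats::rnorm(J, set$beta_out, set$se_out)
      weighted_median_estimate(by / bx, (abs(bx) / set$se_out)^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_estimate("weighted_median", "n/a", b, se, p, J)
}
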