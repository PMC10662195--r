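#' Cochran's Q heterogeneity test
#'
#' For `reference = "ivw"`: `Q = sum(w_j * (theta_j - theta_ivw)^2)` with
#' the IVW weights `beta_exp^2 / se_out^2`, the fixed-effect IVW pooled
#' estimate, and J - 1 degrees of freedom. For `reference = "egger"`: the
#' weighted residual sum of squares of the MR-Egger fit with J - 2 degrees
#' of freedom (often called Rucker's Q'). The p-value is the upper tail of
#' the chi-square distribution; p < 0.05 is the conventional heterogeneity
#' call that switches IVW to random effects.
#'
#' @param set a `harmonized_set` (J >= 2 for ivw, J >= 3 for egger).
#' @param reference `"ivw"` (default) or `"egger"`.
#' @return Data frame with columns `reference`, `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(set, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  J <- nrow(set)
  w <- ivw_weights(set)
  if (reference == "ivw") {
    if (J < 2) stop("Q (ivw) requires at least 2 instruments", call. = FALSE)
    b <- sum(w * set$wald_ratio) / sum(w)
    q <- sum(w * (set$wald_ratio - b)^2)
    df <- J - 1
  } else {
    if (J < 3) stop("Q (egger) requires at least 3 instruments", call. = FALSE)
    o <- orient_positive(as.data.frame(set))
    fit <- mr_egger(set)
    resid <- o$beta_out - fit$pleiotropy$intercept -
      fit$estimate$b * o$beta_exp
    q <- sum(resid^2 / o$se_out^2)
    df <- J - 2
  }
  data.frame(reference = reference, q_stat = q, df = df,
             pval = stats::pchisq(q, df = df, lower.tail = FALSE))
}

loo_row <- function(snp, est, error = NA_character_) {
  data.frame(snp = snp,
             b = est$b, se = est$se, ci_low = est$ci_low,
             ci_high = est$ci_high, pval = est$pval,
             effects_model = est$effects_model, n_snp = est$n_snp,
             error = error, stringsAsFactors = FALSE)
}

na_est_row <- function() {
  data.frame(b = NA_real_, se = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pval = NA_real_,
             effects_model = NA_character_, n_snp = NA_integer_)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, each omitting one instrument,
#' plus the all-instrument estimate (row `"All"`). Every row is a complete
#' from-scratch analysis of its subset — in particular the fixed/random
#' auto rule is re-evaluated within each subset, and for the weighted
#' median the bootstrap is re-run. An estimator failure on a subset flags
#' the row in its `error` column rather than dropping it.
#'
#' @param set a `harmonized_set` with J >= 3 instruments.
#' @param method `"ivw"` (default, the usual leave-one-out convention),
#'   `"egger"`, or `"weighted_median"`.
#' @param effects_model passed to [mr_ivw()] when `method = "ivw"`.
#' @param n_boot,seed passed to [mr_weighted_median()] when applicable.
#' @return Data frame with J + 1 rows: `snp` (the left-out id or `"All"`),
#'   `b`, `se`, `ci_low`, `ci_high`, `pval`, `effects_model`, `n_snp`,
#'   `error`.
#' @export
leave_one_out <- function(set, method = c("ivw", "egger", "weighted_median"),
                          effects_model = "auto", n_boot = 1000,
                          seed = NULL) {
  method <- match.arg(method)
  J <- nrow(set)
  if (J < 3) stop("leave-one-out requires at least 3 instruments",
                  call. = FALSE)
  fit_one <- function(subset) {
    switch(method,
           ivw = mr_ivw(subset, effects_model = effects_model),
           egger = mr_egger(subset)$estimate,
           weighted_median = mr_weighted_median(subset, n_boot = n_boot,
                                                seed = seed))
  }
  rows <- lapply(seq_len(J), function(j) {
    subset <- replace_instruments(set, as.data.frame(set)[-j, , drop = FALSE])
    tryCatch(loo_row(set$snp[j], fit_one(subset)),
             error = function(e) loo_row(set$snp[j], na_est_row(),
                                         error = conditionMessage(e)))
  })
  rows[[J + 1]] <- tryCatch(loo_row("All", fit_one(set)),
                            error = function(e)
                              loo_row("All", na_est_row(),
                                      error = conditionMessage(e)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-SNP (Wald ratio) influence table
#'
#' One Wald-ratio estimate per instrument with its 95% CI and a
#' significance flag (CI excludes zero on the log-odds scale) — the tabular
#' form of the single-SNP forest plot.
#'
#' @param set a `harmonized_set` with J >= 1 instruments.
#' @return Data frame with J rows: `snp`, `b`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `or`, `or_lci`, `or_uci`, `significant`.
#' @export
single_snp_table <- function(set) {
  if (nrow(set) < 1) stop("empty instrument set", call. = FALSE)
  rows <- lapply(seq_len(nrow(set)), function(j) {
    est <- mr_wald_ratio(set[j, ])
    data.frame(snp = set$snp[j], b = est$b, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               or = est$or, or_lci = est$or_lci, or_uci = est$or_uci,
               significant = est$ci_low > 0 | est$ci_high < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / (n_exposures * n_outcomes)`: the family-wise threshold for a
#' study testing every exposure-outcome pair. The pipeline labels p-values
#' below it "significant" and those in `[threshold, 0.05)` "nominal".
#'
#' @param alpha family-wise error rate in (0, 1); default 0.05.
#' @param n_exposures,n_outcomes positive integer counts.
#' @return Numeric threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures = 1,
                                 n_outcomes = 1) {
  stopifnot(alpha > 0, alpha < 1, n_exposures >= 1, n_outcomes >= 1)
  alpha / (n_exposures * n_outcomes)
}
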