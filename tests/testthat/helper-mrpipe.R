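# Shared helpers: direct construction of harmonized sets and tiny datasets
# so estimator tests do not depend on the harmonization path.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# Build a harmonized_set straight from effect vectors.
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      snp = sprintf("rs%d", seq_along(beta_exp))) {
  df <- data.frame(
    snp = snp,
    effect_allele = rep_len("A", length(beta_exp)),
    other_allele = rep_len("G", length(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    eaf_exp = rep_len(NA_real_, length(beta_exp)),
    beta_out = beta_out, se_out = se_out,
    pval_out = 2 * pnorm(-abs(beta_out / se_out)),
    f_stat = (beta_exp / se_exp)^2,
    wald_ratio = beta_out / beta_exp,
    wald_se = se_out / abs(beta_exp),
    stringsAsFactors = FALSE
  )
  mrpipe:::new_harmonized_set(
    df, data.frame(snp = character(0), reason = character(0)),
    provenance = list())
}

# Random strong-instrument set for property loops.
random_hset <- function(J, theta = 0.1) {
  beta_exp <- runif(J, 0.05, 0.4) * sample(c(-1, 1), J, replace = TRUE)
  se_exp <- runif(J, 0.005, 0.02)
  se_out <- runif(J, 0.003, 0.015)
  beta_out <- rnorm(J, theta * beta_exp, se_out)
  make_hset(beta_exp, se_exp, beta_out, se_out)
}

# Minimal summary dataset from a data frame of loose columns.
make_dataset <- function(..., trait = "t") {
  summary_dataset(data.frame(...), trait = trait)
}

# Independent oracle for the interpolated 50% weighted quantile: build the
# piecewise-linear weighted empirical quantile relation explicitly and
# invert it by root finding (a different computational route from the
# implementation's interpolation call).
brute_force_weighted_median <- function(theta, weights) {
  o <- order(theta)
  th <- theta[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(s)])
  if (any(duplicated(th))) {
    # vertical segment: quantile function jumps; fall back to direct
    # linear interpolation on the (s, theta) polyline
    return(approx(s, th, xout = 0.5, ties = "ordered")$y)
  }
  f <- approxfun(th, s)  # CDF-like relation theta -> s, strictly increasing
  uniroot(function(t) f(t) - 0.5, range(th), tol = 1e-12)$root
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mrpipe")
  stopifnot(nzchar(p))
  p
}
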