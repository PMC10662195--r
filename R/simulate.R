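# Seeded generator of two-sample GWAS summary statistics with known truth.
#
# Effects are simulated directly on the summary-statistic (log-odds) scale:
# the analysis consumes only summary statistics, so individual-level
# genotypes are never needed, and the generator reproduces exactly the
# noise model the estimators assume. Standard errors follow the
# standardized-trait approximation se = (2 n p (1 - p))^(-1/2), which
# couples SE to allele frequency and sample size the way real GWAS output
# does.

#' Simulation configuration
#'
#' Defaults emulate a study of ~19 independent instruments drawn from a
#' large case-control exposure GWAS (9153 cases / 368124 controls) tested
#' against a very large outcome GWAS (60620 cases / 970216 controls), with
#' a true causal log-odds effect of 0.1 (odds ratio ≈ 1.105 per exposure
#' log-odds unit), no pleiotropy, and a realistic share of allele-order
#' flips between the two datasets. For binary traits the precision of a
#' log-odds effect is governed by the effective sample size
#' `4 / (1 / n_cases + 1 / n_controls)`, so `n_exp` and `n_out` default to
#' the effective sizes of those two studies (35705 and 228280); passing
#' total sizes instead simply simulates a better-powered GWAS.
#'
#' @param n_snp number of instruments J.
#' @param theta true causal effect on the log-odds scale.
#' @param n_exp,n_out exposure / outcome effective GWAS sample sizes.
#' @param maf_range uniform range of minor-allele frequencies, within
#'   (0, 0.5].
#' @param gamma_range range of |true SNP-exposure effect| (log-odds per
#'   allele).
#' @param gamma_sign `"positive"` (default: effect alleles oriented to the
#'   exposure-increasing allele, as in published instrument lists) or
#'   `"random"`.
#' @param pleio_mean,pleio_sd mean and SD of per-SNP direct (pleiotropic)
#'   effects alpha_j ~ N(pleio_mean, pleio_sd^2); both 0 disables
#'   pleiotropy, pleio_mean != 0 is directional pleiotropy (InSIDE holds:
#'   alpha is drawn independently of gamma).
#' @param frac_palindromic fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs.
#' @param frac_flipped fraction of outcome rows written with swapped allele
#'   order (beta negated, eaf complemented), to exercise harmonization.
#' @param seed integer RNG seed (required; the generator has no default
#'   randomness source).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 19, theta = 0.1,
                       n_exp = 35705, n_out = 228280,
                       maf_range = c(0.1, 0.45),
                       gamma_range = c(0.1, 0.35),
                       gamma_sign = c("positive", "random"),
                       pleio_mean = 0, pleio_sd = 0,
                       frac_palindromic = 0, frac_flipped = 0.3,
                       seed) {
  gamma_sign <- match.arg(gamma_sign)
  if (missing(seed) || is.null(seed)) {
    stop("sim_config requires an explicit seed", call. = FALSE)
  }
  cfg <- list(n_snp = as.integer(n_snp), theta = theta,
              n_exp = n_exp, n_out = n_out,
              maf_range = maf_range, gamma_range = gamma_range,
              gamma_sign = gamma_sign,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              frac_palindromic = frac_palindromic,
              frac_flipped = frac_flipped, seed = as.integer(seed))
  stopifnot(cfg$n_snp >= 1, cfg$n_exp > 0, cfg$n_out > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            length(gamma_range) == 2, gamma_range[1] <= gamma_range[2],
            pleio_sd >= 0,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_flipped >= 0, frac_flipped <= 1)
  class(cfg) <- "sim_config"
  cfg
}

NON_PALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"),
                              c("C", "T"), c("G", "A"), c("G", "T"),
                              c("T", "C"), c("T", "G"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"),
                          c("G", "C"))

#' Simulate a two-sample GWAS summary-statistic pair with known truth
#'
#' Per SNP j: minor-allele frequency `p_j ~ U(maf_range)`; true exposure
#' effect `gamma_j` with `|gamma_j| ~ U(gamma_range)`; per-SNP direct
#' effect `alpha_j ~ N(pleio_mean, pleio_sd^2)`; standard errors
#' `se_X = (2 n_exp p (1-p))^(-1/2)` (outcome analogous); observed effects
#' `beta_X ~ N(gamma_j, se_X^2)` and
#' `beta_Y ~ N(theta * gamma_j + alpha_j, se_Y^2)`; two-sided normal
#' p-values. A configured fraction of SNPs receives palindromic allele
#' pairs, and a configured fraction of outcome rows is written with the
#' allele order swapped (effect negated, frequency complemented) so that
#' harmonization must recover the original orientation. All draws come
#' from the seeded generator: the same config yields bit-identical data.
#'
#' @param config a [sim_config()].
#' @return List with `exposure` and `outcome` (`summary_dataset`s) and
#'   `truth` (list: `theta`, `gamma`, `alpha`, `maf`, `palindromic_ids`,
#'   `flipped_ids`, `config`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    J <- config$n_snp
    snp <- sprintf("rs%07d", sample.int(9999999, J))
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    sign <- if (config$gamma_sign == "positive") {
      rep(1, J)
    } else {
      sample(c(-1, 1), J, replace = TRUE)
    }
    gamma <- sign * stats::runif(J, config$gamma_range[1],
                                 config$gamma_range[2])
    alpha <- if (config$pleio_sd == 0 && config$pleio_mean == 0) {
      rep(0, J)
    } else {
      stats::rnorm(J, config$pleio_mean, config$pleio_sd)
    }
    se_x <- 1 / sqrt(2 * config$n_exp * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * config$n_out * maf * (1 - maf))
    beta_x <- stats::rnorm(J, gamma, se_x)
    beta_y <- stats::rnorm(J, config$theta * gamma + alpha, se_y)
    # two-sided normal p, floored at the smallest normalized double: at
    # these sample sizes |z| can exceed 40 and the p-value underflows to 0,
    # which a validated record may not carry
    pfun <- function(beta, se) {
      pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    }

    n_pal <- round(config$frac_palindromic * J)
    pal_idx <- if (n_pal > 0) sample.int(J, n_pal) else integer(0)
    pairs <- vector("list", J)
    for (j in seq_len(J)) {
      pool <- if (j %in% pal_idx) PALINDROMIC_PAIRS else NON_PALINDROMIC_PAIRS
      pairs[[j]] <- pool[[sample.int(length(pool), 1)]]
    }
    ea <- vapply(pairs, `[`, character(1), 1)
    oa <- vapply(pairs, `[`, character(1), 2)

    n_flip <- round(config$frac_flipped * J)
    flip_idx <- if (n_flip > 0) sample.int(J, n_flip) else integer(0)
    flipped <- seq_len(J) %in% flip_idx

    exposure <- summary_dataset(data.frame(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_x, se = se_x, pval = pfun(beta_x, se_x),
      n = config$n_exp), trait = "exposure",
      metadata = list(simulated = TRUE, n = config$n_exp))
    outcome <- summary_dataset(data.frame(
      snp = snp,
      effect_allele = ifelse(flipped, oa, ea),
      other_allele = ifelse(flipped, ea, oa),
      eaf = ifelse(flipped, 1 - maf, maf),
      beta = ifelse(flipped, -beta_y, beta_y),
      se = se_y, pval = pfun(ifelse(flipped, -beta_y, beta_y), se_y),
      n = config$n_out), trait = "outcome",
      metadata = list(simulated = TRUE, n = config$n_out))
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                      maf = maf, snp = snp,
                      palindromic_ids = snp[pal_idx],
                      flipped_ids = snp[flip_idx],
                      config = config))
  })
}

#' Simulate a block-diagonal pairwise r-squared matrix
#'
#' SNPs are assigned round-robin to `n_blocks` LD blocks; within a block
#' every off-diagonal entry is `within_r2`, between blocks 0, diagonal 1.
#' Intended for exercising [ld_prune()].
#'
#' @param snp_ids character vector of SNP ids (row/column names).
#' @param n_blocks number of blocks, `<= length(snp_ids)`.
#' @param within_r2 within-block r-squared in `[0, 1)`.
#' @return Symmetric numeric matrix with `snp_ids` dimnames.
#' @export
simulate_ld_matrix <- function(snp_ids, n_blocks, within_r2) {
  J <- length(snp_ids)
  stopifnot(n_blocks >= 1, n_blocks <= J, within_r2 >= 0, within_r2 < 1)
  block <- rep_len(seq_len(n_blocks), J)
  m <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(m) <- 1
  dimnames(m) <- list(snp_ids, snp_ids)
  m
}
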