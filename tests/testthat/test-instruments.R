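test_that("significance filter is strict at the boundary and order-preserving", {
  ds <- make_dataset(snp = c("rs1", "rs2", "rs3"),
                     effect_allele = "A", other_allele = "G",
                     beta = 0.1, se = 0.01,
                     pval = c(1e-9, 5e-8, 1e-7))
  kept <- filter_significant(ds, 5e-8)
  expect_equal(kept$snp, "rs1")
  expect_equal(filter_significant(ds, 1)$snp, ds$snp)
})

test_that("significance filter matches an independent per-record check", {
  sim <- simulate_two_sample(sim_config(n_snp = 100, seed = 11,
                                        gamma_range = c(0, 0.2)))
  kept <- quietly(filter_significant(sim$exposure, 5e-8))
  manual <- sim$exposure$snp[vapply(seq_len(nrow(sim$exposure)),
                                    function(i) sim$exposure$pval[i] < 5e-8,
                                    logical(1))]
  expect_identical(kept$snp, manual)
  expect_true(length(manual) > 0 && length(manual) < 100)
})

test_that("ld_prune keeps all SNPs under an identity matrix and the min-p SNP of a correlated pair", {
  ds <- make_dataset(snp = c("rsA", "rsB"), effect_allele = "A",
                     other_allele = "G", beta = 0.1, se = 0.01,
                     pval = c(1e-10, 1e-9))
  ident <- diag(2)
  dimnames(ident) <- list(ds$snp, ds$snp)
  expect_equal(ld_prune(ds, ident)$snp, ds$snp)

  corr <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(ds$snp, ds$snp))
  expect_equal(ld_prune(ds, corr, 0.001)$snp, "rsA")
  expect_error(ld_prune(ds, corr[1, 1, drop = FALSE]), "rsB")
})

test_that("block-structured LD yields one survivor per block, the block's min-p", {
  set.seed(21)
  J <- 20
  ds <- make_dataset(snp = sprintf("rs%02d", 1:J), effect_allele = "A",
                     other_allele = "G", beta = 0.1, se = 0.01,
                     pval = runif(J, 1e-12, 1e-8))
  r2 <- simulate_ld_matrix(ds$snp, n_blocks = 4, within_r2 = 0.8)
  pruned <- ld_prune(ds, r2, 0.001)
  expect_equal(nrow(pruned), 4)
  # exhaustive pairwise independence check
  for (a in pruned$snp) for (b in pruned$snp) {
    if (a != b) expect_lt(r2[a, b], 0.001)
  }
  # each survivor is the min-p member of its block
  block_of <- function(s) which(r2[s, ] >= 0.8 | colnames(r2) == s)
  for (s in pruned$snp) {
    members <- colnames(r2)[block_of(s)]
    expect_equal(ds$pval[ds$snp == s],
                 min(ds$pval[ds$snp %in% members]))
  }
  # invariant to input row order
  shuffled <- ds[sample(nrow(ds)), ]
  attr(shuffled, "trait") <- attr(ds, "trait")
  class(shuffled) <- class(ds)
  expect_setequal(ld_prune(shuffled, r2, 0.001)$snp, pruned$snp)
})

test_that("palindrome detection covers the four strand-ambiguous pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "single bases")
})

test_that("harmonize aligns matched, swapped and strand-complemented alleles", {
  exposure <- make_dataset(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("G", "A", "C", "A", "A"),
    other_allele = c("A", "G", "T", "T", "G"),
    eaf = 0.3, beta = c(0.2, 0.3, 0.25, 0.4, 0.2), se = 0.01,
    pval = 1e-12)
  outcome <- make_dataset(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("G", "G", "G", "A", "C"),
    other_allele = c("A", "A", "A", "T", "G"),
    eaf = c(0.3, 0.7, 0.68, 0.3, 0.5),
    beta = c(0.05, 0.12, -0.06, 0.08, 0.02), se = 0.004, pval = 1e-4)
  h <- quietly(harmonize(exposure, outcome))
  # rs1 identical alleles: unchanged
  expect_equal(h$beta_out[h$snp == "rs1"], 0.05)
  # rs2 swapped: negated
  expect_equal(h$beta_out[h$snp == "rs2"], -0.12)
  # rs3 strand complement of swap (C/T vs G/A): complement G/A -> C/T, direct
  expect_equal(h$beta_out[h$snp == "rs3"], -0.06)
  # rs4 palindromic: excluded by default
  ex <- exclusions(h)
  expect_equal(ex$reason[ex$snp == "rs4"], "palindromic")
  # rs5 incompatible allele sets
  expect_equal(ex$reason[ex$snp == "rs5"], "incompatible alleles")
  # conservation over the snp-id intersection
  expect_equal(nrow(h) + nrow(ex), 5)
  # per-SNP derived quantities
  expect_equal(h$f_stat, (h$beta_exp / h$se_exp)^2, tolerance = 1e-10)
  expect_equal(h$wald_ratio, h$beta_out / h$beta_exp)
  expect_error(quietly(harmonize(exposure,
                                 make_dataset(snp = "zzz",
                                              effect_allele = "A",
                                              other_allele = "G",
                                              beta = 1, se = 1,
                                              pval = 0.5))),
               "no snp ids")
})

test_that("self-harmonization gives unit Wald ratios; double swap is identity", {
  sim <- simulate_two_sample(sim_config(n_snp = 15, seed = 9,
                                        frac_flipped = 0))
  h <- quietly(harmonize(sim$exposure, sim$exposure))
  expect_equal(h$wald_ratio, rep(1, nrow(h)))
  expect_equal(h$beta_out, h$beta_exp)

  swap <- function(ds) {
    df <- as.data.frame(ds)
    df[, c("effect_allele", "other_allele")] <-
      df[, c("other_allele", "effect_allele")]
    df$beta <- -df$beta
    df$eaf <- 1 - df$eaf
    summary_dataset(df, trait = attr(ds, "trait"))
  }
  h1 <- quietly(harmonize(sim$exposure, sim$outcome))
  h2 <- quietly(harmonize(sim$exposure, swap(swap(sim$outcome))))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
  # single swap is absorbed by harmonization
  h3 <- quietly(harmonize(sim$exposure, swap(sim$outcome)))
  expect_equal(h1$beta_out, h3$beta_out)
})

test_that("palindrome rescue keeps only frequency-resolvable palindromes when enabled", {
  exposure <- make_dataset(snp = c("rs1", "rs2"),
                           effect_allele = c("A", "C"),
                           other_allele = c("T", "G"),
                           eaf = c(0.10, 0.48), beta = 0.2, se = 0.01,
                           pval = 1e-12)
  outcome <- make_dataset(snp = c("rs1", "rs2"),
                          effect_allele = c("A", "C"),
                          other_allele = c("T", "G"),
                          eaf = c(0.12, 0.47), beta = 0.05, se = 0.004,
                          pval = 1e-4)
  h_off <- quietly(harmonize(exposure, outcome))
  expect_equal(nrow(h_off), 0)
  h_on <- quietly(harmonize(exposure, outcome, palindrome_rescue = TRUE))
  expect_equal(h_on$snp, "rs1")  # rs2 frequency too close to 0.5
  expect_equal(exclusions(h_on)$snp, "rs2")
})

test_that("F-statistic screen is inclusive at the bound and logs weak instruments", {
  h <- make_hset(beta_exp = c(0.1, 0.03), se_exp = c(0.02, 0.01),
                 beta_out = c(0.01, 0.01), se_out = 0.005)
  expect_equal(h$f_stat[1], 25)   # (0.1 / 0.02)^2
  expect_equal(h$f_stat[2], 9)    # (0.03 / 0.01)^2, below the screen
  kept <- filter_strength(h, 10)
  expect_equal(kept$snp, "rs1")
  ex <- exclusions(kept)
  expect_equal(ex$reason[ex$snp == "rs2"], "weak instrument")
  expect_equal(mean_f_stat(kept), 25, tolerance = 1e-12)

  # inclusive boundary, on exactly representable values: F = 4 survives a
  # screen at 4, F = 1 does not
  h2 <- make_hset(beta_exp = c(0.5, 0.5), se_exp = c(0.25, 0.5),
                  beta_out = 0.01, se_out = 0.005)
  expect_identical(h2$f_stat, c(4, 1))
  expect_equal(filter_strength(h2, 4)$snp, "rs1")
})
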