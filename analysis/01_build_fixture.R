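#!/usr/bin/env Rscript
# Builds the bundled synthetic two-sample GWAS fixture under inst/extdata/.
#
# The fixture stands in for a published instrument list: 19 valid
# independent instruments plus five deliberately problematic candidates
# that the selection pipeline must remove —
#   rs9000001 / rs9000002  palindromic (A/T, C/G), genome-wide significant
#   rs9000003 / rs9000004  below genome-wide significance
#   rs9000005              significant but absent from the outcome GWAS
# Everything is generated from the package's seeded simulator (seed 193)
# and hand-specified constants; the files are deterministic and this
# script only needs rerunning if the generator changes.

library(mrpipe)

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_two_sample(sim_config(n_snp = 19, seed = 193))

expo <- as.data.frame(sim$exposure)
outc <- as.data.frame(sim$outcome)

extra_exp <- data.frame(
  snp = sprintf("rs%07d", 9000001:9000005),
  effect_allele = c("A", "C", "A", "G", "C"),
  other_allele = c("T", "G", "C", "A", "T"),
  eaf = c(0.30, 0.22, 0.15, 0.40, 0.35),
  beta = c(0.21, -0.18, 0.052, -0.047, 0.19),
  se = c(0.012, 0.013, 0.012, 0.011, 0.012),
  n = 35705
)
extra_exp$pval <- 2 * pnorm(-abs(extra_exp$beta / extra_exp$se))

# the palindromes and sub-threshold SNPs also appear in the outcome GWAS;
# rs9000005 deliberately does not
extra_out <- data.frame(
  snp = sprintf("rs%07d", 9000001:9000004),
  effect_allele = c("A", "C", "A", "G"),
  other_allele = c("T", "G", "C", "A"),
  eaf = c(0.31, 0.21, 0.15, 0.41),
  beta = c(0.02, -0.017, 0.006, -0.004),
  se = c(0.0048, 0.0051, 0.0047, 0.0046),
  n = 228280
)
extra_out$pval <- 2 * pnorm(-abs(extra_out$beta / extra_out$se))

exposure <- summary_dataset(rbind(expo, extra_exp), trait = "synthetic CAVS",
                            metadata = list(synthetic = TRUE))
outcome <- summary_dataset(rbind(outc, extra_out), trait = "synthetic AF",
                           metadata = list(synthetic = TRUE))

write_summary_stats(exposure, file.path(out_dir, "synthetic_exposure.tsv"))
write_summary_stats(outcome, file.path(out_dir, "synthetic_outcome.tsv"))

truth <- data.frame(snp = sim$truth$snp, gamma = sim$truth$gamma,
                    alpha = sim$truth$alpha, maf = sim$truth$maf,
                    flipped = sim$truth$snp %in% sim$truth$flipped_ids)
write_table(truth, file.path(out_dir, "synthetic_truth.tsv"))

cat("wrote", nrow(exposure), "exposure and", nrow(outcome),
    "outcome records; true theta =", sim$truth$theta, "\n")
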