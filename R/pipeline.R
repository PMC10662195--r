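#' Analysis configuration
#'
#' Bundles every setting of the end-to-end analysis. `exposure` and
#' `outcome` may be file paths (read with `column_map`) or
#' `summary_dataset` objects; `r2_matrix` may be a path to a square
#' delimited matrix with SNP-id header row/column, a matrix, or NULL
#' (input treated as already clumped).
#'
#' @param exposure,outcome paths or `summary_dataset`s.
#' @param r2_matrix path, matrix, or NULL.
#' @param column_map column mapping for file inputs; see
#'   [default_column_map()].
#' @param delimiter input file delimiter.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold LD clumping threshold (default 0.001).
#' @param f_min minimum per-SNP F statistic (default 10).
#' @param drop_palindromic exclude palindromic SNPs (default TRUE).
#' @param methods estimators to run; default all of `"ivw"`, `"egger"`,
#'   `"weighted_median"`.
#' @param effects_model IVW effects model: `"auto"` (default), `"fixed"`,
#'   `"random"`.
#' @param n_boot weighted-median bootstrap replicates (default 1000).
#' @param seed integer seed; required whenever the weighted median is
#'   enabled.
#' @param bonferroni integer pair (number of exposures, number of
#'   outcomes) for the corrected significance threshold; default c(1, 1).
#' @param output_dir directory for report TSVs, or NULL to skip writing.
#' @return An `mr_config` list.
#' @export
mr_config <- function(exposure, outcome, r2_matrix = NULL,
                      column_map = default_column_map(), delimiter = "\t",
                      p_threshold = 5e-8, r2_threshold = 0.001, f_min = 10,
                      drop_palindromic = TRUE,
                      methods = c("ivw", "egger", "weighted_median"),
                      effects_model = "auto", n_boot = 1000, seed = NULL,
                      bonferroni = c(1, 1), output_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("weighted_median" %in% methods && is.null(seed)) {
    stop("a seed is required when the weighted median is enabled",
         call. = FALSE)
  }
  structure(list(exposure = exposure, outcome = outcome,
                 r2_matrix = r2_matrix, column_map = column_map,
                 delimiter = delimiter, p_threshold = p_threshold,
                 r2_threshold = r2_threshold, f_min = f_min,
                 drop_palindromic = drop_palindromic, methods = methods,
                 effects_model = effects_model, n_boot = n_boot,
                 seed = seed, bonferroni = bonferroni,
                 output_dir = output_dir),
            class = "mr_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [mr_config()]; relative paths are resolved
#' against the YAML file's directory. Keys supplied in `...` override the
#' file.
#'
#' @param path YAML file path.
#' @param ... overrides passed to [mr_config()].
#' @return An `mr_config`.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  for (key in c("exposure", "outcome", "r2_matrix")) {
    if (!is.null(raw[[key]]) && is.character(raw[[key]]) &&
        !file.exists(raw[[key]])) {
      raw[[key]] <- file.path(base_dir, raw[[key]])
    }
  }
  if (!is.null(raw$bonferroni)) raw$bonferroni <- unlist(raw$bonferroni)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(mr_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

read_r2_matrix <- function(x, delimiter = "\t") {
  if (is.null(x) || is.matrix(x)) return(x)
  df <- utils::read.table(x, header = TRUE, sep = delimiter,
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

resolve_dataset <- function(x, config, trait) {
  if (inherits(x, "summary_dataset")) return(x)
  read_summary_stats(x, column_map = config$column_map,
                     delimiter = config$delimiter, trait = trait)
}

#' Run the full two-sample MR analysis
#'
#' Executes, in order: read/validate both datasets; significance filter on
#' the exposure; LD clumping (when an r-squared matrix is supplied); allele
#' harmonization; instrument-strength filter; the configured estimators
#' (IVW with the heterogeneity-triggered fixed/random rule, MR-Egger,
#' weighted median); Cochran's Q for the IVW and Egger fits; leave-one-out
#' and single-SNP influence tables; Bonferroni significance labelling.
#' Every stage logs kept/dropped counts, and the exclusions log accounts
#' for every candidate SNP that is not among the final instruments.
#' Identical config, inputs and seed give an identical report.
#'
#' @param config an [mr_config()].
#' @return An `mr_report` list: `estimates`, `heterogeneity`, `pleiotropy`,
#'   `single_snp`, `loo`, `instruments`, `exclusions`, `n_candidates`,
#'   `bonferroni_threshold`, `config`, `version`. Written to
#'   `config$output_dir` via [write_report()] when set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  exposure <- with_stage("read_exposure",
                         resolve_dataset(config$exposure, config, "exposure"))
  outcome <- with_stage("read_outcome",
                        resolve_dataset(config$outcome, config, "outcome"))

  log <- list()
  note <- function(stage, snps, reason) {
    if (length(snps)) {
      log[[length(log) + 1]] <<- data.frame(stage = stage, snp = snps,
                                            reason = reason)
    }
  }

  sig <- with_stage("filter_significant",
                    filter_significant(exposure, config$p_threshold))
  note("filter_significant", setdiff(exposure$snp, sig$snp),
       sprintf("p >= %g", config$p_threshold))
  message(sprintf("filter_significant: kept %d of %d", nrow(sig),
                  nrow(exposure)))

  r2 <- with_stage("ld_prune", read_r2_matrix(config$r2_matrix,
                                              config$delimiter))
  clumped <- with_stage("ld_prune", ld_prune(sig, r2, config$r2_threshold))
  note("ld_prune", setdiff(sig$snp, clumped$snp),
       sprintf("r2 >= %g with a better instrument", config$r2_threshold))
  message(sprintf("ld_prune: kept %d of %d", nrow(clumped), nrow(sig)))

  note("join", setdiff(clumped$snp, outcome$snp), "absent from outcome")
  hset <- with_stage("harmonize",
                     harmonize(clumped, outcome,
                               drop_palindromic = config$drop_palindromic))
  hx <- exclusions(hset)
  note("harmonize", hx$snp, hx$reason)

  hset <- with_stage("filter_strength", filter_strength(hset, config$f_min))
  strength_x <- exclusions(hset)
  strength_x <- strength_x[strength_x$reason == "weak instrument", ,
                           drop = FALSE]
  note("filter_strength", strength_x$snp, strength_x$reason)
  message(sprintf("instruments after all filters: %d", nrow(hset)))
  if (nrow(hset) == 0) stop("[stage filter_strength] no instruments remain",
                            call. = FALSE)

  thr <- bonferroni_threshold(0.05, config$bonferroni[1],
                              config$bonferroni[2])
  ests <- list()
  het <- list()
  pleio <- NULL
  if ("ivw" %in% config$methods) {
    ests$ivw <- with_stage("ivw", mr_ivw(hset, config$effects_model))
    if (nrow(hset) >= 2) het$ivw <- with_stage("cochran_q",
                                               cochran_q(hset, "ivw"))
  }
  if ("egger" %in% config$methods && nrow(hset) >= 3) {
    eg <- with_stage("egger", mr_egger(hset))
    ests$egger <- eg$estimate
    pleio <- eg$pleiotropy
    het$egger <- with_stage("cochran_q", cochran_q(hset, "egger"))
  }
  if ("weighted_median" %in% config$methods && nrow(hset) >= 3) {
    ests$weighted_median <- with_stage(
      "weighted_median",
      mr_weighted_median(hset, n_boot = config$n_boot, seed = config$seed))
  }
  estimates <- do.call(rbind, unname(ests))
  estimates$significance <- ifelse(estimates$pval < thr, "significant",
                                   ifelse(estimates$pval < 0.05, "nominal",
                                          "ns"))

  loo <- if (nrow(hset) >= 3 && "ivw" %in% config$methods) {
    with_stage("leave_one_out",
               leave_one_out(hset, "ivw",
                             effects_model = config$effects_model))
  } else {
    NULL
  }
  singles <- with_stage("single_snp", single_snp_table(hset))

  report <- structure(list(
    estimates = estimates,
    heterogeneity = do.call(rbind, unname(het)),
    pleiotropy = pleio,
    single_snp = singles,
    loo = loo,
    instruments = as.data.frame(hset),
    exclusions = if (length(log)) do.call(rbind, log) else
      data.frame(stage = character(0), snp = character(0),
                 reason = character(0)),
    n_candidates = nrow(exposure),
    mean_f = mean_f_stat(hset),
    bonferroni_threshold = thr,
    config = config,
    version = as.character(utils::packageVersion("mrpipe"))
  ), class = "mr_report")

  if (!is.null(config$output_dir)) {
    with_stage("write_report", write_report(report, config$output_dir))
  }
  report
}

#' Write an analysis report to a directory of TSVs
#'
#' Emits `estimates.tsv`, `heterogeneity.tsv`, `pleiotropy.tsv`,
#' `single_snp.tsv`, `loo.tsv`, `instruments.tsv`, `exclusions.tsv`, a
#' config echo (`config.yaml`) and a human-readable `summary.txt` whose
#' odds ratios are rounded to 3 decimals (the TSVs keep full precision).
#' Output is deterministic: a rerun with the same report is byte-identical.
#' On any write error, partial outputs are removed.
#'
#' @param report an `mr_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(rows, name, allow_empty = FALSE) {
    if (is.null(rows)) return()
    p <- file.path(dir, name)
    write_table(rows, p, allow_empty = allow_empty)
    written <<- c(written, p)
  }
  tryCatch({
    emit(report$estimates, "estimates.tsv")
    emit(report$heterogeneity, "heterogeneity.tsv")
    emit(report$pleiotropy, "pleiotropy.tsv")
    emit(report$single_snp, "single_snp.tsv")
    emit(report$loo, "loo.tsv")
    emit(report$instruments, "instruments.tsv")
    emit(report$exclusions, "exclusions.tsv", allow_empty = TRUE)

    cfg_path <- file.path(dir, "config.yaml")
    cfg <- report$config
    cfg$output_dir <- NULL  # implied by file location; keeps echo portable
    for (key in c("exposure", "outcome")) {
      if (!is.character(cfg[[key]])) cfg[[key]] <- "<in-memory dataset>"
    }
    if (!is.null(cfg$r2_matrix) && !is.character(cfg$r2_matrix)) {
      cfg$r2_matrix <- "<in-memory matrix>"
    }
    yaml::write_yaml(unclass(cfg), cfg_path)
    written <- c(written, cfg_path)

    sum_path <- file.path(dir, "summary.txt")
    con <- file(sum_path, open = "w", encoding = "UTF-8")
    writeLines(format_report(report, config_hash =
                               unname(tools::md5sum(cfg_path))), con)
    close(con)
    written <- c(written, sum_path)
  }, error = function(e) {
    unlink(written)
    stop(conditionMessage(e), call. = FALSE)
  })
  invisible(dir)
}

format_report <- function(report, config_hash = NA_character_) {
  e <- report$estimates
  lines <- c(
    sprintf("mrpipe %s analysis report", report$version),
    sprintf("config md5: %s", config_hash),
    sprintf("instruments: %d (mean F = %.1f); candidates read: %d",
            nrow(report$instruments), report$mean_f, report$n_candidates),
    sprintf("Bonferroni-corrected threshold: %g",
            report$bonferroni_threshold),
    "",
    "method            model   OR (95% CI)            p            call")
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf(
      "%-17s %-7s %.3f (%.3f-%.3f)    %-12.3g %s",
      e$method[i], e$effects_model[i], e$or[i], e$or_lci[i], e$or_uci[i],
      e$pval[i], e$significance[i]))
  }
  if (!is.null(report$heterogeneity)) {
    h <- report$heterogeneity
    lines <- c(lines, "", "heterogeneity:")
    for (i in seq_len(nrow(h))) {
      lines <- c(lines, sprintf("  Q (%s) = %.3f, df = %d, p = %.3f",
                                h$reference[i], h$q_stat[i], h$df[i],
                                h$pval[i]))
    }
  }
  if (!is.null(report$pleiotropy)) {
    lines <- c(lines, sprintf(
      "Egger intercept = %.3f (SE %.3f), p = %.3f",
      report$pleiotropy$intercept, report$pleiotropy$se,
      report$pleiotropy$pval))
  }
  lines
}

#' Print method for analysis reports
#'
#' @param x an `mr_report`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
print.mr_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Compare two analysis reports method-by-method
#'
#' Lists per-method differences in estimate, SE and p-value, flags sign
#' disagreements of the point estimates, and reports whether every delta
#' falls within `tolerance` (relative, against the magnitude of the first
#' report's value, absolute below magnitude 1). Used to check replication
#' across exposure datasets.
#'
#' @param a,b `mr_report` objects sharing a method set.
#' @param tolerance relative tolerance (default 1e-8, i.e. effectively
#'   exact).
#' @return Data frame `method`, `field`, `value_a`, `value_b`, `delta`,
#'   `within`, `sign_disagreement`; attribute `all_within`.
#' @export
compare_reports <- function(a, b, tolerance = 1e-8) {
  ma <- a$estimates$method
  mb <- b$estimates$method
  if (!setequal(ma, mb)) {
    stop("reports have different method sets: {",
         paste(ma, collapse = ","), "} vs {",
         paste(mb, collapse = ","), "}", call. = FALSE)
  }
  rows <- list()
  for (m in ma) {
    ra <- a$estimates[a$estimates$method == m, ]
    rb <- b$estimates[b$estimates$method == m, ]
    sign_dis <- sign(ra$b) != sign(rb$b)
    for (field in c("b", "se", "pval")) {
      va <- ra[[field]]
      vb <- rb[[field]]
      delta <- vb - va
      within <- abs(delta) <= tolerance * max(1, abs(va))
      rows[[length(rows) + 1]] <- data.frame(
        method = m, field = field, value_a = va, value_b = vb,
        delta = delta, within = within, sign_disagreement = sign_dis)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, all_within = all(out$within))
}
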