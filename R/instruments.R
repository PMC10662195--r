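#' Filter to genome-wide significant records
#'
#' Keeps records with association p-value strictly below `p_threshold`
#' (conventionally 5e-8), preserving input order.
#'
#' @param dataset a `summary_dataset`.
#' @param p_threshold significance threshold in (0, 1); default `5e-8`.
#' @return A `summary_dataset` with the surviving records.
#' @export
filter_significant <- function(dataset, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold < 1 ||
              p_threshold == 1)
  keep <- dataset$pval < p_threshold
  if (!any(keep)) {
    warning("no records pass p < ", format(p_threshold), call. = FALSE)
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait", "metadata", "read_report")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- class(dataset)
  out
}

#' Greedy LD clumping against a pairwise r-squared matrix
#'
#' Repeatedly keeps the remaining record with the smallest p-value (ties
#' broken lexicographically on snp id) and drops every remaining record
#' whose r-squared with it is at or above `r2_threshold`. The survivors are
#' pairwise "independent" at the threshold. With `r2_matrix = NULL` the
#' input is treated as already clumped and returned unchanged.
#'
#' @param dataset a `summary_dataset`.
#' @param r2_matrix symmetric numeric matrix of pairwise r-squared values
#'   with snp ids as dimnames, diagonal 1; or NULL.
#' @param r2_threshold independence threshold in `[0, 1]`; default 0.001.
#' @return A `summary_dataset` of the clumped survivors, in input order.
#' @export
ld_prune <- function(dataset, r2_matrix = NULL, r2_threshold = 0.001) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  if (is.null(r2_matrix)) return(dataset)
  ids <- dataset$snp
  missing_ids <- setdiff(ids, rownames(r2_matrix))
  if (length(missing_ids)) {
    stop("snp id(s) absent from r2 matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  remaining <- ids[order(dataset$pval, ids)]
  keep <- character(0)
  while (length(remaining)) {
    lead <- remaining[1]
    keep <- c(keep, lead)
    r2 <- r2_matrix[lead, remaining]
    remaining <- remaining[r2 < r2_threshold & remaining != lead]
  }
  out <- dataset[dataset$snp %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait", "metadata", "read_report")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- class(dataset)
  out
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are reverse complements of each
#' other ({A,T} or {C,G}), so the strand cannot be resolved from the alleles
#' alone.
#'
#' @param effect_allele,other_allele single bases (A/C/G/T), vectorized.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (!all(ea %in% VALID_BASES) || !all(oa %in% VALID_BASES)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

new_harmonized_set <- function(instruments, exclusions, provenance) {
  rownames(instruments) <- NULL
  rownames(exclusions) <- NULL
  structure(instruments,
            exclusions = exclusions,
            provenance = provenance,
            class = c("harmonized_set", "data.frame"))
}

replace_instruments <- function(set, instruments, exclusions = NULL) {
  excl <- attr(set, "exclusions")
  if (!is.null(exclusions) && nrow(exclusions)) excl <- rbind(excl, exclusions)
  new_harmonized_set(instruments, excl, attr(set, "provenance"))
}

#' Exclusion log of a harmonized set
#'
#' @param set a `harmonized_set`.
#' @return Data frame with columns `snp`, `reason`.
#' @export
exclusions <- function(set) attr(set, "exclusions")

#' Harmonize exposure and outcome effects to a shared effect allele
#'
#' Inner-joins the two datasets on snp id and aligns every outcome effect to
#' the exposure's effect allele:
#' \itemize{
#'   \item identical allele pair: effects copied unchanged;
#'   \item swapped alleles (outcome effect allele = exposure other allele):
#'     outcome beta negated, outcome eaf complemented;
#'   \item strand-complement match or complement-plus-swap, for
#'     non-palindromic SNPs only: treated as above (complementing both
#'     alleles of a non-palindromic SNP is unambiguous);
#'   \item anything else: excluded as incompatible.
#' }
#' Palindromic SNPs are excluded by default because their strand cannot be
#' verified. An opt-in frequency-based rescue keeps a palindromic SNP when
#' both datasets report an effect-allele frequency on the same side of 0.5
#' and away from it (both below `eaf_cutoff` or both above
#' `1 - eaf_cutoff`), inferring same-strand alignment.
#'
#' Each surviving SNP carries its Wald ratio `beta_out / beta_exp`, the
#' first-order (delta-method) SE `se_out / |beta_exp|`, and the one-degree
#' instrument-strength statistic `F = (beta_exp / se_exp)^2`.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param drop_palindromic exclude palindromic SNPs (default TRUE).
#' @param palindrome_rescue opt-in frequency-based palindrome rescue
#'   (default FALSE).
#' @param eaf_cutoff rescue frequency cutoff (default 0.42).
#' @return A `harmonized_set`: data frame with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `pval_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `pval_out`, `f_stat`, `wald_ratio`,
#'   `wald_se`, plus an `exclusions` attribute (snp, reason) covering every
#'   joined SNP not retained.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE,
                      palindrome_rescue = FALSE, eaf_cutoff = 0.42) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) {
    stop("exposure and outcome share no snp ids", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  rows <- vector("list", length(shared))
  excl <- list()
  for (i in seq_along(shared)) {
    e <- ex[i, ]
    o <- ou[i, ]
    pal <- is_palindromic(e$effect_allele, e$other_allele)

    if (pal && drop_palindromic) {
      rescued <- FALSE
      if (palindrome_rescue && !is.na(e$eaf) && !is.na(o$eaf)) {
        same_side <- (e$eaf < eaf_cutoff && o$eaf < eaf_cutoff) ||
          (e$eaf > 1 - eaf_cutoff && o$eaf > 1 - eaf_cutoff)
        rescued <- same_side &&
          o$effect_allele %in% c(e$effect_allele, e$other_allele)
      }
      if (!rescued) {
        excl[[length(excl) + 1]] <- data.frame(snp = e$snp,
                                               reason = "palindromic")
        next
      }
    }

    # classify allele orientation; strand complement only for non-palindromes
    direct <- o$effect_allele == e$effect_allele &&
      o$other_allele == e$other_allele
    swapped <- o$effect_allele == e$other_allele &&
      o$other_allele == e$effect_allele
    if (!direct && !swapped && !pal) {
      cea <- complement_base(o$effect_allele)
      coa <- complement_base(o$other_allele)
      direct <- cea == e$effect_allele && coa == e$other_allele
      swapped <- cea == e$other_allele && coa == e$effect_allele
    }
    if (!direct && !swapped) {
      excl[[length(excl) + 1]] <- data.frame(snp = e$snp,
                                             reason = "incompatible alleles")
      next
    }
    if (e$beta == 0) {
      excl[[length(excl) + 1]] <- data.frame(snp = e$snp,
                                             reason = "zero exposure effect")
      next
    }
    beta_out <- if (swapped) -o$beta else o$beta
    rows[[i]] <- data.frame(
      snp = e$snp,
      effect_allele = e$effect_allele,
      other_allele = e$other_allele,
      beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf_exp = e$eaf,
      beta_out = beta_out, se_out = o$se, pval_out = o$pval,
      f_stat = (e$beta / e$se)^2,
      wald_ratio = beta_out / e$beta,
      wald_se = o$se / abs(e$beta),
      stringsAsFactors = FALSE
    )
  }
  inst <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(inst)) {
    inst <- data.frame(snp = character(0), effect_allele = character(0),
                       other_allele = character(0), beta_exp = numeric(0),
                       se_exp = numeric(0), pval_exp = numeric(0),
                       eaf_exp = numeric(0), beta_out = numeric(0),
                       se_out = numeric(0), pval_out = numeric(0),
                       f_stat = numeric(0), wald_ratio = numeric(0),
                       wald_se = numeric(0))
  }
  excl_df <- if (length(excl)) do.call(rbind, excl) else
    data.frame(snp = character(0), reason = character(0))
  message(sprintf("harmonize: %d shared snps, %d instruments, %d excluded",
                  length(shared), nrow(inst), nrow(excl_df)))
  new_harmonized_set(
    inst, excl_df,
    provenance = list(exposure = attr(exposure, "trait"),
                      outcome = attr(outcome, "trait"),
                      drop_palindromic = drop_palindromic,
                      palindrome_rescue = palindrome_rescue,
                      eaf_cutoff = eaf_cutoff)
  )
}

#' Screen out weak instruments by per-SNP F statistic
#'
#' Instruments with `f_stat < f_min` are moved to the exclusion log with
#' reason `"weak instrument"`. The boundary is inclusive: `F = f_min` is
#' kept (the conventional screen is F >= 10).
#'
#' @param set a `harmonized_set`.
#' @param f_min minimum per-SNP F statistic; default 10.
#' @return A `harmonized_set`.
#' @export
filter_strength <- function(set, f_min = 10) {
  stopifnot(f_min >= 0)
  weak <- set$f_stat < f_min
  dropped <- set[weak, , drop = FALSE]
  excl <- if (nrow(dropped)) {
    data.frame(snp = dropped$snp, reason = "weak instrument")
  } else {
    NULL
  }
  replace_instruments(set, as.data.frame(set)[!weak, , drop = FALSE], excl)
}

#' Mean F statistic across instruments
#'
#' The per-SNP F statistics are the screening quantity; the mean F is an
#' informal overall strength summary.
#'
#' @param set a `harmonized_set`.
#' @return Numeric scalar.
#' @export
mean_f_stat <- function(set) mean(set$f_stat)
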