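#' Default column mapping for GWAS summary-statistic exports
#'
#' Maps the internal field names used throughout the package to the column
#' headers of a common GWAS summary-statistic export. Override individual
#' entries to adapt to other layouts, e.g.
#' `default_column_map(snp = "rsid", pval = "P")`.
#'
#' @param ... named character overrides for any of `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return Named character vector mapping internal field -> file column.
#' @export
default_column_map <- function(...) {
  map <- c(
    snp = "SNP",
    effect_allele = "effect_allele",
    other_allele = "other_allele",
    eaf = "eaf",
    beta = "beta",
    se = "se",
    pval = "pval",
    n = "samplesize"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) {
      stop("unknown column-map field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(dots)] <- dots
  }
  map
}

VALID_BASES <- c("A", "C", "G", "T")

# Validate one candidate record; returns NA_character_ if valid, otherwise a
# short human-readable rejection reason.
validate_record <- function(snp, ea, oa, eaf, beta, se, pval) {
  if (is.na(snp) || !nzchar(snp)) return("missing snp id")
  if (is.na(ea) || !ea %in% VALID_BASES) return("invalid effect allele")
  if (is.na(oa) || !oa %in% VALID_BASES) return("invalid other allele")
  if (ea == oa) return("identical alleles")
  if (is.na(beta) || !is.finite(beta)) return("missing beta")
  if (is.na(se) || !is.finite(se) || se <= 0) return("nonpositive SE")
  if (is.na(pval) || pval <= 0 || pval > 1) return("p-value outside (0,1]")
  if (!is.na(eaf) && (eaf <= 0 || eaf >= 1)) return("eaf outside (0,1)")
  NA_character_
}

#' Construct a summary dataset from a data frame
#'
#' A `summary_dataset` is a validated data frame of per-SNP association
#' records for one trait, with columns `snp`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Effects are taken to be
#' on the log-odds scale for binary traits; p-values are kept exactly as
#' supplied and never recomputed from beta/se (published tables round the
#' two inconsistently).
#'
#' @param df data frame already using the internal column names.
#' @param trait trait label, e.g. `"CAVS"`.
#' @param metadata optional named list of provenance (source, ancestry,
#'   case/control counts).
#' @return A `summary_dataset` object (a data frame with attributes
#'   `trait`, `metadata`, `read_report`).
#' @export
summary_dataset <- function(df, trait = "trait", metadata = list()) {
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$n)) df$n <- NA_real_
  df <- df[c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
             "pval", "n")]
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) df[[col]] <- as.numeric(df[[col]])

  reasons <- mapply(validate_record, df$snp, df$effect_allele, df$other_allele,
                    df$eaf, df$beta, df$se, df$pval, USE.NAMES = FALSE)
  dropped <- df[!is.na(reasons), , drop = FALSE]
  dropped$reason <- reasons[!is.na(reasons)]
  kept <- df[is.na(reasons), , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no valid summary-statistic rows for trait '", trait, "'",
         call. = FALSE)
  }
  dup <- unique(kept$snp[duplicated(kept$snp)])
  if (length(dup)) {
    stop("duplicate snp id(s) in trait '", trait, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(kept) <- NULL
  structure(
    kept,
    trait = trait,
    metadata = metadata,
    read_report = list(
      n_input = nrow(df), n_kept = nrow(kept), n_dropped = nrow(dropped),
      dropped = dropped[, c("snp", "reason")]
    ),
    class = c("summary_dataset", "data.frame")
  )
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a delimited text file, renames columns according to `column_map`,
#' validates every row, and returns the valid records as a
#' [summary_dataset()]. Rows failing validation are rejected individually
#' with a per-row reason kept in the read report; a kept/dropped summary is
#' emitted as a message.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named mapping internal field -> file column; see
#'   [default_column_map()]. `eaf` and `n` entries may point at absent
#'   columns (treated as missing); all other mapped columns must exist.
#' @param delimiter field delimiter (default tab; use `","` for CSV).
#' @param trait trait label stored on the dataset.
#' @param metadata optional provenance list.
#' @return A `summary_dataset`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               delimiter = "\t", trait = NULL,
                               metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  optional <- c("eaf", "n")
  need <- column_map[!names(column_map) %in% optional]
  absent <- need[!need %in% names(raw)]
  if (length(absent)) {
    stop("mapped column(s) not found in ", basename(path), ": ",
         paste(sprintf("%s (field %s)", absent, names(absent)),
               collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(column_map)) {
    col <- column_map[[field]]
    df[[field]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  if (is.null(trait)) trait <- basename(path)
  ds <- summary_dataset(df, trait = trait, metadata = metadata)
  rep <- attr(ds, "read_report")
  message(sprintf("read %s: %d rows, kept %d, dropped %d",
                  basename(path), rep$n_input, rep$n_kept, rep$n_dropped))
  ds
}

#' Write a tabular result to tab-delimited text
#'
#' Tab-delimited UTF-8 with a header row; numeric fields are written at full
#' double precision (17 significant digits) so read/write round-trips are
#' lossless.
#'
#' @param rows data frame to write.
#' @param path output path.
#' @param allow_empty permit writing a table with zero rows (default FALSE).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, allow_empty = FALSE) {
  if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  if (nrow(rows) == 0 && !allow_empty) {
    stop("refusing to write empty table to ", path,
         " (set allow_empty = TRUE to override)", call. = FALSE)
  }
  out <- rows
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_ else sprintf("%.17g", x)
      }, character(1))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a summary dataset as TSV
#'
#' Column headers follow the default export profile
#' (see [default_column_map()]), so a written dataset reads back with the
#' default mapping.
#'
#' @param dataset a `summary_dataset`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(dataset, path) {
  df <- as.data.frame(dataset)
  map <- default_column_map()
  names(df) <- unname(map[names(df)])
  write_table(df, path)
}
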