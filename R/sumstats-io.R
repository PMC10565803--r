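#' Canonical summary-statistic columns
#'
#' Column order of the canonical tab-separated GWAS summary-statistic format
#' used throughout the package. `snp_id`, `effect_allele`, `other_allele`,
#' `beta`, `se` and `pvalue` are mandatory; the rest may be `NA`.
#'
#' @return Character vector of canonical column names.
#' @export
sumstat_columns <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pvalue", "n")
}

.mandatory_columns <- c("snp_id", "effect_allele", "other_allele",
                        "beta", "se", "pvalue")

#' Default column mapping for the two-sample-MR exchange format
#'
#' Maps canonical field names to the column headers used by the common
#' two-sample-MR summary-statistic exchange format (`SNP`, `effect_allele`,
#' `beta`, `se`, `pval`, `samplesize`, ...).
#'
#' @return Named character vector; names are canonical fields, values are
#'   source column headers.
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval",
    n = "samplesize")
}

#' Construct a validated GWAS summary-statistic dataset
#'
#' Validates per-SNP records against the biallelic-SNP data model: single-base
#' A/C/G/T alleles, effect allele distinct from the other allele, positive
#' standard error, p-value in (0, 1], allele frequency in \[0, 1\] and
#' position >= 1 where present. Rows violating any invariant are dropped and
#' counted; duplicate `snp_id`s keep the first occurrence only.
#'
#' @param x data.frame containing (at least) the mandatory canonical columns.
#' @param trait_id Identifier of the trait (taxon name or `"outcome"`).
#' @param trait_type Either `"exposure"` or `"outcome"`.
#' @param quiet Suppress the dropped-row message.
#'
#' @return A `gwas_dataset`: a data.frame with the canonical columns, with
#'   attributes `trait_id`, `trait_type`, `n_input`, `n_dropped` and
#'   `n_duplicate`.
#' @export
gwas_dataset <- function(x, trait_id, trait_type = c("exposure", "outcome"),
                         quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.mandatory_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(sumstat_columns(), names(x))) {
    x[[col]] <- NA
  }
  x <- x[sumstat_columns()]

  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$n <- suppressWarnings(as.numeric(x$n))

  n_input <- nrow(x)
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(x$snp_id) & nzchar(x$snp_id) &
    x$effect_allele %in% bases & x$other_allele %in% bases &
    x$effect_allele != x$other_allele &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    (is.na(x$pos) | x$pos >= 1)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]

  dup <- duplicated(x$snp_id)
  n_duplicate <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  rownames(x) <- NULL

  if (!quiet && (n_dropped > 0 || n_duplicate > 0)) {
    message(sprintf("%s: dropped %d invalid row(s), %d duplicate rsID(s); %d retained",
                    trait_id, n_dropped, n_duplicate, nrow(x)))
  }

  structure(x,
            trait_id = trait_id,
            trait_type = trait_type,
            n_input = n_input,
            n_dropped = n_dropped,
            n_duplicate = n_duplicate,
            class = c("gwas_dataset", "data.frame"))
}

#' @export
print.gwas_dataset <- function(x, ...) {
  cat(sprintf("<gwas_dataset> %s (%s): %d SNPs (%d dropped, %d duplicate at read)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x),
              attr(x, "n_dropped") %||% 0L, attr(x, "n_duplicate") %||% 0L))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset while keeping class and trait attributes.
subset_dataset <- function(dataset, keep) {
  out <- as.data.frame(dataset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_id", "trait_type")) attr(out, a) <- attr(dataset, a)
  class(out) <- c("gwas_dataset", "data.frame")
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-separated file (delimiter auto-detected from the
#' header line), renames columns via `column_map`, and validates records with
#' [gwas_dataset()]. Rows failing the record invariants are dropped and
#' counted; row order is preserved.
#'
#' @param path Path to the file.
#' @param trait_id Trait identifier to attach to the dataset.
#' @param column_map Named character vector mapping canonical field names to
#'   source column headers; defaults to [default_column_map()]. Fields mapped
#'   to columns absent from the file are an error when mandatory, ignored
#'   otherwise.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @param quiet Suppress the dropped-row message.
#'
#' @return A `gwas_dataset`.
#' @export
read_sumstats <- function(path, trait_id, column_map = default_column_map(),
                          trait_type = c("exposure", "outcome"), quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0 || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty file: ", path)

  for (field in .mandatory_columns) {
    src <- column_map[[field]]
    if (is.null(src) || is.na(src)) {
      stop("column_map does not map mandatory field: ", field)
    }
    if (!src %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (field %s) missing from %s",
                   src, field, path))
    }
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in sumstat_columns()) {
    src <- column_map[[field]]
    out[[field]] <- if (!is.null(src) && !is.na(src) && src %in% names(raw)) {
      raw[[src]]
    } else {
      NA
    }
  }
  gwas_dataset(out, trait_id = trait_id, trait_type = trait_type, quiet = quiet)
}

# Full-precision text rendering of a numeric column, NA as "NA".
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a dataset in the canonical summary-statistic format
#'
#' Writes a tab-separated file with the fixed canonical header
#' (`snp_id chrom pos effect_allele other_allele eaf beta se pvalue n`).
#' Missing optional values are serialized as `NA`. Numeric fields are written
#' at full precision so that `read_sumstats()` of the result reproduces the
#' dataset field-by-field.
#'
#' @param dataset A `gwas_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(dataset, path) {
  stopifnot(inherits(dataset, "gwas_dataset"))
  df <- as.data.frame(dataset)
  out <- data.frame(
    snp_id = df$snp_id,
    chrom = ifelse(is.na(df$chrom), "NA", df$chrom),
    pos = ifelse(is.na(df$pos), "NA", as.character(df$pos)),
    effect_allele = df$effect_allele,
    other_allele = df$other_allele,
    eaf = .fmt_num(df$eaf),
    beta = .fmt_num(df$beta),
    se = .fmt_num(df$se),
    pvalue = .fmt_num(df$pvalue),
    n = .fmt_num(df$n),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Canonical column map for files written by [write_sumstats()]
#'
#' @return Named character vector mapping each canonical field to itself.
#' @export
canonical_column_map <- function() {
  stats::setNames(sumstat_columns(), sumstat_columns())
}

#' Write the screening report
#'
#' Serializes a batch of per-taxon results as a TSV (one row per exposure and
#' method, with effect estimate, odds ratio, 95% CI, heterogeneity and
#' pleiotropy diagnostics, and the verdict) plus a machine-readable JSON twin
#' with the same content at `<path minus extension>.json`. A
#' Benjamini-Hochberg adjusted p-value column (`pvalue_bh`, computed within
#' method across exposures) is included for information only; verdicts are
#' based on nominal p-values.
#'
#' @param results A list of `taxon_result` objects or an `mr_batch`.
#' @param path Output TSV path.
#' @return Invisibly, the report data.frame.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "mr_batch")) results <- results$results
  if (inherits(results, "taxon_result")) results <- list(results)
  if (length(results) == 0) stop("no results to report")

  rows <- list()
  for (res in results) {
    q <- res$q
    ic <- res$egger_intercept
    ests <- res$estimates
    if (length(ests) == 0) {
      ests <- list(none = list(method = "none", beta = NA_real_, se = NA_real_,
                               or_ = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, pvalue = NA_real_,
                               n_snp = 0L))
    }
    for (est in ests) {
      rows[[length(rows) + 1L]] <- data.frame(
        exposure_id = res$exposure_id,
        level = res$level,
        method = est$method,
        n_snp = est$n_snp,
        beta = est$beta,
        se = est$se,
        or = est$or_,
        ci_low = est$ci_low,
        ci_high = est$ci_high,
        pvalue = est$pvalue,
        q = if (is.null(q)) NA_real_ else q$q,
        q_pvalue = if (is.null(q)) NA_real_ else q$pvalue,
        egger_intercept = if (is.null(ic)) NA_real_ else ic$intercept,
        egger_intercept_pvalue = if (is.null(ic)) NA_real_ else ic$pvalue,
        verdict = res$verdict,
        direction = res$direction,
        headline = res$headline %||% NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  report$pvalue_bh <- NA_real_
  for (m in unique(report$method)) {
    idx <- report$method == m
    report$pvalue_bh[idx] <- stats::p.adjust(report$pvalue[idx], method = "BH")
  }
  num <- vapply(report, is.numeric, logical(1))
  out <- report
  for (col in names(report)[num]) out[[col]] <- .fmt_num(report[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(report, json_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
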