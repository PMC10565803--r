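#' Construct a pairwise LD matrix
#'
#' @param r2 Square numeric matrix of squared allelic correlations with unit
#'   diagonal, symmetric, entries in \[0, 1\].
#' @param snp_ids SNP identifiers (used as dimnames); defaults to existing
#'   row names of `r2`.
#'
#' @return An `ld_matrix` (a named numeric matrix).
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(snp_ids) || length(snp_ids) != nrow(r2)) {
    stop("snp_ids must name every row of the LD matrix")
  }
  if (anyDuplicated(snp_ids)) stop("duplicate snp_id in LD matrix")
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("LD r2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from delimited text
#'
#' Accepts either a square tab-separated matrix whose header row and first
#' column hold SNP identifiers, or a 3-column long format
#' (`snp_a  snp_b  r2`) which is symmetrized on load (missing pairs are
#' treated as r2 = 0, the diagonal as 1).
#'
#' @param path Path to the file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) == 3 && !all(vapply(raw, is.numeric, logical(1))[1:2])) {
    ids <- sort(unique(c(as.character(raw[[1]]), as.character(raw[[2]]))))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      a <- as.character(raw[i, 1]); b <- as.character(raw[i, 2])
      m[a, b] <- m[b, a] <- as.numeric(raw[i, 3])
    }
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    if (ncol(m) != length(ids)) stop("square LD file: header/row mismatch")
    colnames(m) <- ids
  }
  ld_matrix(m)
}

#' Clumping configuration
#'
#' Defaults reproduce the instrument-selection settings used for
#' microbiota-scale screens: suggestive threshold p < 1e-5, r2 < 0.001 within
#' a 10,000 kb window.
#'
#' @param p_threshold Significance cutoff; instruments must have p strictly
#'   below it.
#' @param r2_threshold LD cutoff; SNP pairs at or below it are considered
#'   independent.
#' @param window_kb Physical window in kilobases; pairs farther apart are
#'   never clumped together.
#'
#' @return A `clump_config` list.
#' @export
clump_config <- function(p_threshold = 1e-5, r2_threshold = 0.001,
                         window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r2_threshold >= 0, r2_threshold <= 1,
            window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb),
            class = "clump_config")
}

#' Filter records by association p-value
#'
#' Retains exactly the records with `pvalue` strictly below `threshold`;
#' row order is preserved. An empty result is legal.
#'
#' @param dataset A `gwas_dataset`.
#' @param threshold Significance cutoff.
#' @return A `gwas_dataset`.
#' @export
filter_by_pvalue <- function(dataset, threshold = 1e-5) {
  stopifnot(inherits(dataset, "gwas_dataset"), threshold > 0, threshold <= 1)
  subset_dataset(dataset, dataset$pvalue < threshold)
}

# Deterministic candidate ordering: ascending p, then chrom, pos, snp_id.
.clump_order <- function(df) {
  order(df$pvalue, df$chrom, df$pos, df$snp_id, method = "radix")
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome, position,
#' then identifier, making the result invariant to input row order), then
#' repeatedly takes the most significant remaining SNP as an index SNP and
#' removes every remaining SNP on the same chromosome within `window_kb` of it
#' whose r2 with it exceeds `r2_threshold`. Records absent from the LD matrix
#' are dropped with a warning before clumping.
#'
#' @param dataset A `gwas_dataset` of candidate instruments.
#' @param ld An `ld_matrix` covering the candidates.
#' @param config A [clump_config()].
#' @return A `gwas_dataset` of index SNPs in selection order, with attribute
#'   `n_missing_ld` (candidates absent from `ld`).
#' @export
ld_clump <- function(dataset, ld, config = clump_config()) {
  stopifnot(inherits(dataset, "gwas_dataset"), inherits(ld, "ld_matrix"),
            inherits(config, "clump_config"))
  present <- dataset$snp_id %in% rownames(ld)
  n_missing <- sum(!present)
  if (n_missing > 0) {
    warning(sprintf("%d candidate SNP(s) absent from the LD matrix were dropped",
                    n_missing))
  }
  df <- as.data.frame(dataset)[present, , drop = FALSE]
  if (nrow(df) == 0) {
    out <- subset_dataset(dataset, rep(FALSE, nrow(dataset)))
    attr(out, "n_missing_ld") <- n_missing
    return(out)
  }
  df <- df[.clump_order(df), , drop = FALSE]
  window_bp <- config$window_kb * 1000
  alive <- rep(TRUE, nrow(df))
  keep_ids <- character(0)
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    keep_ids <- c(keep_ids, df$snp_id[i])
    if (i == nrow(df)) break
    rest <- seq.int(i + 1L, nrow(df))
    rest <- rest[alive[rest]]
    if (length(rest) == 0) next
    same_chr <- !is.na(df$chrom[rest]) & !is.na(df$chrom[i]) &
      df$chrom[rest] == df$chrom[i]
    near <- same_chr & !is.na(df$pos[rest]) & !is.na(df$pos[i]) &
      abs(df$pos[rest] - df$pos[i]) <= window_bp
    r2 <- ld[df$snp_id[i], df$snp_id[rest]]
    alive[rest[near & r2 > config$r2_threshold]] <- FALSE
  }
  out <- subset_dataset(dataset, match(keep_ids, dataset$snp_id))
  attr(out, "n_missing_ld") <- n_missing
  out
}

#' Select independent suggestive instruments for one exposure
#'
#' Applies the p-value filter then greedy LD clumping, recording the number of
#' candidates removed at each stage.
#'
#' @inheritParams ld_clump
#' @param exposure A `gwas_dataset` of exposure summary statistics.
#' @return A `gwas_dataset` of instruments with attribute `selection_counts`:
#'   a named vector `(input, removed_p, removed_missing_ld, removed_ld,
#'   retained)` whose stages sum to the input count.
#' @export
select_instruments <- function(exposure, ld, config = clump_config()) {
  suggestive <- filter_by_pvalue(exposure, config$p_threshold)
  clumped <- ld_clump(suggestive, ld, config)
  n_missing <- attr(clumped, "n_missing_ld") %||% 0L
  counts <- c(input = nrow(exposure),
              removed_p = nrow(exposure) - nrow(suggestive),
              removed_missing_ld = n_missing,
              removed_ld = nrow(suggestive) - n_missing - nrow(clumped),
              retained = nrow(clumped))
  attr(clumped, "selection_counts") <- counts
  clumped
}
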