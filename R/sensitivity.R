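#' Cochran's Q heterogeneity test
#'
#' With per-SNP Wald ratios `theta_j`, weights `w_j = beta_exp_j^2 /
#' se_out_j^2` and the fixed-effect IVW estimate `theta_hat`,
#' `Q = sum_j w_j (theta_j - theta_hat)^2` is referred to a chi-square
#' distribution with k - 1 degrees of freedom (upper tail). p > 0.05 is read
#' as absence of heterogeneity.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @return A `q_result` list: `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h) {
  ins <- .instruments(h)
  if (nrow(ins) < 2) stop("Cochran's Q requires >= 2 instruments")
  core <- .ivw_core(ins$beta_exp, ins$beta_out, ins$se_out)
  structure(list(q = core$q, df = core$df,
                 pvalue = stats::pchisq(core$q, core$df, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' Per-instrument variance explained and F statistic
#'
#' For each SNP, the variance in the exposure explained by the instrument is
#' `R2 = 2 * (1 - MAF) * MAF * beta^2` with `MAF = min(eaf, 1 - eaf)`, and
#' instrument strength is `F = R2 / (1 - R2) * (n - k - 1) / k`. Per-SNP
#' strength (the default, `k = 1`) reduces to the standard single-instrument
#' F and drives the weak-instrument filter; passing the exposure's full
#' instrument count as `k` gives the joint-reading variant.
#'
#' @param dataset A `gwas_dataset` (typically the selected instruments), or a
#'   data.frame with columns `snp_id`, `eaf`, `beta` and optionally `n`.
#' @param n Sample size of the exposure GWAS; defaults to the per-record `n`
#'   column. Must exceed `k + 1`.
#' @param k Number of instruments entering the F formula (default 1: per-SNP
#'   strength).
#' @return A data.frame with columns `snp_id`, `maf`, `r2`, `f`. SNPs with
#'   missing `eaf` (or missing `n`) get `NA` in `maf`/`r2`/`f`.
#' @export
instrument_strength <- function(dataset, n = NULL, k = 1) {
  df <- as.data.frame(dataset)
  stopifnot(all(c("snp_id", "eaf", "beta") %in% names(df)))
  n_vec <- if (is.null(n)) df$n else rep_len(n, nrow(df))
  if (is.null(n_vec)) n_vec <- rep(NA_real_, nrow(df))
  maf <- pmin(df$eaf, 1 - df$eaf)
  r2 <- 2 * (1 - maf) * maf * df$beta^2
  if (any(r2 >= 1, na.rm = TRUE)) {
    stop("R2 >= 1: malformed summary statistics (beta not on a standardized scale)")
  }
  usable <- !is.na(r2) & !is.na(n_vec)
  if (any(usable & n_vec <= k + 1)) stop("sample size n must exceed k + 1")
  f <- ifelse(usable, r2 / (1 - r2) * (n_vec - k - 1) / k, NA_real_)
  data.frame(snp_id = df$snp_id, maf = maf, r2 = r2, f = f,
             stringsAsFactors = FALSE)
}

#' Filter weak instruments by F statistic
#'
#' Splits instruments into those with `f > f_min` (kept) and the rest
#' (removed), mirroring the conventional F > 10 weak-instrument rule.
#' Instruments whose F is undefined (missing allele frequency) are kept with
#' a warning under the default `"permissive"` policy and removed under
#' `"strict"`.
#'
#' @param strengths Output of [instrument_strength()].
#' @param f_min Threshold (default 10); instruments must have F strictly
#'   above it.
#' @param missing_policy `"permissive"` (keep undefined-F instruments) or
#'   `"strict"` (remove them).
#' @return List with data.frames `kept` and `removed`; together they
#'   partition the input.
#' @export
filter_weak_instruments <- function(strengths, f_min = 10,
                                    missing_policy = c("permissive", "strict")) {
  missing_policy <- match.arg(missing_policy)
  undefined <- is.na(strengths$f)
  if (any(undefined) && missing_policy == "permissive") {
    warning(sprintf("%d instrument(s) with undefined F kept under the permissive policy",
                    sum(undefined)))
  }
  keep <- if (missing_policy == "permissive") {
    undefined | strengths$f > f_min
  } else {
    !undefined & strengths$f > f_min
  }
  list(kept = strengths[keep, , drop = FALSE],
       removed = strengths[!keep, , drop = FALSE])
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate k times, omitting each instrument in turn. A
#' row is flagged `influential` when dropping that SNP changes the sign of
#' the causal beta or moves its p-value across 0.05 relative to the full-set
#' IVW estimate.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param alpha Significance level used for the p-crossing flag.
#' @return A data.frame with one row per excluded SNP: `excluded_snp`,
#'   `beta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`, `n_snp`,
#'   `influential`.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  ins <- .instruments(h)
  k <- nrow(ins)
  if (k < 3) stop("leave-one-out requires >= 3 instruments")
  full <- mr_ivw(h)
  rows <- lapply(seq_len(k), function(j) {
    sub <- new_harmonized_set(h$exposure_id, ins[-j, , drop = FALSE],
                              h$dropped)
    est <- mr_ivw(sub)
    data.frame(excluded_snp = ins$snp_id[j], beta = est$beta, se = est$se,
               or = est$or_, ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, n_snp = est$n_snp,
               influential = sign(est$beta) != sign(full$beta) ||
                 (est$pvalue < alpha) != (full$pvalue < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a leave-one-out table to TSV
#'
#' @param loo Output of [leave_one_out()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_leave_one_out <- function(loo, path) {
  utils::write.table(loo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
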