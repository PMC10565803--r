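#' Is an allele pair palindromic?
#'
#' A biallelic SNP is palindromic (strand-ambiguous) when its two alleles are
#' complementary: A/T or C/G. For such SNPs the strand cannot be resolved from
#' the alleles alone, so they are removed during harmonization.
#'
#' @param a1,a2 Single-base alleles (A, C, G or T); vectorized.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  bases <- c("A", "C", "G", "T")
  if (any(!a1 %in% bases) || any(!a2 %in% bases)) {
    stop("alleles must be single bases A/C/G/T")
  }
  if (any(a1 == a2)) stop("identical alleles do not form a valid SNP")
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns the outcome effect of each instrument to the exposure's effect
#' allele. For each exposure SNP: absent from the outcome dataset ->
#' dropped (`missing_in_outcome`); palindromic in either dataset -> dropped
#' (`palindromic`), unconditionally and without allele-frequency rescue;
#' outcome alleles identical to exposure alleles -> kept as-is; outcome
#' alleles swapped -> outcome beta negated and `flipped = TRUE`; any other
#' combination (including strand complements) -> dropped (`allele_mismatch`).
#'
#' @param exposure A `gwas_dataset` of selected instruments.
#' @param outcome A `gwas_dataset` of outcome summary statistics.
#' @return A `harmonized_set`: list with `exposure_id`, `instruments`
#'   (data.frame: `snp_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `eaf_exp`, `flipped`) and `dropped` (data.frame: `snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "gwas_dataset"), inherits(outcome, "gwas_dataset"))
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)
  idx <- match(exp_df$snp_id, out_df$snp_id)

  kept <- list()
  dropped <- list()
  drop <- function(id, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(snp_id = id, reason = reason,
                                                   stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(exp_df))) {
    j <- idx[i]
    if (is.na(j)) { drop(exp_df$snp_id[i], "missing_in_outcome"); next }
    e1 <- exp_df$effect_allele[i]; e2 <- exp_df$other_allele[i]
    o1 <- out_df$effect_allele[j]; o2 <- out_df$other_allele[j]
    if (is_palindromic(e1, e2) || is_palindromic(o1, o2)) {
      drop(exp_df$snp_id[i], "palindromic"); next
    }
    if (o1 == e1 && o2 == e2) {
      beta_out <- out_df$beta[j]; flipped <- FALSE
    } else if (o1 == e2 && o2 == e1) {
      beta_out <- -out_df$beta[j]; flipped <- TRUE
    } else {
      drop(exp_df$snp_id[i], "allele_mismatch"); next
    }
    kept[[length(kept) + 1L]] <- data.frame(
      snp_id = exp_df$snp_id[i],
      beta_exp = exp_df$beta[i],
      se_exp = exp_df$se[i],
      beta_out = beta_out,
      se_out = out_df$se[j],
      eaf_exp = exp_df$eaf[i],
      flipped = flipped,
      stringsAsFactors = FALSE
    )
  }
  instruments <- if (length(kept)) do.call(rbind, kept) else
    data.frame(snp_id = character(0), beta_exp = numeric(0),
               se_exp = numeric(0), beta_out = numeric(0),
               se_out = numeric(0), eaf_exp = numeric(0),
               flipped = logical(0), stringsAsFactors = FALSE)
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(snp_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  new_harmonized_set(attr(exposure, "trait_id"), instruments, dropped)
}

new_harmonized_set <- function(exposure_id, instruments, dropped) {
  structure(list(exposure_id = exposure_id,
                 instruments = instruments,
                 dropped = dropped),
            class = "harmonized_set")
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where exposure and
#' outcome effects are already expressed on the same effect allele.
#'
#' @param beta_exp,se_exp Exposure effects and standard errors.
#' @param beta_out,se_out Outcome effects and standard errors.
#' @param snp_id Instrument identifiers; generated when omitted.
#' @param eaf_exp Optional effect-allele frequencies.
#' @param exposure_id Label for the exposure.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = NULL, eaf_exp = NA_real_,
                           exposure_id = "exposure") {
  k <- length(beta_exp)
  stopifnot(length(se_exp) == k, length(beta_out) == k, length(se_out) == k,
            all(se_exp > 0), all(se_out > 0))
  if (is.null(snp_id)) snp_id <- sprintf("snp_%04d", seq_len(k))
  instruments <- data.frame(snp_id = snp_id, beta_exp = beta_exp,
                            se_exp = se_exp, beta_out = beta_out,
                            se_out = se_out,
                            eaf_exp = rep_len(eaf_exp, k),
                            flipped = FALSE, stringsAsFactors = FALSE)
  new_harmonized_set(exposure_id, instruments,
                     data.frame(snp_id = character(0), reason = character(0),
                                stringsAsFactors = FALSE))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s: %d instrument(s), %d dropped\n",
              x$exposure_id, nrow(x$instruments), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) {
    print(table(x$dropped$reason))
  }
  invisible(x)
}
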