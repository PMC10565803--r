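#' Ground-truth parameters for a synthetic two-sample MR dataset
#'
#' Defaults emulate a microbiota-taxon exposure GWAS (N = 18,340, roughly 10
#' independent suggestive instruments per taxon) screened against a binary
#' outcome GWAS of 8,288 cases and 68,969 controls (N = 77,257) on the
#' log-odds scale, with no causal effect and no assumption violations.
#' Pleiotropy modes violate the exclusion assumption by design: `"balanced"`
#' draws zero-mean direct effects, `"directional"` draws them around
#' `pleio_mean`; `pleio_frac` sets the fraction of instruments that are
#' invalid. Direct effects are defined in the exposure-increasing-allele
#' frame (allele coding is arbitrary, so directionality is only meaningful
#' relative to the allele that raises the exposure). `het_sd` adds extra
#' outcome-effect noise that Cochran's Q should detect.
#'
#' @param theta True causal effect (log-OR per unit of exposure).
#' @param k_true Number of true instruments (>= 1).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleio_mean Mean direct effect (directional mode).
#' @param pleio_sd Spread of direct effects.
#' @param pleio_frac Fraction of instruments given a direct effect.
#' @param het_sd SD of extra per-SNP outcome-effect noise.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param beta_exp_sd Spread of true instrument effects (standardized-trait
#'   scale).
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param n_decoy Null SNPs added so the p-value filter does nontrivial work
#'   (default 50 per true instrument).
#' @param palindrome_frac Fraction of SNPs given palindromic (A/T or C/G)
#'   alleles, to exercise harmonization.
#' @param seed Integer seed (mandatory).
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(theta = 0, k_true = 10,
                             pleiotropy_mode = c("none", "balanced", "directional"),
                             pleio_mean = 0, pleio_sd = 0, pleio_frac = 1,
                             het_sd = 0, maf_range = c(0.05, 0.5),
                             beta_exp_sd = 0.08,
                             n_exp = 18340, n_out = 77257,
                             n_decoy = 50 * k_true, palindrome_frac = 0,
                             seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("simulation_truth requires an explicit seed")
  stopifnot(k_true >= 1, n_decoy >= 0, het_sd >= 0, pleio_sd >= 0,
            pleio_frac >= 0, pleio_frac <= 1,
            palindrome_frac >= 0, palindrome_frac <= 1,
            beta_exp_sd > 0, n_exp > 2, n_out > 2)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2]) {
    stop("degenerate maf_range: need 0 < low < high <= 0.5")
  }
  if (pleiotropy_mode == "none" && (pleio_mean != 0 || pleio_sd != 0)) {
    stop("pleiotropy_mode 'none' requires pleio_mean = pleio_sd = 0")
  }
  structure(list(theta = theta, k_true = as.integer(k_true),
                 pleiotropy_mode = pleiotropy_mode, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, pleio_frac = pleio_frac,
                 het_sd = het_sd, maf_range = maf_range,
                 beta_exp_sd = beta_exp_sd, n_exp = n_exp, n_out = n_out,
                 n_decoy = as.integer(n_decoy),
                 palindrome_frac = palindrome_frac, seed = as.integer(seed)),
            class = "simulation_truth")
}

# Suggestive threshold the generator guarantees true instruments clear.
.suggestive_p <- 1e-5

# Draw a truncated N(0, sd) with |x| >= lo by rejection sampling.
.draw_instrument_effect <- function(sd, lo) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, 0, sd)
    if (abs(x) >= lo) return(x)
  }
  stop("beta_exp_sd too small relative to the suggestive threshold at n_exp")
}

#' Simulate one exposure/outcome summary-statistic pair with known truth
#'
#' Generates `k_true` true instruments plus `n_decoy` null SNPs on a shared
#' panel. For each true instrument: MAF ~ Uniform(`maf_range`); the true
#' exposure effect is drawn from Normal(0, `beta_exp_sd`) resampled until it
#' clears the suggestive threshold (p < 1e-5) at `n_exp` with probability
#' near 1; standard errors follow the standardized-trait approximation
#' `1 / sqrt(2 MAF (1 - MAF) n)`; the true outcome effect is
#' `theta * beta_exp` plus any direct (pleiotropic) effect, and observed
#' effects add sampling noise (plus `het_sd` noise on the outcome). P-values
#' are exact normal tails of the observed z-scores. Alleles are drawn from
#' non-palindromic ordered pairs unless `palindrome_frac > 0`. SNPs are
#' placed more than one clump window apart, consistent with the identity LD
#' matrix returned alongside.
#'
#' @param truth A [simulation_truth()].
#' @param trait_id Exposure trait identifier (default `"genus.SimTaxon"`).
#' @return List with `exposure` and `outcome` (`gwas_dataset`s), `ld` (an
#'   identity `ld_matrix` over the panel) and `truth` (the input echoed with
#'   `instrument_ids`, per-instrument `beta_exp_true` and `direct_effect`).
#' @export
simulate_taxon <- function(truth, trait_id = "genus.SimTaxon") {
  stopifnot(inherits(truth, "simulation_truth"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(truth$seed)

  k <- truth$k_true
  m <- k + truth$n_decoy
  ids <- sprintf("snp_%05d", seq_len(m))
  maf <- stats::runif(m, truth$maf_range[1], truth$maf_range[2])
  eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_exp)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_out)

  z_req <- stats::qnorm(1 - .suggestive_p / 2) + 3
  bx_true <- numeric(m)
  for (j in seq_len(k)) {
    bx_true[j] <- .draw_instrument_effect(truth$beta_exp_sd, z_req * se_exp[j])
  }

  direct <- numeric(m)
  if (truth$pleiotropy_mode != "none" && truth$pleio_frac > 0) {
    n_invalid <- round(truth$pleio_frac * k)
    invalid <- sample(seq_len(k), n_invalid)
    mu <- if (truth$pleiotropy_mode == "directional") truth$pleio_mean else 0
    direct[invalid] <- stats::rnorm(n_invalid, mu, truth$pleio_sd)
  }
  # Direct effects act in the exposure-increasing-allele frame.
  by_true <- truth$theta * bx_true + sign(bx_true) * direct

  bx_obs <- stats::rnorm(m, bx_true, se_exp)
  by_noise <- if (truth$het_sd > 0) stats::rnorm(m, 0, truth$het_sd) else 0
  by_obs <- stats::rnorm(m, by_true + by_noise, se_out)

  p_exp <- 2 * stats::pnorm(-abs(bx_obs / se_exp))
  p_out <- 2 * stats::pnorm(-abs(by_obs / se_out))

  non_pal <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  use_pal <- stats::runif(m) < truth$palindrome_frac
  pick_np <- sample(nrow(non_pal), m, replace = TRUE)
  pick_p <- sample(nrow(pal), m, replace = TRUE)
  a1 <- ifelse(use_pal, pal[pick_p, 1], non_pal[pick_np, 1])
  a2 <- ifelse(use_pal, pal[pick_p, 2], non_pal[pick_np, 2])

  chrom <- as.character(((seq_len(m) - 1) %% 22) + 1)
  pos <- as.integer(((seq_len(m) - 1) %/% 22) * 15000000 + 1000000)

  base <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                     effect_allele = a1, other_allele = a2, eaf = eaf,
                     stringsAsFactors = FALSE)
  exposure <- base
  exposure$beta <- bx_obs; exposure$se <- se_exp
  exposure$pvalue <- pmax(p_exp, .Machine$double.xmin)
  exposure$n <- truth$n_exp
  outcome <- base
  outcome$beta <- by_obs; outcome$se <- se_out
  outcome$pvalue <- pmax(p_out, .Machine$double.xmin)
  outcome$n <- truth$n_out

  truth_echo <- truth
  truth_echo$instrument_ids <- ids[seq_len(k)]
  truth_echo$beta_exp_true <- bx_true[seq_len(k)]
  truth_echo$direct_effect <- direct[seq_len(k)]

  list(exposure = gwas_dataset(exposure, trait_id, "exposure", quiet = TRUE),
       outcome = gwas_dataset(outcome, "outcome", "outcome", quiet = TRUE),
       ld = ld_matrix(diag(m), ids),
       truth = truth_echo)
}

#' Simulate a block-diagonal LD matrix
#'
#' Builds an LD matrix with constant `within_r2` inside each block, zero
#' across blocks and unit diagonal. The accompanying map places every block
#' within one clump window (members 10 kb apart on one chromosome) and
#' distinct blocks more than a window apart, so clumping with default
#' settings treats blocks as LD units.
#'
#' @param snp_ids Ordered SNP identifiers.
#' @param block_sizes Integer partition of `length(snp_ids)`.
#' @param within_r2 Squared correlation inside blocks, in \[0, 1\].
#' @return An `ld_matrix` with attribute `map`: a data.frame
#'   (`snp_id`, `chrom`, `pos`) consistent with the block structure.
#' @export
simulate_ld <- function(snp_ids, block_sizes, within_r2) {
  if (sum(block_sizes) != length(snp_ids) || any(block_sizes < 1)) {
    stop("block_sizes must be a partition of snp_ids")
  }
  stopifnot(within_r2 >= 0, within_r2 <= 1)
  m <- length(snp_ids)
  r2 <- matrix(0, m, m)
  pos <- integer(m)
  offset <- 0L
  for (b in seq_along(block_sizes)) {
    idx <- offset + seq_len(block_sizes[b])
    r2[idx, idx] <- within_r2
    pos[idx] <- (b - 1L) * 20000000L + (seq_len(block_sizes[b]) - 1L) * 10000L + 1L
    offset <- offset + block_sizes[b]
  }
  diag(r2) <- 1
  out <- ld_matrix(r2, snp_ids)
  attr(out, "map") <- data.frame(snp_id = snp_ids, chrom = "1", pos = pos,
                                 stringsAsFactors = FALSE)
  out
}
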