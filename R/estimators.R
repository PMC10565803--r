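#' Construct an MR causal-effect estimate
#'
#' Packages a causal log-odds estimate with its standard error, two-sided
#' p-value, odds ratio and 95% confidence interval
#' (`exp(beta +/- 1.96 * se)`).
#'
#' @param method One of `"wald_ratio"`, `"ivw"`, `"mr_egger"`,
#'   `"weighted_median"`.
#' @param beta Causal log-OR.
#' @param se Standard error (> 0).
#' @param pvalue Two-sided p-value.
#' @param n_snp Number of instruments used.
#' @return An `mr_estimate` list with fields `method`, `beta`, `se`,
#'   `pvalue`, `or_`, `ci_low`, `ci_high`, `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, pvalue, n_snp) {
  stopifnot(se > 0)
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se), n_snp = as.integer(n_snp)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pvalue, x$n_snp))
  invisible(x)
}

.instruments <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h$instruments
}

#' Per-SNP Wald ratio estimate
#'
#' The single-instrument causal estimate: outcome beta divided by exposure
#' beta, with the first-order delta-method standard error
#' `se_out / |beta_exp|` and a normal two-sided p-value.
#'
#' @param inst A single harmonized instrument: a one-row data.frame (or list)
#'   with fields `beta_exp`, `beta_out`, `se_out`.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(inst) {
  bx <- inst$beta_exp; by <- inst$beta_out; seo <- inst$se_out
  stopifnot(length(bx) == 1)
  if (bx == 0) stop("wald_ratio undefined for beta_exp = 0")
  beta <- by / bx
  se <- seo / abs(bx)
  mr_estimate("wald_ratio", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

# Shared IVW core: fixed-effect estimate, SE and Cochran's Q.
.ivw_core <- function(bx, by, seo) {
  w <- bx^2 / seo^2
  theta <- by / bx
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  list(beta = beta, se_fixed = se_fixed, q = q, df = length(bx) - 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios with weights `beta_exp^2 / se_out^2`
#' (equivalently, the slope of the zero-intercept weighted regression of
#' outcome on exposure betas with weights `1 / se_out^2`). The default
#' reported standard error is multiplicative random-effects: the fixed-effect
#' SE inflated by `max(1, sqrt(Q / (k - 1)))`, where Q is Cochran's
#' heterogeneity statistic; `se_type = "fixed"` reports the plain
#' fixed-effect SE. P-values are normal two-sided.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param se_type `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with extra fields `se_fixed`, `se_random` and
#'   `pvalue_fixed`.
#' @export
mr_ivw <- function(h, se_type = c("random", "fixed")) {
  se_type <- match.arg(se_type)
  ins <- .instruments(h)
  k <- nrow(ins)
  if (k < 2) stop("IVW requires >= 2 instruments; use wald_ratio() for a single SNP")
  core <- .ivw_core(ins$beta_exp, ins$beta_out, ins$se_out)
  se_random <- core$se_fixed * max(1, sqrt(core$q / core$df))
  se <- if (se_type == "random") se_random else core$se_fixed
  est <- mr_estimate("ivw", core$beta, se,
                     2 * stats::pnorm(-abs(core$beta / se)), k)
  est$se_fixed <- core$se_fixed
  est$se_random <- se_random
  est$pvalue_fixed <- 2 * stats::pnorm(-abs(core$beta / core$se_fixed))
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept and weights `1 / se_out^2`, after orienting every instrument so
#' its exposure beta is non-negative (Egger regression is not invariant to
#' allele orientation; the exposure-increasing-allele convention makes it
#' deterministic). The slope estimates the causal effect; the intercept
#' estimates average directional pleiotropy. Coefficient standard errors use
#' the weighted-regression covariance with the residual variance floored at 1
#' (multiplicative random effects), and p-values come from the t distribution
#' with k - 2 degrees of freedom.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return An `mr_egger_fit` list: `estimate` (an `mr_estimate` for the
#'   slope), `intercept` (list `intercept`, `se`, `pvalue`), `sigma`
#'   (residual SD after flooring) and `studentized_residuals` (internally
#'   studentized, used for per-SNP pleiotropy flags).
#' @export
mr_egger <- function(h) {
  ins <- .instruments(h)
  k <- nrow(ins)
  if (k < 3) stop("MR-Egger requires >= 3 instruments")
  sgn <- ifelse(ins$beta_exp < 0, -1, 1)
  bx <- sgn * ins$beta_exp
  by <- sgn * ins$beta_out
  w <- 1 / ins$se_out^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  if (det <= .Machine$double.eps * sw * sxx) {
    stop("zero variance in beta_exp: Egger slope unidentified")
  }
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (sxx * swy - swx * sxy) / det
  fitted <- intercept + slope * bx
  rss <- sum(w * (by - fitted)^2)
  sigma2 <- max(1, rss / (k - 2))
  se_slope <- sqrt(sigma2 * sw / det)
  se_intercept <- sqrt(sigma2 * sxx / det)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  p_intercept <- 2 * stats::pt(-abs(intercept / se_intercept), df = k - 2)

  # Internally studentized residuals on the weighted scale (hat values of
  # the weighted design), used to flag individual pleiotropic instruments.
  hat <- w * (sxx - 2 * bx * swx + bx^2 * sw) / det
  stud <- sqrt(w) * (by - fitted) / sqrt(sigma2 * pmax(1e-12, 1 - hat))

  est <- mr_estimate("mr_egger", slope, se_slope, p_slope, k)
  structure(list(estimate = est,
                 intercept = list(intercept = intercept, se = se_intercept,
                                  pvalue = p_intercept),
                 sigma = sqrt(sigma2),
                 studentized_residuals = stats::setNames(stud, ins$snp_id)),
            class = "mr_egger_fit")
}

# Weighted median of ratios theta with weights w (normalized internally):
# sort ascending, form cumulative-weight midpoints s_j = cum(w)_j - w_j / 2,
# linearly interpolate theta at s = 0.5, clamping outside [s_1, s_k].
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2`, consistent when instruments carrying more than
#' half of the total weight are valid. The standard error is the standard
#' deviation of the estimate over `n_boot` parametric-bootstrap replicates
#' (each replicate redraws every `beta_exp` and `beta_out` from
#' `Normal(beta, se)` and recomputes ratios, weights and the weighted
#' median); the p-value is normal two-sided.
#'
#' @param h A `harmonized_set` with at least 2 usable instruments.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (mandatory, for
#'   reproducibility). The caller's RNG state is restored on exit.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  if (missing(seed)) stop("mr_weighted_median requires an explicit seed")
  stopifnot(n_boot >= 1)
  ins <- .instruments(h)
  zero <- ins$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("dropping %d instrument(s) with beta_exp = 0", sum(zero)))
    ins <- ins[!zero, , drop = FALSE]
  }
  k <- nrow(ins)
  if (k < 2) stop("weighted median requires >= 2 instruments with beta_exp != 0")

  theta <- ins$beta_out / ins$beta_exp
  w <- ins$beta_exp^2 / ins$se_out^2
  beta <- .weighted_median(theta, w)

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
  set.seed(seed)
  bx_b <- matrix(stats::rnorm(k * n_boot, ins$beta_exp, ins$se_exp), nrow = k)
  by_b <- matrix(stats::rnorm(k * n_boot, ins$beta_out, ins$se_out), nrow = k)
  boots <- vapply(seq_len(n_boot), function(j) {
    bx <- bx_b[, j]
    ok <- bx != 0
    if (sum(ok) < 2) return(NA_real_)
    .weighted_median(by_b[ok, j] / bx[ok], bx[ok]^2 / ins$se_out[ok]^2)
  }, numeric(1))
  se <- stats::sd(boots, na.rm = TRUE)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", beta, se,
              2 * stats::pnorm(-abs(beta / se)), k)
}
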