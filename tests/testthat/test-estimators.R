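two_snp_set <- function() {
  # (beta_exp, beta_out, se_out) = (0.5, 0.1, 0.1) and (0.2, 0.06, 0.2)
  harmonized_set(beta_exp = c(0.5, 0.2), se_exp = c(0.01, 0.01),
                 beta_out = c(0.1, 0.06), se_out = c(0.1, 0.2))
}

test_that("Wald ratio arithmetic, null case and delta-method SE", {
  inst <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.25,
                     se_out = 0.1)
  est <- wald_ratio(inst)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)

  null_est <- wald_ratio(data.frame(beta_exp = 0.5, beta_out = 0, se_out = 0.1))
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$or_, 1)

  expect_error(wald_ratio(data.frame(beta_exp = 0, beta_out = 1, se_out = 1)),
               "beta_exp")
})

test_that("IVW reproduces the closed-form two-instrument solution", {
  est <- mr_ivw(two_snp_set())
  # weights 25 and 1: beta = (25*0.2 + 1*0.3)/26, fixed SE = 1/sqrt(26)
  expect_equal(est$beta, 5.3 / 26, tolerance = 1e-12)
  expect_equal(est$se_fixed, 1 / sqrt(26), tolerance = 1e-12)
})

test_that("identical Wald ratios give the ratio exactly with Q = 0 and RE = fixed SE", {
  h <- harmonized_set(beta_exp = c(0.2, 0.4, 0.5), se_exp = rep(0.01, 3),
                      beta_out = 0.3 * c(0.2, 0.4, 0.5),
                      se_out = c(0.05, 0.07, 0.04))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$se_random, est$se_fixed)
  expect_equal(cochran_q(h)$q, 0, tolerance = 1e-20)
})

test_that("IVW equals the zero-intercept WLS oracle on simulated instruments", {
  tr <- simulation_truth(theta = 0.15, k_true = 50, n_decoy = 0, seed = 31)
  res <- sim_harmonized(tr)
  ins <- res$h$instruments
  est <- mr_ivw(res$h)
  fit <- lm(beta_out ~ beta_exp - 1, data = ins, weights = 1 / ins$se_out^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  sm <- summary(fit)
  expect_equal(est$se_fixed, unname(sm$coefficients[1, 2] / sm$sigma),
               tolerance = 1e-10)
})

test_that("IVW rejects a single instrument", {
  h <- harmonized_set(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.1,
                      se_out = 0.1)
  expect_error(mr_ivw(h), "wald_ratio")
})

test_that("MR-Egger recovers an exact linear relationship with floored SEs", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonized_set(beta_exp = bx, se_exp = rep(0.01, 4),
                      beta_out = 0.03 + 0.4 * bx, se_out = rep(0.1, 4))
  fit <- mr_egger(h)
  expect_equal(fit$estimate$beta, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept$intercept, 0.03, tolerance = 1e-12)
  expect_equal(fit$sigma, 1)  # residual variance floored at 1

  expect_error(mr_egger(harmonized_set(beta_exp = c(1, 2), se_exp = c(1, 1),
                                       beta_out = c(1, 2), se_out = c(1, 1))))
  expect_error(mr_egger(harmonized_set(beta_exp = rep(0.2, 3),
                                       se_exp = rep(0.01, 3),
                                       beta_out = c(0.1, 0.2, 0.3),
                                       se_out = rep(0.1, 3))),
               "unidentified")
})

test_that("MR-Egger equals the WLS-with-intercept oracle on simulated instruments", {
  tr <- simulation_truth(theta = 0.2, k_true = 20, n_decoy = 0,
                         pleiotropy_mode = "balanced", pleio_sd = 0.02,
                         seed = 33)
  res <- sim_harmonized(tr)
  ins <- res$h$instruments
  sgn <- ifelse(ins$beta_exp < 0, -1, 1)
  df <- data.frame(bx = sgn * ins$beta_exp, by = sgn * ins$beta_out)
  w <- 1 / ins$se_out^2
  fit <- lm(by ~ bx, data = df, weights = w)
  egger <- mr_egger(res$h)
  expect_equal(egger$estimate$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(egger$intercept$intercept, unname(coef(fit)[1]),
               tolerance = 1e-10)
  sm <- summary(fit)
  scale <- max(1, sm$sigma) / sm$sigma
  expect_equal(egger$estimate$se, unname(sm$coefficients[2, 2]) * scale,
               tolerance = 1e-10)
  expect_equal(egger$intercept$se, unname(sm$coefficients[1, 2]) * scale,
               tolerance = 1e-10)
  # t reference with k - 2 df
  expect_equal(egger$estimate$pvalue,
               2 * pt(-abs(egger$estimate$beta / egger$estimate$se), 18),
               tolerance = 1e-12)
})

test_that("weighted median of equal-weight ratios is the middle ratio", {
  h <- harmonized_set(beta_exp = rep(1, 3), se_exp = rep(0.01, 3),
                      beta_out = c(0.1, 0.2, 0.3), se_out = rep(0.1, 3))
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)
})

test_that("a dominant-weight instrument pins the weighted median to its neighborhood", {
  h <- harmonized_set(beta_exp = c(1, 0.1, 0.1), se_exp = rep(0.01, 3),
                      beta_out = c(0.5, 0.09, 0.2), se_out = rep(0.1, 3))
  # weights proportional to 100, 1, 1: first ratio (0.5) dominates, and the
  # estimate must sit in its interpolation neighborhood
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_lt(abs(est$beta - 0.5), 0.05)
})

test_that("weighted median brackets the weighted-absolute-deviation grid minimizer", {
  # The interpolated weighted median lies between the two sorted ratios whose
  # cumulative-weight midpoints bracket 0.5; the WAD minimizer is one of those
  # two endpoints, so the two must agree to within that interpolation gap.
  for (seed in c(41, 42, 43)) {
    tr <- simulation_truth(theta = 0.25, k_true = 15, n_decoy = 0, seed = seed)
    res <- sim_harmonized(tr)
    est <- mr_weighted_median(res$h, n_boot = 20, seed = seed)
    ins <- res$h$instruments
    theta <- ins$beta_out / ins$beta_exp
    w <- ins$beta_exp^2 / ins$se_out^2
    grid <- seq(min(theta), max(theta), length.out = 20001)
    wad <- vapply(grid, function(g) sum(w * abs(theta - g)), numeric(1))
    wad_min <- grid[which.min(wad)]

    sorted <- sort(theta)
    below <- sorted[sorted <= est$beta]
    above <- sorted[sorted >= est$beta]
    lo <- if (length(below)) max(below) else min(sorted)
    hi <- if (length(above)) min(above) else max(sorted)
    gap <- (hi - lo) + diff(grid[1:2])
    expect_lt(abs(est$beta - wad_min), gap + 1e-12)
  }
})

test_that("weighted median drops zero-exposure instruments and its bootstrap is seed-stable", {
  h <- harmonized_set(beta_exp = c(0, 1, 1, 1), se_exp = rep(0.01, 4),
                      beta_out = c(5, 0.1, 0.2, 0.3), se_out = rep(0.1, 4))
  expect_warning(est <- mr_weighted_median(h, n_boot = 50, seed = 2),
                 "beta_exp = 0")
  expect_equal(est$n_snp, 3L)

  h2 <- harmonized_set(beta_exp = c(0.3, 0.5), se_exp = rep(0.01, 2),
                      beta_out = c(0.06, 0.11), se_out = c(0.05, 0.06))
  a <- mr_weighted_median(h2, n_boot = 200, seed = 10)
  b <- mr_weighted_median(h2, n_boot = 200, seed = 10)
  expect_identical(a$se, b$se)
})

test_that("estimators are sign- and scale-equivariant", {
  tr <- simulation_truth(theta = 0.2, k_true = 12, n_decoy = 0, seed = 51)
  res <- sim_harmonized(tr)
  h <- res$h
  neg <- h; neg$instruments$beta_out <- -neg$instruments$beta_out
  scl <- h; scl$instruments$beta_exp <- 2 * scl$instruments$beta_exp

  for (pair in list(list(mr_ivw(h), mr_ivw(neg), mr_ivw(scl)),
                    list(mr_egger(h)$estimate, mr_egger(neg)$estimate,
                         mr_egger(scl)$estimate))) {
    expect_equal(pair[[2]]$beta, -pair[[1]]$beta, tolerance = 1e-10)
    expect_equal(pair[[2]]$or_, 1 / pair[[1]]$or_, tolerance = 1e-10)
    expect_equal(pair[[3]]$beta, pair[[1]]$beta / 2, tolerance = 1e-10)
  }
  wm <- mr_weighted_median(h, n_boot = 20, seed = 3)
  wm_neg <- mr_weighted_median(neg, n_boot = 20, seed = 3)
  expect_equal(wm_neg$beta, -wm$beta, tolerance = 1e-10)
})

test_that("confidence bounds are symmetric about the log odds ratio", {
  est <- mr_ivw(two_snp_set())
  expect_equal(log(est$ci_low) + log(est$ci_high), 2 * log(est$or_),
               tolerance = 1e-12)
  expect_true(est$ci_low < est$or_ && est$or_ < est$ci_high)
})

test_that("Egger intercept p-values are calibrated under balanced pleiotropy", {
  reject <- vapply(1:200, function(i) {
    tr <- simulation_truth(theta = 0.1, k_true = 15, n_decoy = 0,
                           pleiotropy_mode = "balanced", pleio_sd = 0.01,
                           seed = 5000 + i)
    res <- sim_harmonized(tr)
    mr_egger(res$h)$intercept$pvalue < 0.05
  }, logical(1))
  # 99% binomial band around 0.05 for 200 draws
  expect_gte(mean(reject), 0.01)
  expect_lte(mean(reject), 0.105)
})
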