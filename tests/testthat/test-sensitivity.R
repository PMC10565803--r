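test_that("Cochran's Q matches the hand-computed two-instrument value", {
  h <- harmonized_set(beta_exp = c(0.5, 0.2), se_exp = c(0.01, 0.01),
                      beta_out = c(0.1, 0.06), se_out = c(0.1, 0.2))
  qr <- cochran_q(h)
  # weights 25, 1; ratios 0.2, 0.3; pooled 5.3/26
  q_hand <- 25 * (0.2 - 5.3 / 26)^2 + 1 * (0.3 - 5.3 / 26)^2
  expect_equal(qr$q, q_hand, tolerance = 1e-12)
  expect_equal(qr$q, 0.00962, tolerance = 1e-3)
  expect_equal(qr$df, 1)
  expect_equal(qr$pvalue, pchisq(q_hand, 1, lower.tail = FALSE))

  same <- harmonized_set(beta_exp = c(0.2, 0.5), se_exp = c(0.01, 0.01),
                         beta_out = 0.4 * c(0.2, 0.5), se_out = c(0.1, 0.2))
  expect_equal(cochran_q(same)$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(same)$pvalue, 1)
})

test_that("Q is invariant under instrument permutation and outcome sign flip", {
  tr <- simulation_truth(theta = 0.2, k_true = 10, n_decoy = 0, het_sd = 0.01,
                         seed = 61)
  res <- sim_harmonized(tr)
  h <- res$h
  q0 <- cochran_q(h)$q

  perm <- h
  perm$instruments <- perm$instruments[sample(nrow(perm$instruments)), ]
  expect_equal(cochran_q(perm)$q, q0, tolerance = 1e-12)

  neg <- h
  neg$instruments$beta_out <- -neg$instruments$beta_out
  expect_equal(cochran_q(neg)$q, q0, tolerance = 1e-12)
})

test_that("variance explained and F follow the strength equations", {
  # symmetry point: MAF 0.5, beta 1 explains half the variance
  ds <- data.frame(snp_id = "s1", eaf = 0.5, beta = 1, n = 100)
  expect_equal(instrument_strength(ds)$r2, 0.5)

  # MAF 0.3, beta 0.1 at n = 18,340 with k = 1
  ds2 <- data.frame(snp_id = "s2", eaf = 0.3, beta = 0.1, n = 18340)
  st <- instrument_strength(ds2)
  expect_equal(st$r2, 2 * 0.7 * 0.3 * 0.01, tolerance = 1e-12)
  expect_equal(st$f, 0.0042 / (1 - 0.0042) * (18340 - 1 - 1) / 1,
               tolerance = 1e-12)
  expect_equal(st$f, 77.3, tolerance = 1e-2)

  # null effect explains nothing
  ds3 <- data.frame(snp_id = "s3", eaf = 0.2, beta = 0, n = 1000)
  expect_equal(instrument_strength(ds3)$f, 0)

  # eaf above 0.5 folds onto the minor allele: symmetric in MAF <-> 1 - MAF
  a <- instrument_strength(data.frame(snp_id = "a", eaf = 0.1, beta = 0.2,
                                      n = 5000))
  b <- instrument_strength(data.frame(snp_id = "b", eaf = 0.9, beta = 0.2,
                                      n = 5000))
  expect_equal(a$r2, b$r2)

  # joint-k reading is supported and smaller than per-SNP strength
  st_k <- instrument_strength(ds2, k = 10)
  expect_lt(st_k$f, st$f)

  expect_error(instrument_strength(data.frame(snp_id = "x", eaf = 0.5,
                                              beta = 2, n = 100)), "R2")
})

test_that("F is increasing in R2 and in n; missing eaf propagates as NA", {
  betas <- seq(0.05, 0.3, by = 0.05)
  st <- instrument_strength(data.frame(snp_id = paste0("s", seq_along(betas)),
                                       eaf = 0.3, beta = betas, n = 10000))
  expect_true(all(diff(st$f) > 0))
  st_n <- vapply(c(1e3, 1e4, 1e5), function(n) {
    instrument_strength(data.frame(snp_id = "s", eaf = 0.3, beta = 0.1,
                                   n = n))$f
  }, numeric(1))
  expect_true(all(diff(st_n) > 0))

  miss <- instrument_strength(data.frame(snp_id = "m", eaf = NA_real_,
                                         beta = 0.1, n = 1000))
  expect_true(is.na(miss$f))
})

test_that("the weak-instrument filter removes F <= 10 and partitions the input", {
  st <- data.frame(snp_id = c("rs12938514", "rsA", "rsB"),
                   maf = c(0.3, 0.3, 0.3), r2 = c(2e-4, 7e-4, 5e-3),
                   f = c(3.71, 12.18, 88.43))
  fw <- filter_weak_instruments(st, 10)
  expect_equal(fw$removed$snp_id, "rs12938514")
  expect_setequal(fw$kept$snp_id, c("rsA", "rsB"))
  expect_equal(nrow(fw$kept) + nrow(fw$removed), nrow(st))
  expect_length(intersect(fw$kept$snp_id, fw$removed$snp_id), 0)

  all_strong <- st[st$f > 10, ]
  expect_equal(nrow(filter_weak_instruments(all_strong, 10)$removed), 0)

  # missing-F policy: permissive keeps (with a warning), strict removes
  st$f[2] <- NA
  expect_warning(fw_p <- filter_weak_instruments(st, 10), "permissive")
  expect_true("rsA" %in% fw_p$kept$snp_id)
  fw_s <- filter_weak_instruments(st, 10, missing_policy = "strict")
  expect_true("rsA" %in% fw_s$removed$snp_id)
})

test_that("leave-one-out rows match independent subset recomputation", {
  tr <- simulation_truth(theta = 0.15, k_true = 8, n_decoy = 0, seed = 71)
  res <- sim_harmonized(tr)
  h <- res$h
  loo <- leave_one_out(h)
  k <- nrow(h$instruments)
  expect_equal(nrow(loo), k)
  expect_true(all(loo$n_snp == k - 1))

  for (j in seq_len(k)) {
    ins <- h$instruments[-j, ]
    sub <- harmonized_set(ins$beta_exp, ins$se_exp, ins$beta_out, ins$se_out,
                          snp_id = ins$snp_id)
    est <- mr_ivw(sub)
    expect_equal(loo$beta[j], est$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], est$se, tolerance = 1e-12)
  }
})

test_that("identical-ratio instruments yield no influential leave-one-out rows", {
  bx <- c(0.2, 0.3, 0.4)
  h <- harmonized_set(beta_exp = bx, se_exp = rep(0.01, 3),
                      beta_out = 0.5 * bx, se_out = rep(0.05, 3))
  loo <- leave_one_out(h)
  full <- mr_ivw(h)
  expect_true(all(abs(loo$beta - full$beta) < 1e-12))
  expect_false(any(loo$influential))
  expect_error(leave_one_out(harmonized_set(c(1, 1), c(1, 1), c(1, 1),
                                            c(1, 1))), ">= 3")
})

test_that("random-effects SE exceeds the fixed SE exactly when Q exceeds its df", {
  for (seed in 81:85) {
    tr <- simulation_truth(theta = 0.1, k_true = 8, n_decoy = 0,
                           het_sd = 0.02, seed = seed)
    res <- sim_harmonized(tr)
    est <- mr_ivw(res$h)
    qr <- cochran_q(res$h)
    expect_gte(est$se_random, est$se_fixed)
    expect_equal(est$se_random > est$se_fixed, qr$q > qr$df)
  }
})
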