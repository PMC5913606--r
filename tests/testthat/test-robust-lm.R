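make_panel <- function(n_ind = 10, ages = c(10, 12, 14, 16, 18), seed = 1) {
  set.seed(seed)
  n <- n_ind * length(ages)
  samples <- data.frame(
    observation_id = sprintf("o%03d", seq_len(n)),
    individual_id = rep(sprintf("i%02d", seq_len(n_ind)), each = length(ages)),
    age = rep(ages, n_ind),
    exposure = rep(rep(c(0, 1), length.out = n_ind), each = length(ages)),
    stringsAsFactors = FALSE
  )
  samples
}

test_that("build_design produces the canonical columns with centred age", {
  s <- make_panel(n_ind = 2)
  beta <- matrix(runif(10), 1, 10, dimnames = list("cg1", s$observation_id))
  d <- longitudinal_dataset(beta, s)
  des <- build_design(d)
  expect_equal(dim(des$X), c(10, 4))
  expect_identical(colnames(des$X),
                   c("(Intercept)", "exposure", "age", "exposure:age"))
  expect_equal(des$age_origin, 10)
  expect_equal(range(des$X[, "age"]), c(0, 8))
  expect_equal(des$X[, "exposure:age"], des$X[, "exposure"] * des$X[, "age"],
               ignore_attr = TRUE)
  expect_equal(des$clusters$m, 2)

  # constant exposure -> rank deficiency naming the exposure column
  s1 <- s; s1$exposure <- 1
  d1 <- longitudinal_dataset(beta, s1)
  expect_error(build_design(d1), "exposure")

  # covariate duplicating the intercept
  s2 <- s; s2$dup <- 1
  d2 <- longitudinal_dataset(beta, s2)
  expect_error(build_design(d2, analysis_config(covariates = "dup")), "dup")
})

test_that("batch OLS matches exact fits, means and the normal-equations oracle", {
  s <- make_panel(n_ind = 4, seed = 2)
  d <- longitudinal_dataset(
    matrix(runif(20), 1, 20, dimnames = list("cg1", s$observation_id)), s)
  X <- build_design(d)$X

  # y equal to a design column: that coefficient 1, rest 0, residuals 0
  fit <- fit_ols_batch(X[, "age"], X)
  expect_equal(as.numeric(fit$coefficients), c(0, 0, 1, 0), tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)

  # intercept-only design: coefficient is the mean
  set.seed(3)
  y <- rnorm(20)
  fit0 <- fit_ols_batch(y, X[, 1, drop = FALSE])
  expect_equal(as.numeric(fit0$coefficients), mean(y), tolerance = 1e-12)

  # random outcomes vs an independent normal-equations solve
  set.seed(4)
  Y <- matrix(rnorm(20 * 8), 20, 8)
  fitb <- fit_ols_batch(Y, X)
  for (c_idx in 1:8) {
    b_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y[, c_idx]
    expect_equal(as.numeric(fitb$coefficients[, c_idx]),
                 as.numeric(b_oracle), tolerance = 1e-10)
  }

  # batch equals one-at-a-time fitting
  for (c_idx in c(1, 5)) {
    single <- fit_ols_batch(Y[, c_idx], X)
    expect_equal(fitb$coefficients[, c_idx],
                 single$coefficients[, 1], tolerance = 1e-12)
  }
})

test_that("sandwich variance matches a literal per-cluster double loop", {
  # fixed 5 clusters x 3 observations instance
  inst <- random_instance(m = 5, n_per = 3, p = 3, seed = 10)
  fit <- fit_ols_batch(inst$y, inst$X)
  ci <- cluster_index(inst$cluster)
  vr <- cluster_robust_variance(inst$X, fit$residuals, ci)
  V_oracle <- oracle_cluster_sandwich(inst$X, fit$residuals[, 1], inst$cluster)
  expect_lt(max(abs(vr$V[, , 1] - V_oracle)), 1e-12)

  # CR1 correction multiplies the meat by m/(m-1)
  vr1 <- cluster_robust_variance(inst$X, fit$residuals, ci, correction = TRUE)
  expect_equal(vr1$V[, , 1], vr$V[, , 1] * 5 / 4, tolerance = 1e-12)

  # all residuals zero -> zero matrix
  vr0 <- cluster_robust_variance(inst$X, matrix(0, 15, 1), ci)
  expect_equal(max(abs(vr0$V)), 0)

  # V is symmetric PSD
  ev <- eigen(vr$V[, , 1], symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-14))
})

test_that("singleton clusters reproduce the HC0 sandwich", {
  set.seed(11)
  n <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rnorm(n)
  fit <- fit_ols_batch(y, X)
  ci <- cluster_index(as.character(seq_len(n)))
  vr <- cluster_robust_variance(X, fit$residuals, ci)
  expect_lt(max(abs(vr$V[, , 1] - oracle_hc0(X, fit$residuals[, 1]))), 1e-12)
  # and against the established implementation
  df <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  lmfit <- stats::lm(y ~ x1 + x2, data = df)
  V_pkg <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_lt(max(abs(vr$V[, , 1] - V_pkg)), 1e-10)
})

test_that("sandwich agrees with vcovCL on clustered panels", {
  s <- make_panel(n_ind = 12, seed = 12)
  set.seed(13)
  beta <- matrix(runif(3 * nrow(s)), 3, nrow(s),
                 dimnames = list(paste0("cg", 1:3), s$observation_id))
  d <- longitudinal_dataset(beta, s)
  fr <- fit_robust(d)
  s$age_c <- s$age - 10
  for (k in 1:3) {
    s$y <- beta[k, ]
    lmfit <- stats::lm(y ~ exposure * age_c, data = s)
    V_pkg <- sandwich::vcovCL(lmfit, cluster = s$individual_id,
                              type = "HC0", cadjust = FALSE)
    expect_lt(max(abs(fr$V[, , k] - V_pkg)), 1e-12)
  }
})

test_that("wald_test matches normal and t reference quantiles", {
  w <- wald_test(0, 1)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  w <- wald_test(1.959964, 1)
  expect_equal(w$p_value, 0.05, tolerance = 1e-5)

  w <- wald_test(2.228, 1, df_method = "t_clusters_minus_p", df = 10)
  expect_equal(w$p_value, 0.05, tolerance = 1e-3)

  # degenerate SEs
  expect_warning(w <- wald_test(c(0.5, 0), c(0, 0)), "zero standard error")
  expect_equal(w$p_value, c(0, 1))
})

test_that("estimates and inference are invariant to observation permutation", {
  sim <- simulate_dataset(small_sim_config(n_individuals = 30, n_cpgs = 5), 1)
  d <- sim$dataset
  fr <- fit_robust(d)
  set.seed(20)
  perm <- sample(d$n_obs)
  d2 <- longitudinal_dataset(d$beta[, perm], d$samples[perm, ])
  fr2 <- fit_robust(d2)
  expect_equal(fr2$coefficients, fr$coefficients, tolerance = 1e-12)
  expect_equal(fr2$se, fr$se, tolerance = 1e-12)
  expect_equal(fr2$p_value, fr$p_value, tolerance = 1e-12)
})

test_that("rescaling the outcome rescales estimates and SEs, not p-values", {
  sim <- simulate_dataset(small_sim_config(n_individuals = 30, n_cpgs = 3), 2)
  d <- sim$dataset
  fr <- fit_robust(d)
  d2 <- d
  d2$beta <- d$beta * 7
  fr2 <- fit_robust(d2)
  expect_equal(fr2$coefficients, fr$coefficients * 7, tolerance = 1e-10)
  expect_equal(fr2$se, fr$se * 7, tolerance = 1e-10)
  expect_equal(fr2$p_value, fr$p_value, tolerance = 1e-10)
})

test_that("missing cells fall back to per-CpG complete-case fits", {
  s <- make_panel(n_ind = 20, seed = 30)
  set.seed(31)
  beta <- matrix(runif(2 * nrow(s)), 2, nrow(s),
                 dimnames = list(c("cgFull", "cgMiss"), s$observation_id))
  beta["cgMiss", c(3, 17, 40, 77)] <- NA
  d <- longitudinal_dataset(beta, s)
  fr <- fit_robust(d)
  expect_equal(fr$n_used, c(100L, 96L), ignore_attr = TRUE)

  # the incomplete CpG must equal a direct fit on its complete rows
  keep <- which(!is.na(beta["cgMiss", ]))
  s_sub <- s[keep, ]
  s_sub$y <- beta["cgMiss", keep]
  s_sub$age_c <- s_sub$age - 10
  lmfit <- stats::lm(y ~ exposure * age_c, data = s_sub)
  expect_equal(as.numeric(fr$coefficients["cgMiss", ]),
               as.numeric(stats::coef(lmfit)), tolerance = 1e-10)
  V_pkg <- sandwich::vcovCL(lmfit, cluster = s_sub$individual_id,
                            type = "HC0", cadjust = FALSE)
  expect_lt(max(abs(fr$V[, , "cgMiss"] - V_pkg)), 1e-12)

  # a CpG with fewer usable rows than parameters is flagged, not fatal
  beta2 <- beta
  beta2["cgMiss", -(1:3)] <- NA
  d2 <- longitudinal_dataset(beta2, s)
  fr2 <- fit_robust(d2)
  expect_false(fr2$ok[2])
  expect_true(fr2$ok[1])
})

test_that("Type I error is calibrated on independent errors with singleton clusters", {
  # 2000 null outcomes, n = 200 independent observations, alpha = 0.05
  set.seed(40)
  n <- 200
  n_cpg <- 2000
  s <- data.frame(
    observation_id = sprintf("o%03d", 1:n),
    individual_id = sprintf("i%03d", 1:n), # singletons
    age = rep(c(10, 12, 14, 16, 18), length.out = n),
    exposure = rep(c(0, 1), each = n / 2)
  )
  beta <- matrix(rnorm(n_cpg * n), n_cpg, n,
                 dimnames = list(sprintf("cg%04d", 1:n_cpg), s$observation_id))
  d <- longitudinal_dataset(beta, s)
  fr <- fit_robust(d)
  rej <- mean(fr$p_value[, "exposure"] < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / n_cpg)
  expect_lt(abs(rej - 0.05), 3 * mc_sd)
})
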