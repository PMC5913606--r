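sim_one_cpg <- function(n_ind, effects, sd_u0, sd_u1, cor_u, sigma_e, seed,
                        ages = c(10, 12, 14, 16, 18)) {
  set.seed(seed)
  ind <- data.frame(individual_id = sprintf("i%04d", seq_len(n_ind)),
                    exposure = rep(c(0, 1), length.out = n_ind))
  attr(ind, "ages") <- ages
  obs <- longewas:::expand_observations(ind)
  Sigma_u <- matrix(c(sd_u0^2, cor_u * sd_u0 * sd_u1,
                      cor_u * sd_u0 * sd_u1, sd_u1^2), 2, 2)
  obs$y <- simulate_cpg(obs, effects, Sigma_u, sigma_e, age_origin = 10)
  obs
}

eff <- list(beta00 = 0.4, beta01 = 0.02, beta10 = 0.002, beta11 = 0.004)

test_that("with no random effects the LMM collapses to OLS", {
  obs <- sim_one_cpg(80, eff, sd_u0 = 0, sd_u1 = 0, cor_u = 0,
                     sigma_e = 0.03, seed = 1)
  f <- fit_lmm(obs$y, obs, random = "intercept_slope")
  expect_true(f$status %in% c("converged", "boundary"))
  obs$age_c <- obs$age - 10
  ols <- stats::lm(y ~ exposure * age_c, data = obs)
  expect_equal(as.numeric(f$coefficients), as.numeric(stats::coef(ols)),
               tolerance = 1e-6)
  # residual variance absorbed entirely by sigma_e^2
  expect_equal(f$sigma2_e + sum(diag(f$Sigma_u)),
               summary(ols)$sigma^2, tolerance = 0.05)
})

test_that("balanced complete design: GLS fixed effects equal OLS", {
  obs <- sim_one_cpg(100, eff, sd_u0 = 0.025, sd_u1 = 0.007, cor_u = -0.2,
                     sigma_e = 0.0325, seed = 2)
  f <- fit_lmm(obs$y, obs, random = "intercept_slope")
  obs$age_c <- obs$age - 10
  ols <- stats::lm(y ~ exposure * age_c, data = obs)
  expect_equal(as.numeric(f$coefficients), as.numeric(stats::coef(ols)),
               tolerance = 1e-8)
})

test_that("fixed effects are recovered without bias across replicates", {
  reps <- 60
  errs <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    obs <- sim_one_cpg(150, eff, sd_u0 = 0.025, sd_u1 = 0.007, cor_u = -0.2,
                       sigma_e = 0.0325, seed = 100 + r)
    f <- fit_lmm(obs$y, obs, random = "intercept_slope")
    errs[r, ] <- as.numeric(f$coefficients) -
      c(eff$beta00, eff$beta01, eff$beta10, eff$beta11)
  }
  mc_se <- apply(errs, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(colMeans(errs)) <= 3 * mc_se))
})

test_that("Wald inference shares the normal reference with the robust fit", {
  obs <- sim_one_cpg(60, eff, 0.025, 0.007, -0.2, 0.0325, seed = 3)
  f <- lmm_wald(fit_lmm(obs$y, obs))
  w <- wald_test(f$coefficients, f$se)
  expect_equal(f$p_value, w$p_value)
  expect_true(all(f$p_value >= 0 & f$p_value <= 1))
})

test_that("batch fitting isolates failures and is deterministic", {
  sim <- simulate_dataset(small_sim_config(n_individuals = 40, n_cpgs = 5), 1)
  d <- sim$dataset
  d$beta[2, ] <- 0.5                 # constant methylation: unfittable
  d$beta[4, ] <- d$beta[1, ]         # duplicate of CpG 1
  b <- fit_lmm_batch(d, random = "intercept_slope")
  expect_equal(b$fits[[2]]$status, "failed")
  expect_equal(b$n_failed, 1L)
  # identical outcomes give identical fits
  expect_equal(b$fits[[1]]$coefficients, b$fits[[4]]$coefficients)
  expect_equal(b$fits[[1]]$Sigma_u, b$fits[[4]]$Sigma_u)
  # batch equals one-at-a-time
  single <- lmm_wald(fit_lmm(d$beta[3, ], d$samples))
  expect_equal(b$fits[[3]]$coefficients, single$coefficients, tolerance = 1e-8)
  expect_equal(b$fits[[3]]$p_value, single$p_value, tolerance = 1e-8)
  # failed CpGs carry no p-values and are excluded from hit selection
  rt <- as_result_table(b)
  expect_true(all(is.na(rt$p_value[rt$cpg_id == d$cpg_ids[2]])))
  h <- select_hits(rt, "lmm_intercept_slope",
                   analysis_config(significance_threshold = 0.05))
  expect_equal(h$n_excluded, 1L)
})

test_that("adding a design translation shifts fixed effects, not components", {
  obs <- sim_one_cpg(80, eff, 0.025, 0.007, -0.2, 0.0325, seed = 5)
  f1 <- fit_lmm(obs$y, obs)
  shift <- c(0.1, -0.05, 0.01, 0.002)
  X <- cbind(1, obs$exposure, obs$age - 10, obs$exposure * (obs$age - 10))
  f2 <- fit_lmm(obs$y + as.numeric(X %*% shift), obs)
  expect_equal(as.numeric(f2$coefficients - f1$coefficients), shift,
               tolerance = 1e-6)
  expect_equal(f2$Sigma_u, f1$Sigma_u, tolerance = 1e-6)
  expect_equal(f2$sigma2_e, f1$sigma2_e, tolerance = 1e-8)
})

test_that("ignoring a real random slope inflates the interaction Type I error", {
  # null-exposure CpGs generated WITH between-individual slope variance
  n_null <- 150
  null_eff <- list(beta00 = 0.5, beta01 = 0, beta10 = 0.002, beta11 = 0)
  p_int <- p_is <- numeric(n_null)
  for (k in seq_len(n_null)) {
    obs <- sim_one_cpg(100, null_eff, 0.025, 0.007, -0.2, 0.0325,
                       seed = 2000 + k)
    f0 <- lmm_wald(fit_lmm(obs$y, obs, random = "intercept"))
    f1 <- lmm_wald(fit_lmm(obs$y, obs, random = "intercept_slope"))
    p_int[k] <- f0$p_value["exposure:age"]
    p_is[k] <- f1$p_value["exposure:age"]
  }
  t1_int <- mean(p_int < 0.05)
  t1_is <- mean(p_is < 0.05)
  expect_gt(t1_int, t1_is)      # misspecification inflates Type I error
  expect_gt(t1_int, 0.10)       # materially above nominal
  expect_lt(abs(t1_is - 0.05), 3 * sqrt(0.05 * 0.95 / n_null) + 0.02)
})
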