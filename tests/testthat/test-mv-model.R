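test_that("hurdle-lognormal log-density matches closed forms and quadrature", {
  expect_equal(hurdle_lognormal_logdensity(0, 0.3, 0, 1), log(0.3))
  expect_equal(hurdle_lognormal_logdensity(1, 0, 0, 1), -log(sqrt(2 * pi)))
  # independent density oracle: normal density of log(y) with Jacobian
  ref <- log(1 - 0.2) + dnorm(log(0.5), -1, 0.5, log = TRUE) - log(0.5)
  expect_equal(hurdle_lognormal_logdensity(0.5, 0.2, -1, 0.5), ref,
               tolerance = 1e-12)
  # the positive part integrates to 1 - hu (validated by quadrature)
  dens <- function(y) exp(hurdle_lognormal_logdensity(y, 0.2, -1, 0.5))
  expect_equal(integrate(dens, 0, Inf, rel.tol = 1e-10)$value, 0.8,
               tolerance = 1e-7)
  expect_error(hurdle_lognormal_logdensity(-1, 0.2, 0, 1), "nonnegative")
  expect_error(hurdle_lognormal_logdensity(1, 1.2, 0, 1), "hu")
  expect_error(hurdle_lognormal_logdensity(1, 0.2, 0, -1), "sigma")
})

test_that("Bernoulli log-density handles boundaries", {
  expect_equal(bernoulli_logdensity(1, 0.5), log(0.5))
  expect_equal(bernoulli_logdensity(0, 0), 0)
  expect_equal(bernoulli_logdensity(1, 0), -Inf)
  expect_error(bernoulli_logdensity(2, 0.5), "0 or 1")
  expect_error(bernoulli_logdensity(1, 1.5), "\\[0, 1\\]")
})

test_that("joint log-likelihood matches a brute-force per-row reference", {
  dat <- small_recovery_data(n_ego = 6, n_alter = 12, alters_per_ego = 6,
                             seed = 31)
  tab <- dat$table
  X <- multiego:::build_design(tab, model_spec())
  set.seed(32)
  for (rep in 1:3) {
    params <- list(
      beta = matrix(rnorm(ncol(X) * 7, 0, 0.5), ncol(X), 7,
                    dimnames = list(colnames(X), NULL)),
      u = matrix(rnorm(6 * 7, 0, 0.3), 6, 7,
                 dimnames = list(levels(factor(tab$ego_id)), NULL)),
      v = matrix(rnorm(12 * 7, 0, 0.3), 12, 7,
                 dimnames = list(levels(factor(tab$alter_id)), NULL)),
      sigma_contact = 0.7, sigma_proximity = 0.4)
    expect_equal(joint_log_likelihood(tab, params),
                 reference_loglik(tab, params), tolerance = 1e-10)
  }
})

test_that("zero coefficients give the closed-form count log-likelihood", {
  # all etas 0: every Bernoulli/hurdle probability is 1/2; positive values
  # contribute the lognormal density
  tab <- data.frame(
    ego_id = "E1", alter_id = c("A1", "A2", "A3", "A4"),
    partition_index = 2L,
    lag_aggression = 0, lag_contact = 0, lag_groom = 0, lag_play = 0,
    lag_proximity = 0, ego_cohort = c("2016", "2016", "2017", "2017"),
    ego_sex = c("F", "M", "F", "M"), ego_maternal_rank = 0, rank_diff = 0,
    age_diff_years = 0, same_sex = c(TRUE, TRUE, FALSE, FALSE),
    kinship = c("unrelated", "sibling", "unrelated", "comatriline"),
    alter_born_flag = c(TRUE, FALSE, TRUE, FALSE),
    alter_removed_flag = c(FALSE, TRUE, FALSE, TRUE),
    partition_linear = 0,
    aggr_bin = c(0, 1, 0, 1), groom_bin = c(1, 1, 0, 0),
    play_bin = c(0, 0, 1, 1),
    contact_vers = c(0, 0.5, 0, 2), proximity_vers = c(1, 0, 1, 0),
    stringsAsFactors = FALSE)
  X <- multiego:::build_design(tab, model_spec())
  params <- list(
    beta = matrix(0, ncol(X), 7, dimnames = list(colnames(X), NULL)),
    u = matrix(0, 1, 7, dimnames = list("E1", NULL)),
    v = matrix(0, 4, 7, dimnames = list(c("A1", "A2", "A3", "A4"), NULL)),
    sigma_contact = 1, sigma_proximity = 1)
  # 12 Bernoulli terms + 8 hurdle indicators, all log(1/2), plus the
  # lognormal densities of the positive values at mu = 0, sigma = 1
  expected <- 20 * log(0.5) +
    sum(dlnorm(c(0.5, 2), 0, 1, log = TRUE)) +
    sum(dlnorm(c(1, 1), 0, 1, log = TRUE))
  expect_equal(joint_log_likelihood(tab, params), expected,
               tolerance = 1e-12)
  # doubling the table doubles the log-likelihood
  tab2 <- rbind(tab, tab)
  expect_equal(joint_log_likelihood(tab2, params),
               2 * joint_log_likelihood(tab, params), tolerance = 1e-10)
  # perturbing one ego RE changes only that ego's rows (here: all rows)
  params2 <- params
  params2$u["E1", 1] <- 1
  expect_false(joint_log_likelihood(tab, params2) ==
                 joint_log_likelihood(tab, params))
})

test_that("MCMC configuration arithmetic matches the draw count", {
  expect_equal(n_postwarmup_draws(mcmc_config(4, 6000, 2000, 2)), 8000)
  expect_equal(n_postwarmup_draws(mcmc_config(2, 1500, 500, 1)), 2000)
  expect_error(mcmc_config(4, 2000, 2000, 2), "iterations")
  expect_error(mcmc_config(4, 6000, 2000, 7))
})

test_that("simulate_from_model respects degenerate hurdles and seeds", {
  skel <- model_table_skeleton(n_ego = 8, n_alter = 20, alters_per_ego = 8,
                               seed = 41)
  X <- multiego:::build_design(skel, model_spec())
  truth <- random_truth(colnames(X), seed = 42)
  # hu = 1 everywhere: all contact responses are structural zeros
  t2 <- truth
  t2$beta[, "contact_hu"] <- 0
  t2$beta["(Intercept)", "contact_hu"] <- 50
  t2$sd_u <- rep(1e-8, 7); t2$sd_v <- rep(1e-8, 7)
  sim <- simulate_from_model(skel, t2, seed = 43)
  expect_true(all(sim$contact_vers == 0))
  # fixed seed reproducibility
  s1 <- simulate_from_model(skel, truth, seed = 7)
  s2 <- simulate_from_model(skel, truth, seed = 7)
  expect_identical(s1, s2)
  # truth keys must match the design
  bad <- truth
  rownames(bad$beta)[2] <- "nonexistent"
  expect_error(simulate_from_model(skel, bad, seed = 1), "do not match")
})

test_that("realized ego REs reproduce the target cross-correlation", {
  skel <- model_table_skeleton(n_ego = 200, n_alter = 50,
                               alters_per_ego = 2, seed = 51)
  X <- multiego:::build_design(skel, model_spec())
  truth <- random_truth(colnames(X), seed = 52)
  sim <- simulate_from_model(skel, truth, seed = 53)
  u <- attr(sim, "u")
  expect_equal(cor(u[, 1], u[, 2]), 0.7, tolerance = 0.1)
  expect_equal(unname(apply(u, 2, sd)), rep(0.5, 7), tolerance = 0.15)
})

test_that("the sampler is deterministic given seed and configuration", {
  dat <- small_recovery_data(n_ego = 8, n_alter = 20, alters_per_ego = 8,
                             seed = 61)
  mc <- mcmc_config(2, 200, 100, 2, seed = 5)
  f1 <- suppressWarnings(fit_social_model(dat$table, mcmc = mc))
  f2 <- suppressWarnings(fit_social_model(dat$table, mcmc = mc))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$Sigma_u, f2$Sigma_u)
  expect_equal(f1$n_draws, 100)
})

test_that("a planted strong effect is recovered with the right sign and size", {
  skel <- model_table_skeleton(n_ego = 25, n_alter = 75,
                               alters_per_ego = 25, seed = 71)
  X <- multiego:::build_design(skel, model_spec())
  truth <- random_truth(colnames(X), seed = 72, beta_range = c(-0.5, 0.5),
                        re_sd = 0.3)
  truth$beta["lag_proximity", ] <- 1.5
  tab <- simulate_from_model(skel, truth, seed = 73)
  fit <- suppressWarnings(
    fit_social_model(tab, mcmc = mcmc_config(2, 700, 200, 1, seed = 4)))
  for (c in c("aggression", "groom", "play")) {
    dr <- fit$beta[, "lag_proximity", c]
    expect_gt(quantile(dr, 0.025), 0)
    expect_equal(mean(dr), 1.5, tolerance = 0.45)
  }
  # hurdle components are reverse-coded in the report
  fe <- fixed_effect_report(fit)
  raw <- mean(fit$beta[, "lag_proximity", "contact_hu"])
  rep_row <- fe[fe$response == "contact" & fe$component == "connectivity" &
                  fe$term == "lag_proximity", ]
  expect_equal(rep_row$estimate, -raw, tolerance = 1e-10)
  # Bernoulli rows are unchanged
  rep_b <- fe[fe$response == "play" & fe$term == "lag_proximity", ]
  expect_equal(rep_b$estimate, mean(fit$beta[, "lag_proximity", "play"]),
               tolerance = 1e-10)
})

test_that("posterior summaries behave: R2 modes, cross-correlations, diagnostics", {
  dat <- small_recovery_data(n_ego = 15, n_alter = 40, alters_per_ego = 15,
                             seed = 81, re_sd = 0.6)
  fit <- suppressWarnings(
    fit_social_model(dat$table, mcmc = mcmc_config(2, 500, 200, 1,
                                                   seed = 6)))
  r2c <- bayes_r2(fit, "conditional", n_draws_use = 100)
  r2m <- bayes_r2(fit, "marginal", n_draws_use = 100)
  expect_true(all(r2c$estimate >= 0 & r2c$estimate <= 1))
  expect_true(all(r2c$q2.5 <= r2c$estimate & r2c$estimate <= r2c$q97.5))
  # with substantial RE sds the REs add explanatory power on the
  # probability scale (for the hurdle responses the mixed response scale
  # does not guarantee the nesting: the random effects inflate the
  # lognormal residual variance exp-quadratically, so only sanity is
  # asserted there)
  bern <- r2c$response %in% c("aggression", "groom", "play")
  expect_true(all(r2c$estimate[bern] >= r2m$estimate[bern] - 0.02))

  cc <- re_cross_correlations(fit, "ego")
  expect_equal(nrow(cc), 21)
  expect_true(all(cc$mean >= -1 & cc$mean <= 1))
  expect_true(all(cc$q2.5 <= cc$q97.5))
  # correlation matrix summarised symmetrically: querying (i,j) finds the
  # same value regardless of order by construction (pairs are unordered)
  expect_false(any(duplicated(paste(pmin(cc$comp1, cc$comp2),
                                    pmax(cc$comp1, cc$comp2)))))

  d <- fit$diagnostics
  expect_equal(nrow(d), length(fit$predictor_names) * 7)
  expect_true(all(is.finite(d$rhat)))
  expect_true(all(d$ess_bulk > 0))
})

test_that("pure-noise responses give near-zero marginal R2", {
  skel <- model_table_skeleton(n_ego = 30, n_alter = 80,
                               alters_per_ego = 30, seed = 91)
  X <- multiego:::build_design(skel, model_spec())
  truth <- random_truth(colnames(X), seed = 92, beta_range = c(0, 0),
                        re_sd = 1e-6)
  truth$beta[] <- 0
  tab <- simulate_from_model(skel, truth, seed = 93)
  fit <- suppressWarnings(
    fit_social_model(tab, mcmc = mcmc_config(1, 500, 200, 1, seed = 8)))
  r2 <- bayes_r2(fit, "marginal", n_draws_use = 100)
  expect_true(all(r2$estimate < 0.05))
})
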