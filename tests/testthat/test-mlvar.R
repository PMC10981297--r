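test_that("fixed effects approach pooled OLS when random variances vanish", {
  fx <- ols_limit_fixture()
  v <- fx$params$variable_names
  xcols <- paste0("x_", v)
  rows <- fx$design$rows
  for (j in v) {
    ols <- lm(stats::reformulate(xcols, response = paste0("y_", j)),
              data = rows)
    ml <- fx$fit$fits[[j]]$fixed_coefs
    expect_true(all(abs(ml - coef(ols)[xcols]) < 0.03))
  }
  # and both recover the generative matrix reasonably at this scale
  net <- build_temporal_network(fx$fit)
  expect_lt(mean(abs(net$weights - fx$params$fixed_temporal)), 0.02)
})

test_that("estimation degenerate inputs error as specified", {
  params <- null_var_parameters(2)
  one <- simulate_esm_dataset(params, 1, 30, seed = 1, discretize = FALSE)
  d1 <- build_lagged_design(one, "listwise")
  expect_error(fit_node(d1, 1, fit_config()), "fewer than 2 persons")

  # persons under the row threshold are dropped with a warning
  two <- simulate_esm_dataset(params, 3, 30, seed = 2, discretize = FALSE)
  d2 <- build_lagged_design(two, "listwise")
  d2$rows <- d2$rows[-(1:25), ] # starve person 1
  expect_warning(f <- fit_node(d2, 1, fit_config(min_rows_per_person = 10)),
                 "Excluding 1 person")
  expect_identical(f$n_persons, 2L)
})

test_that("node-wise fits are deterministic and permutation-equivariant", {
  params <- null_var_parameters(3)
  ds <- simulate_esm_dataset(params, 20, 30, seed = 3, discretize = FALSE)
  design <- build_lagged_design(ds, "listwise")
  f1 <- fit_all_nodes(design, fit_config())
  f2 <- fit_all_nodes(design, fit_config())
  for (v in design$variable_names)
    expect_equal(f1$fits[[v]]$fixed_coefs, f2$fits[[v]]$fixed_coefs,
                 tolerance = 1e-8)

  perm <- c(3, 1, 2)
  ds_p <- ds
  ds_p$variable_names <- ds$variable_names[perm]
  f3 <- fit_all_nodes(build_lagged_design(ds_p, "listwise"), fit_config())
  n1 <- build_temporal_network(f1)
  n3 <- build_temporal_network(f3)
  # equivariant up to optimizer path differences after reordering
  expect_equal(n3$weights, n1$weights[perm, perm], tolerance = 1e-3)
})

test_that("fit output satisfies its structural invariants", {
  fx <- ols_limit_fixture()
  for (f in fx$fit$fits) {
    expect_true(all(f$p_values >= 0 & f$p_values <= 1))
    expect_true(all(f$random_sd >= 0))
    expect_identical(length(f$residuals), as.integer(f$n_rows))
  }
})

test_that("random-effect SD network recovers homogeneity and heterogeneity", {
  fx <- ols_limit_fixture()
  sd_net <- random_effects_sd_network(fx$fit)
  expect_true(all(sd_net >= 0))
  expect_true(all(sd_net < 0.05)) # generator had zero slope heterogeneity

  # one genuinely heterogeneous edge should dominate the estimates
  B <- diag(0.2, 3)
  S <- matrix(0, 3, 3); S[2, 1] <- 0.1
  params <- var_parameters(B, random_slope_sd = S,
                           random_mean_sd = rep(0.5, 3))
  hits <- 0
  for (r in 1:10) {
    ds <- simulate_esm_dataset(params, 200, 50, seed = 100 + r,
                               discretize = FALSE)
    fit <- fit_all_nodes(build_lagged_design(ds, "listwise"), fit_config())
    est <- random_effects_sd_network(fit)
    if (which.max(est) == 2L) hits <- hits + 1 # linear index of entry [2, 1]
  }
  expect_gte(hits, 9)
})

test_that("pairwise combination follows the sign-consistency rule", {
  expect_identical(esmnet:::combine_pcor(0.3, -0.2), 0)
  expect_identical(esmnet:::combine_pcor(0, 0.2), 0)
  expect_equal(esmnet:::combine_pcor(0.4, 0.1), sqrt(0.04))
  expect_equal(esmnet:::combine_pcor(-0.4, -0.1), -sqrt(0.04))
})

test_that("residual network matches the covariance-inversion oracle", {
  # known dependence structure on 4 nodes
  set.seed(201)
  n <- 5000
  Sigma <- matrix(c(1, .5, .2, 0,
                    .5, 1, .3, 0,
                    .2, .3, 1, .4,
                    0, 0, .4, 1), 4, 4)
  L <- t(chol(Sigma))
  R <- t(L %*% matrix(rnorm(4 * n), 4, n))
  colnames(R) <- paste0("V", 1:4)
  net <- residual_network(R, config = fit_config())
  K <- solve(cov(R))
  pcor_oracle <- -K / sqrt(diag(K) %o% diag(K))
  diag(pcor_oracle) <- 0
  expect_true(all(abs(net$weights - pcor_oracle) < 0.05))
  expect_true(all(abs(net$weights) <= 1))
  expect_true(all(diag(net$weights) == 0))
  expect_equal(net$weights, t(net$weights))
})

test_that("and-rule keeps the null retained-edge rate at or below alpha", {
  set.seed(202)
  n_reps <- 60
  retained <- 0; pairs <- 0
  for (r in 1:n_reps) {
    R <- matrix(rnorm(500 * 3), 500, 3)
    net <- residual_network(R, config = fit_config(alpha = 0.05))
    sig <- net$significant
    retained <- retained + sum(sig[upper.tri(sig)])
    pairs <- pairs + 3
  }
  rate <- retained / pairs
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / pairs))
})

test_that("contemporaneous network from fits checks residual alignment", {
  fx <- ols_limit_fixture()
  cn <- fit_contemporaneous(fx$fit, fit_config())
  expect_equal(cn$weights, t(cn$weights))
  expect_true(all(diag(cn$weights) == 0))
  expect_true(all(abs(cn$weights) <= 1))
  # generator had identity innovations: nothing should be strongly linked
  expect_true(all(abs(cn$weights) < 0.05))

  broken <- fx$fit
  broken$fits[[1]]$residuals <- broken$fits[[1]]$residuals[-1]
  broken$fits[[1]]$n_rows <- broken$fits[[1]]$n_rows - 1
  expect_error(fit_contemporaneous(broken, fit_config()), "misaligned")
})

test_that("unimplemented and invalid configurations are rejected", {
  expect_error(fit_config(alpha = 0), "alpha")
  expect_error(fit_config(pvalue_method = "satterthwaite"), "Satterthwaite")
})
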