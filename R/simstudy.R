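#' Null-world generator parameters for calibration studies
#'
#' A VAR(1) world with no cross-lagged structure: zero off-diagonal fixed
#' effects and zero SDs for their random slopes, autoregressive fixed
#' effects `auto` (with heterogeneity `auto_slope_sd`), person-mean SD
#' `mean_sd` and identity innovation covariance. Under this generator every
#' off-diagonal temporal edge is a true null, so the fraction of edges
#' passing the significance threshold estimates the per-edge false-positive
#' rate.
#'
#' @param p number of variables.
#' @param auto autoregressive fixed effect shared by all variables.
#' @param mean_sd person-mean SD.
#' @param auto_slope_sd random-slope SD of the autoregressive effects.
#' @return a [var_parameters()] object.
#' @export
null_var_parameters <- function(p = 3, auto = 0.15, mean_sd = 0.5,
                                auto_slope_sd = 0.05) {
  S <- matrix(0, p, p)
  diag(S) <- auto_slope_sd
  var_parameters(fixed_temporal = diag(auto, p),
                 fixed_means = rep(0, p),
                 random_slope_sd = S,
                 random_mean_sd = rep(mean_sd, p))
}

#' Per-edge false-positive rate of temporal edge selection
#'
#' Replicated null-world simulation: datasets are drawn from
#' [null_var_parameters()] (continuous scale), fit node-wise, and the
#' fraction of off-diagonal temporal p-values below `alpha` is recorded.
#' Under a correctly calibrated test this fraction approximates `alpha`.
#'
#' @param n_reps number of replications.
#' @param n_persons,n_days dataset dimensions per replication.
#' @param p number of variables.
#' @param alpha nominal level.
#' @param seed top-level seed; per-replication seeds derive from it.
#' @param params optional generator override (default
#'   `null_var_parameters(p)`).
#' @return a list with `rate` (observed false-positive fraction), `n_tests`
#'   (number of null edge tests), and `alpha`.
#' @export
edge_false_positive_rate <- function(n_reps = 100, n_persons = 50,
                                     n_days = 50, p = 3, alpha = 0.05,
                                     seed = 1, params = NULL) {
  if (is.null(params)) params <- null_var_parameters(p)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2^31 - 1, n_reps)
  cfg <- fit_config(alpha = alpha)
  hits <- 0L; total <- 0L
  for (r in seq_len(n_reps)) {
    ds <- simulate_esm_dataset(params, n_persons, n_days,
                               seed = rep_seeds[r], discretize = FALSE)
    design <- build_lagged_design(ds, "listwise")
    fit <- fit_all_nodes(design, cfg)
    net <- build_temporal_network(fit)
    pv <- net$p_values
    diag(pv) <- NA
    hits <- hits + sum(pv < alpha, na.rm = TRUE)
    total <- total + sum(!is.na(pv))
  }
  list(rate = hits / total, n_tests = total, alpha = alpha,
       n_reps = n_reps)
}

#' Fixed-effect recovery study at a given design scale
#'
#' Replicated simulation from `params` (continuous scale): each replication
#' is fit node-wise and compared with the generative fixed temporal matrix.
#' Reports the mean absolute error of the estimated fixed effects and the
#' empirical coverage of the nominal 95% Wald intervals, both pooled over
#' all p x p coefficients and replications.
#'
#' @param params a [var_parameters()] generator (default
#'   [default_gad_parameters()]).
#' @param n_reps number of replications.
#' @param n_persons,n_days dataset dimensions.
#' @param seed top-level seed.
#' @return a list with `mae`, `coverage`, `n_coefs` and the per-replication
#'   `mae_by_rep`.
#' @export
recovery_study <- function(params = default_gad_parameters(), n_reps = 5,
                           n_persons = 115, n_days = 50, seed = 1) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2^31 - 1, n_reps)
  cfg <- fit_config()
  truth <- params$fixed_temporal
  abs_err <- c(); covered <- c()
  mae_by_rep <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    ds <- simulate_esm_dataset(params, n_persons, n_days,
                               seed = rep_seeds[r], discretize = FALSE)
    design <- build_lagged_design(ds, "listwise")
    fit <- fit_all_nodes(design, cfg)
    net <- build_temporal_network(fit)
    se <- vapply(params$variable_names,
                 function(v) fit$fits[[v]]$std_errors[params$variable_names],
                 numeric(params$n_vars))
    err <- abs(net$weights - truth)
    abs_err <- c(abs_err, as.vector(err))
    covered <- c(covered, as.vector(err <= stats::qnorm(0.975) * se))
    mae_by_rep[r] <- mean(err)
  }
  list(mae = mean(abs_err), coverage = mean(covered),
       n_coefs = length(covered), mae_by_rep = mae_by_rep)
}
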