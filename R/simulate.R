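#' Simulate a daily-diary dataset from a person-heterogeneous VAR(1)
#'
#' Draws, for each person i, a mean vector `mu_i ~ N(fixed_means,
#' diag(random_mean_sd^2))` and a temporal matrix `B_i` whose entries deviate
#' independently from `fixed_temporal` with the standard deviations in
#' `random_slope_sd` (the generative mirror of orthogonal random effects).
#' The latent series then follows
#' `y_t = mu_i + B_i'(y_{t-1} - mu_i) + eps_t`, `eps_t ~ N(0,
#' innovation_cov)`, where `B[i, j]` is the effect of variable i at t-1 on
#' variable j at t. A burn-in of `burn_in` steps precedes the first retained
#' day so retained days start near the stationary distribution. Person
#' matrices with spectral radius >= 1 are redrawn (up to `max_redraws`
#' times) to keep every person's process stationary.
#'
#' @param params a [var_parameters()] object.
#' @param n_persons number of persons (study value 115).
#' @param n_days number of daily assessments per person (study value 50).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param discretize if `TRUE` (default) observations are rounded
#'   half-away-from-zero and clipped into `params$likert_bounds`, emulating
#'   the 1-7 rating scale; if `FALSE` the latent continuous values are kept.
#' @param burn_in number of pre-sample steps discarded per person.
#' @param attention_fail_rate probability that a day's attention check is
#'   failed (default 0; the generator does not model careless responding).
#' @param max_redraws retry cap for non-stationary person matrices.
#' @return an [esm_dataset()].
#' @export
simulate_esm_dataset <- function(params, n_persons, n_days, seed,
                                 discretize = TRUE, burn_in = 100,
                                 attention_fail_rate = 0,
                                 max_redraws = 1000) {
  validate_var_parameters(params)
  stopifnot(n_persons >= 1, n_days >= 2)
  set.seed(as.integer(seed))
  p <- params$n_vars
  L <- t(chol(params$innovation_cov))
  out <- vector("list", n_persons)
  for (i in seq_len(n_persons)) {
    mu_i <- params$fixed_means + stats::rnorm(p, 0, params$random_mean_sd)
    B_i <- draw_person_temporal(params, max_redraws)
    total <- burn_in + n_days
    eps <- L %*% matrix(stats::rnorm(p * total), p, total)
    y <- matrix(0, total, p)
    dev <- numeric(p) # start at the person mean
    tB <- t(B_i)
    for (t in seq_len(total)) {
      dev <- as.numeric(tB %*% dev) + eps[, t]
      y[t, ] <- mu_i + dev
    }
    y <- y[(burn_in + 1):total, , drop = FALSE]
    if (discretize)
      y <- apply(y, 2, discretize_likert, bounds = params$likert_bounds)
    df <- data.frame(person_id = sprintf("P%03d", i), day = seq_len(n_days))
    df[params$variable_names] <- as.data.frame(y)
    df$attention_pass <- stats::runif(n_days) >= attention_fail_rate
    out[[i]] <- df
  }
  esm_dataset(do.call(rbind, out), params$variable_names,
              likert_bounds = params$likert_bounds, discretized = discretize)
}

# Rejection sampling keeps each person's VAR stationary; the hierarchical
# draw can otherwise produce explosive matrices.
draw_person_temporal <- function(params, max_redraws) {
  p <- params$n_vars
  if (all(params$random_slope_sd == 0)) return(params$fixed_temporal)
  for (k in seq_len(max_redraws)) {
    B <- params$fixed_temporal +
      matrix(stats::rnorm(p * p, 0, as.vector(params$random_slope_sd)), p, p)
    if (spectral_radius(B) < 1) return(B)
  }
  stop("Could not draw a stationary person-level temporal matrix in ",
       max_redraws, " attempts; reduce `random_slope_sd`.", call. = FALSE)
}

#' Round continuous scores onto a bounded ordinal rating scale
#'
#' Values are rounded to the nearest integer (halves away from zero) and
#' clipped into the inclusive bounds; missing values stay missing.
#'
#' @param values numeric vector.
#' @param bounds inclusive integer range, low < high.
#' @return numeric vector of ordinal ratings.
#' @export
discretize_likert <- function(values, bounds = c(1L, 7L)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  r <- sign(values) * floor(abs(values) + 0.5)
  pmin(pmax(r, bounds[1]), bounds[2])
}

#' Delete observed cells completely at random
#'
#' Each non-missing symptom cell is independently set to missing with
#' probability `rate` (missing completely at random, at the cell level).
#' Person-day rows are never deleted and attention-check flags are untouched.
#'
#' @param dataset an [esm_dataset()].
#' @param rate missingness probability in `[0, 1]`.
#' @param seed integer seed for reproducibility.
#' @return an `esm_dataset` with additional missing cells.
#' @export
inject_missingness <- function(dataset, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1)
    stop("`rate` must be a single probability in [0, 1].", call. = FALSE)
  set.seed(as.integer(seed))
  d <- dataset$data
  for (v in dataset$variable_names) {
    obs <- which(!is.na(d[[v]]))
    if (length(obs))
      d[[v]][obs[stats::runif(length(obs)) < rate]] <- NA
  }
  dataset$data <- d
  dataset
}
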