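#' Ground-truth parameters for a person-heterogeneous VAR(1) generator
#'
#' Bundles the generative quantities of a multilevel lag-1 vector
#' autoregression: a population-mean temporal matrix, population means,
#' standard deviations of mutually independent ("orthogonal") person-level
#' deviations in means and temporal coefficients, and the innovation
#' covariance of the same-day shocks.
#'
#' The temporal matrix follows the edge convention used throughout the
#' package: entry `[i, j]` is the effect of variable `i` at day `t - 1` on
#' variable `j` at day `t`, so rows are predictors and columns are outcomes.
#'
#' @param fixed_temporal p x p numeric matrix of population-mean lag-1
#'   coefficients. Its spectral radius must be strictly below 1.
#' @param fixed_means length-p vector of population-mean person means, in
#'   rating-scale units.
#' @param random_slope_sd p x p matrix of standard deviations of
#'   person-specific deviations in the temporal coefficients; entries must be
#'   nonnegative. Defaults to all zero (no slope heterogeneity).
#' @param random_mean_sd length-p vector of standard deviations of
#'   person-specific means; defaults to all zero.
#' @param innovation_cov p x p symmetric positive-definite covariance of the
#'   same-day innovations; defaults to the identity.
#' @param likert_bounds inclusive integer observation range used when
#'   observations are discretized; default `c(1, 7)`.
#' @param variable_names optional length-p character vector of labels.
#'
#' @return An object of class `var_parameters`.
#' @seealso [default_gad_parameters()], [simulate_esm_dataset()]
#' @export
var_parameters <- function(fixed_temporal,
                           fixed_means = rep(0, nrow(fixed_temporal)),
                           random_slope_sd = NULL,
                           random_mean_sd = NULL,
                           innovation_cov = NULL,
                           likert_bounds = c(1L, 7L),
                           variable_names = NULL) {
  fixed_temporal <- as.matrix(fixed_temporal)
  p <- nrow(fixed_temporal)
  if (ncol(fixed_temporal) != p)
    stop("`fixed_temporal` must be square.", call. = FALSE)
  if (is.null(random_slope_sd)) random_slope_sd <- matrix(0, p, p)
  if (is.null(random_mean_sd)) random_mean_sd <- rep(0, p)
  if (is.null(innovation_cov)) innovation_cov <- diag(p)
  random_slope_sd <- as.matrix(random_slope_sd)
  innovation_cov <- as.matrix(innovation_cov)
  if (is.null(variable_names)) {
    variable_names <- if (!is.null(rownames(fixed_temporal)))
      rownames(fixed_temporal) else paste0("V", seq_len(p))
  }
  obj <- structure(
    list(
      n_vars = p,
      fixed_temporal = fixed_temporal,
      fixed_means = as.numeric(fixed_means),
      random_slope_sd = random_slope_sd,
      random_mean_sd = as.numeric(random_mean_sd),
      innovation_cov = innovation_cov,
      likert_bounds = as.integer(likert_bounds),
      variable_names = variable_names
    ),
    class = "var_parameters"
  )
  validate_var_parameters(obj)
  obj
}

#' Validate VAR generator parameters
#'
#' Checks the invariants of a [var_parameters()] object: square conformable
#' dimensions, spectral radius of the mean temporal matrix strictly below 1,
#' symmetric positive-definite innovation covariance, nonnegative
#' random-effect standard deviations, and an increasing integer rating range.
#'
#' @param params a `var_parameters` object.
#' @return `params`, invisibly; errors describe the violated invariant.
#' @export
validate_var_parameters <- function(params) {
  p <- params$n_vars
  stopifnot(is.matrix(params$fixed_temporal))
  if (length(params$fixed_means) != p)
    stop("`fixed_means` must have length ", p, ".", call. = FALSE)
  if (!all(dim(params$random_slope_sd) == c(p, p)))
    stop("`random_slope_sd` must be ", p, " x ", p, ".", call. = FALSE)
  if (length(params$random_mean_sd) != p)
    stop("`random_mean_sd` must have length ", p, ".", call. = FALSE)
  if (any(params$random_slope_sd < 0) || any(params$random_mean_sd < 0))
    stop("Random-effect standard deviations must be nonnegative.", call. = FALSE)
  sr <- spectral_radius(params$fixed_temporal)
  if (sr >= 1)
    stop("`fixed_temporal` is non-stationary: spectral radius ",
         format(sr, digits = 4), " >= 1.", call. = FALSE)
  S <- params$innovation_cov
  if (!all(dim(S) == c(p, p)) || max(abs(S - t(S))) > 1e-8)
    stop("`innovation_cov` must be a symmetric ", p, " x ", p, " matrix.",
         call. = FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("`innovation_cov` must be positive definite.", call. = FALSE)
  lb <- params$likert_bounds
  if (length(lb) != 2 || lb[1] >= lb[2])
    stop("`likert_bounds` must be an increasing pair of integers.", call. = FALSE)
  if (length(params$variable_names) != p)
    stop("`variable_names` must have length ", p, ".", call. = FALSE)
  invisible(params)
}

#' Spectral radius of a square matrix
#'
#' Largest modulus among the eigenvalues; a lag-1 VAR mean process is
#' stationary when the spectral radius of its coefficient matrix is below 1.
#'
#' @param m a square numeric matrix.
#' @return a nonnegative scalar.
#' @export
spectral_radius <- function(m) {
  max(Mod(eigen(as.matrix(m), only.values = TRUE)$values))
}

#' Symptom labels of the daily GAD diary protocol
#'
#' The eight DSM-5-based generalized anxiety disorder symptoms rated once a
#' day on a 1-7 scale in the study the defaults emulate.
#'
#' @return a character vector of length 8.
#' @export
gad_symptom_labels <- function() {
  c("excessive_worry", "uncontrollable_worry", "restlessness", "fatigue",
    "difficulty_concentrating", "irritability", "muscle_tension",
    "sleep_disturbance")
}

#' Default generator parameters emulating a GAD daily-diary study
#'
#' A stated-world parameterization of the eight-symptom daily diary design:
#' population means match the reported per-symptom means; the fixed temporal
#' matrix carries positive cross-lagged effects in the reported 0.04-0.33
#' range, dominated by outgoing edges of sleep disturbance, plus
#' autocorrelations up to 0.15; same-day innovations are correlated most
#' strongly between the two worry items. Person heterogeneity is modest:
#' mean SD 1.0, slope SD 0.05 on every temporal coefficient (mutually
#' independent, matching the orthogonal random-effect constraint of the
#' estimator).
#'
#' @return a [var_parameters()] object with `n_vars = 8`.
#' @export
default_gad_parameters <- function() {
  v <- gad_symptom_labels()
  p <- length(v)
  B <- matrix(0, p, p, dimnames = list(v, v))
  diag(B) <- c(0.15, 0.12, 0.11, 0.13, 0.11, 0.10, 0.10, 0.15)
  edge <- function(from, to, w) B[from, to] <<- w
  edge("excessive_worry", "uncontrollable_worry", 0.10)
  edge("uncontrollable_worry", "excessive_worry", 0.08)
  edge("uncontrollable_worry", "restlessness", 0.09)
  edge("restlessness", "fatigue", 0.06)
  edge("restlessness", "difficulty_concentrating", 0.04)
  edge("fatigue", "restlessness", 0.12)
  edge("fatigue", "difficulty_concentrating", 0.06)
  edge("fatigue", "muscle_tension", 0.05)
  edge("difficulty_concentrating", "uncontrollable_worry", 0.04)
  edge("difficulty_concentrating", "restlessness", 0.10)
  edge("difficulty_concentrating", "fatigue", 0.09)
  edge("muscle_tension", "fatigue", 0.04)
  edge("sleep_disturbance", "excessive_worry", 0.24)
  edge("sleep_disturbance", "uncontrollable_worry", 0.19)
  edge("sleep_disturbance", "restlessness", 0.09)
  edge("sleep_disturbance", "fatigue", 0.33)
  edge("sleep_disturbance", "difficulty_concentrating", 0.23)
  edge("sleep_disturbance", "irritability", 0.19)
  edge("sleep_disturbance", "muscle_tension", 0.14)

  R <- diag(p)
  dimnames(R) <- list(v, v)
  cor_edge <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  cor_edge("excessive_worry", "uncontrollable_worry", 0.50)
  cor_edge("excessive_worry", "restlessness", 0.30)
  cor_edge("uncontrollable_worry", "restlessness", 0.30)
  cor_edge("fatigue", "difficulty_concentrating", 0.30)
  cor_edge("irritability", "muscle_tension", 0.30)

  var_parameters(
    fixed_temporal = B,
    fixed_means = c(3.91, 3.67, 3.43, 4.02, 3.65, 3.03, 2.82, 3.73),
    random_slope_sd = matrix(0.05, p, p),
    random_mean_sd = rep(1.0, p),
    innovation_cov = R,
    likert_bounds = c(1L, 7L),
    variable_names = v
  )
}

#' @export
print.var_parameters <- function(x, ...) {
  cat("VAR(1) generator parameters:", x$n_vars, "variables\n")
  cat("  spectral radius of mean temporal matrix:",
      format(spectral_radius(x$fixed_temporal), digits = 3), "\n")
  cat("  cross-lagged edges (nonzero, off-diagonal):",
      sum(x$fixed_temporal != 0) - sum(diag(x$fixed_temporal) != 0), "\n")
  cat("  rating bounds: [", x$likert_bounds[1], ",", x$likert_bounds[2], "]\n")
  invisible(x)
}
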