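#' Configuration of the node-wise multilevel VAR estimator
#'
#' @param alpha significance level for edge selection (study value 0.05).
#' @param random_structure `"orthogonal"` (random intercept plus mutually
#'   uncorrelated random slopes for every lagged predictor — the constraint
#'   that makes the model estimable with many predictors) or
#'   `"intercept_only"`.
#' @param pvalue_method `"wald_normal"`: two-sided p-values from the normal
#'   reference for the Wald z = estimate / SE. With thousands of design rows
#'   the normal reference is adequate; Satterthwaite degrees of freedom are
#'   not implemented.
#' @param min_rows_per_person persons contributing fewer retained rows are
#'   excluded (with a warning) before fitting; near-empty persons
#'   destabilize the person-level effects.
#' @param estimator `"reml"` (default, standard for variance components) or
#'   `"ml"`.
#' @param contemporaneous `"pooled"` (default) or `"multilevel"` (random
#'   intercept) residual regressions for the contemporaneous network.
#' @param max_restarts refits with alternative optimizers after a
#'   convergence failure.
#' @return a `fit_config` list.
#' @export
fit_config <- function(alpha = 0.05,
                       random_structure = c("orthogonal", "intercept_only"),
                       pvalue_method = c("wald_normal", "satterthwaite"),
                       min_rows_per_person = 10,
                       estimator = c("reml", "ml"),
                       contemporaneous = c("pooled", "multilevel"),
                       max_restarts = 3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  pvalue_method <- match.arg(pvalue_method)
  if (pvalue_method == "satterthwaite")
    stop("Satterthwaite p-values are not implemented; use \"wald_normal\".",
         call. = FALSE)
  structure(list(alpha = alpha,
                 random_structure = match.arg(random_structure),
                 pvalue_method = pvalue_method,
                 min_rows_per_person = min_rows_per_person,
                 estimator = match.arg(estimator),
                 contemporaneous = match.arg(contemporaneous),
                 max_restarts = max_restarts),
            class = "fit_config")
}

# Drop persons with too few rows; shared by all node fits so rows stay
# aligned across nodes.
prune_design_rows <- function(design, config) {
  rows <- design$rows
  counts <- table(rows$person_id)
  small <- names(counts)[counts < config$min_rows_per_person]
  if (length(small)) {
    warning("Excluding ", length(small), " person(s) with fewer than ",
            config$min_rows_per_person, " design rows.", call. = FALSE)
    rows <- rows[!rows$person_id %in% small, , drop = FALSE]
  }
  rows
}

#' Fit one node of the multilevel lag-1 VAR
#'
#' Regresses variable `target` at day t on all p within-person-centered
#' lagged predictors (day t-1) with a person-level random intercept and,
#' under the orthogonal structure, mutually uncorrelated random slopes —
#' one independent variance component per incoming edge. Estimation uses
#' `lme4::lmer`; boundary (zero) variance estimates are permitted.
#'
#' @param design a centered `lagged_design` ([within_person_center()] is
#'   applied automatically if needed).
#' @param target variable name or index of the outcome node.
#' @param config a [fit_config()].
#' @return a `nodewise_fit`: fixed effects (`fixed_coefs`, named by
#'   predictor, self-lag = autocorrelation), `intercept`, `std_errors`,
#'   `p_values`, `random_sd` (intercept + each slope; intercept-only models
#'   report zero slope SDs), conditional `residuals` aligned with the
#'   retained rows, and `n_rows` / `n_persons`.
#' @export
fit_node <- function(design, target, config = fit_config()) {
  stopifnot(inherits(design, "lagged_design"))
  design <- within_person_center(design)
  v <- design$variable_names
  if (is.numeric(target)) target <- v[target]
  stopifnot(target %in% v)
  rows <- prune_design_rows(design, config)
  if (nrow(rows) == 0)
    stop("No design rows available for node '", target, "'.", call. = FALSE)
  if (length(unique(rows$person_id)) < 2)
    stop("Multilevel model inestimable: fewer than 2 persons.", call. = FALSE)

  xcols <- paste0("x_", v)
  dat <- rows[c("person_id", xcols)]
  dat$.y <- rows[[paste0("y_", target)]]
  dat$person_id <- factor(dat$person_id)
  re <- if (config$random_structure == "orthogonal")
    paste(c("(1 | person_id)",
            sprintf("(0 + %s | person_id)", xcols)), collapse = " + ")
  else "(1 | person_id)"
  form <- stats::as.formula(
    paste(".y ~", paste(xcols, collapse = " + "), "+", re))

  fit <- fit_lmer_robust(form, dat, reml = config$estimator == "reml",
                         max_restarts = config$max_restarts)

  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf / se
  pv <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  rsd <- stats::setNames(numeric(length(v) + 1), c("(Intercept)", v))
  for (term in vc) {
    nm <- rownames(term)[1]
    sd_ <- attr(term, "stddev")[1]
    if (nm == "(Intercept)") rsd["(Intercept)"] <- sd_
    else rsd[sub("^x_", "", nm)] <- sd_
  }
  structure(list(
    target = target,
    variable_names = v,
    fixed_coefs = stats::setNames(as.numeric(cf[xcols]), v),
    intercept = as.numeric(cf["(Intercept)"]),
    std_errors = stats::setNames(as.numeric(se[xcols]), v),
    intercept_se = as.numeric(se["(Intercept)"]),
    p_values = stats::setNames(as.numeric(pv[xcols]), v),
    random_sd = rsd,
    residuals = as.numeric(stats::residuals(fit)),
    row_person = as.character(rows$person_id),
    n_rows = nrow(rows),
    n_persons = length(unique(rows$person_id)),
    estimator = config$estimator,
    converged = TRUE
  ), class = "nodewise_fit")
}

# lmer with fallback optimizers; singular (boundary) fits are accepted.
fit_lmer_robust <- function(form, dat, reml, max_restarts = 3) {
  opts <- c("nloptwrap", "bobyqa", "Nelder_Mead")
  last_err <- NULL
  for (k in seq_len(min(max_restarts, length(opts)))) {
    res <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = dat, REML = reml,
                   control = lme4::lmerControl(
                     optimizer = opts[k], calc.derivs = FALSE,
                     check.conv.singular = "ignore")))),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  stop("Node-wise model failed to converge: ",
       conditionMessage(last_err), call. = FALSE)
}

#' Fit all p node-wise regressions
#'
#' One [fit_node()] per variable, in `variable_names` order. Failures are
#' isolated: a failing node leaves an error record and the remaining nodes
#' are still fit.
#'
#' @inheritParams fit_node
#' @return an `mlvar_fit`: list with `fits` (per-node `nodewise_fit` or
#'   error record), `variable_names`, `config`, and `errors` (named list of
#'   failure messages, empty on full success).
#' @export
fit_all_nodes <- function(design, config = fit_config()) {
  design <- within_person_center(design)
  fits <- list()
  errors <- list()
  for (v in design$variable_names) {
    res <- tryCatch(fit_node(design, v, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[v]] <- conditionMessage(res)
      fits[[v]] <- NULL
    } else fits[[v]] <- res
  }
  structure(list(fits = fits, variable_names = design$variable_names,
                 config = config, errors = errors),
            class = "mlvar_fit")
}

#' @export
print.mlvar_fit <- function(x, ...) {
  cat("Node-wise multilevel VAR fit:", length(x$fits), "of",
      length(x$variable_names), "nodes fit\n")
  if (length(x$errors))
    cat("  failed nodes:", paste(names(x$errors), collapse = ", "), "\n")
  if (length(x$fits))
    cat("  rows:", x$fits[[1]]$n_rows, " persons:", x$fits[[1]]$n_persons, "\n")
  invisible(x)
}

#' Contemporaneous partial-correlation network from node residuals
#'
#' After the temporal effects are removed, same-day dependence lives in the
#' node residuals. Each node's residuals are regressed on all other nodes'
#' residuals (pooled OLS by default; optionally with a person random
#' intercept). For a pair (j, k) the two regression coefficients b_jk and
#' b_kj combine into a partial correlation `sign(b_jk) * sqrt(b_jk * b_kj)`
#' when they agree in sign, and 0 otherwise; the edge is retained only if
#' both coefficients are significant at `alpha` (the "and" rule).
#'
#' @param fit an `mlvar_fit` with all nodes present (residuals must align
#'   on one shared row set).
#' @param config a [fit_config()]; `config$contemporaneous` picks pooled or
#'   multilevel residual regressions.
#' @return a `contemporaneous_network`: symmetric `weights` with zero
#'   diagonal clipped into [-1, 1], symmetric `significant` mask, `alpha`.
#' @export
fit_contemporaneous <- function(fit, config = fit_config()) {
  stopifnot(inherits(fit, "mlvar_fit"))
  v <- fit$variable_names
  if (length(fit$errors))
    stop("Cannot build contemporaneous network: node(s) failed: ",
         paste(names(fit$errors), collapse = ", "), call. = FALSE)
  n <- unique(vapply(fit$fits, function(f) f$n_rows, numeric(1)))
  if (length(n) != 1)
    stop("Residuals misaligned: node fits use different row sets.",
         call. = FALSE)
  R <- vapply(fit$fits, function(f) f$residuals, numeric(n))
  colnames(R) <- v
  residual_network(R, person_id = fit$fits[[1]]$row_person, config = config)
}

#' Partial-correlation network from a residual matrix
#'
#' The node-wise regression engine behind [fit_contemporaneous()], exposed
#' so residual-level oracles (e.g. covariance inversion on simulated
#' residuals) can be checked directly.
#'
#' @param residuals n x p numeric matrix, one column per node.
#' @param person_id optional length-n grouping used when
#'   `config$contemporaneous = "multilevel"`.
#' @param config a [fit_config()].
#' @return a `contemporaneous_network`.
#' @export
residual_network <- function(residuals, person_id = NULL,
                             config = fit_config()) {
  R <- as.matrix(residuals)
  p <- ncol(R)
  v <- colnames(R)
  if (is.null(v)) v <- paste0("V", seq_len(p))
  B <- matrix(NA_real_, p, p, dimnames = list(v, v)) # B[j,k]: coef of k in eq j
  P <- matrix(NA_real_, p, p, dimnames = list(v, v))
  multilevel <- identical(config$contemporaneous, "multilevel") &&
    !is.null(person_id)
  for (j in seq_len(p)) {
    dat <- as.data.frame(R)
    names(dat) <- paste0("r_", seq_len(p))
    form_rhs <- paste(paste0("r_", setdiff(seq_len(p), j)), collapse = " + ")
    if (multilevel) {
      dat$person_id <- factor(person_id)
      m <- fit_lmer_robust(
        stats::as.formula(paste0("r_", j, " ~ ", form_rhs, " + (1 | person_id)")),
        dat, reml = config$estimator == "reml")
      cf <- lme4::fixef(m)
      se <- sqrt(diag(as.matrix(stats::vcov(m))))
      pv <- 2 * stats::pnorm(-abs(cf / se))
    } else {
      m <- stats::lm(stats::as.formula(paste0("r_", j, " ~ ", form_rhs)),
                     data = dat)
      sm <- summary(m)$coefficients
      cf <- sm[, 1]; pv <- sm[, 4]
    }
    for (k in setdiff(seq_len(p), j)) {
      B[j, k] <- cf[paste0("r_", k)]
      P[j, k] <- pv[paste0("r_", k)]
    }
  }
  W <- matrix(0, p, p, dimnames = list(v, v))
  sig <- matrix(FALSE, p, p, dimnames = list(v, v))
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    W[j, k] <- W[k, j] <- combine_pcor(B[j, k], B[k, j])
    sig[j, k] <- sig[k, j] <-
      P[j, k] < config$alpha && P[k, j] < config$alpha
  }
  W <- pmin(pmax(W, -1), 1)
  structure(list(weights = W, significant = sig, alpha = config$alpha,
                 variable_names = v, coefficients = B, p_values = P),
            class = "contemporaneous_network")
}

# Sign-consistent combination of the two directed residual coefficients
# into one undirected partial-correlation weight; conflicting signs give 0.
combine_pcor <- function(b_jk, b_kj) {
  if (b_jk == 0 || b_kj == 0 || sign(b_jk) != sign(b_kj)) return(0)
  sign(b_jk) * sqrt(b_jk * b_kj)
}

#' Inter-individual heterogeneity of the temporal network
#'
#' Standard deviations of the person-specific deviations in each temporal
#' coefficient: entry `[i, j]` is the random-slope SD of lagged predictor i
#' in the node-j regression. Large entries flag edges whose strength varies
#' most across persons.
#'
#' @param fit an `mlvar_fit`.
#' @return a p x p nonnegative matrix in the predictor-by-outcome edge
#'   convention.
#' @export
random_effects_sd_network <- function(fit) {
  stopifnot(inherits(fit, "mlvar_fit"))
  v <- fit$variable_names
  if (length(fit$errors))
    stop("Random-effect network requires all nodes fit.", call. = FALSE)
  out <- matrix(0, length(v), length(v), dimnames = list(v, v))
  for (j in v) out[, j] <- fit$fits[[j]]$random_sd[v]
  out
}
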