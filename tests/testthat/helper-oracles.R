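# Independent oracles and shared fixtures. Oracles are written in the most
# literal form possible (explicit loops / direct summation) so they stay
# independent of the vectorized implementation paths they check.

# KPSS level-stationarity statistic by direct summation.
kpss_oracle <- function(y, L) {
  T_ <- length(y)
  ybar <- 0
  for (t in 1:T_) ybar <- ybar + y[t]
  ybar <- ybar / T_
  e <- numeric(T_)
  for (t in 1:T_) e[t] <- y[t] - ybar
  S <- numeric(T_)
  acc <- 0
  for (t in 1:T_) { acc <- acc + e[t]; S[t] <- acc }
  lrv <- 0
  for (t in 1:T_) lrv <- lrv + e[t]^2
  lrv <- lrv / T_
  if (L >= 1) for (l in 1:L) {
    g <- 0
    for (t in (l + 1):T_) g <- g + e[t] * e[t - l]
    g <- g / T_
    lrv <- lrv + 2 * (1 - l / (L + 1)) * g
  }
  num <- 0
  for (t in 1:T_) num <- num + S[t]^2
  if (lrv <= 0) 0 else num / (T_^2 * lrv)
}

# All simple directed cycles of length 2..3 by exhaustive enumeration over
# node tuples, canonicalized to start at the smallest index.
cycles_oracle <- function(adj) {
  p <- nrow(adj)
  found <- character(0)
  if (p >= 2) for (i in 1:p) for (j in 1:p) {
    if (i != j && adj[i, j] && adj[j, i]) {
      a <- min(i, j); b <- max(i, j)
      found <- c(found, paste("2", a, b))
    }
  }
  if (p >= 3) for (i in 1:p) for (j in 1:p) for (k in 1:p) {
    if (length(unique(c(i, j, k))) == 3 && adj[i, j] && adj[j, k] && adj[k, i]) {
      # rotate so the smallest node leads
      nodes <- c(i, j, k)
      s <- which.min(nodes)
      nodes <- nodes[((s - 1 + 0:2) %% 3) + 1]
      found <- c(found, paste("3", paste(nodes, collapse = " ")))
    }
  }
  sort(unique(found))
}

# Canonical keys of the package's loop output, comparable to cycles_oracle.
loop_keys <- function(loops, variable_names) {
  keys <- vapply(loops, function(l) {
    idx <- match(l$nodes, variable_names)
    if (length(idx) == 2) paste("2", min(idx), max(idx))
    else paste("3", paste(idx, collapse = " "))
  }, character(1))
  sort(keys)
}

# Fake node-wise fits from given weight and p-value matrices, for network
# construction tests (W[i, j] = effect of predictor i on node j).
fake_mlvar_fit <- function(W, P, alpha = 0.05) {
  v <- rownames(W)
  if (is.null(v)) v <- paste0("V", seq_len(nrow(W)))
  dimnames(W) <- dimnames(P) <- list(v, v)
  fits <- lapply(seq_along(v), function(j) {
    structure(list(target = v[j], variable_names = v,
                   fixed_coefs = stats::setNames(W[, j], v),
                   intercept = 0,
                   std_errors = stats::setNames(rep(0.01, length(v)), v),
                   p_values = stats::setNames(P[, j], v),
                   random_sd = stats::setNames(numeric(length(v) + 1),
                                               c("(Intercept)", v)),
                   residuals = numeric(0), row_person = character(0),
                   n_rows = 0, n_persons = 0, estimator = "reml",
                   converged = TRUE),
              class = "nodewise_fit")
  })
  names(fits) <- v
  structure(list(fits = fits, variable_names = v,
                 config = fit_config(alpha = alpha), errors = list()),
            class = "mlvar_fit")
}

# Random significance-masked temporal network.
random_masked_network <- function(p, seed) {
  set.seed(seed)
  v <- paste0("V", seq_len(p))
  W <- matrix(stats::rnorm(p * p), p, p, dimnames = list(v, v))
  P <- matrix(stats::runif(p * p), p, p, dimnames = list(v, v))
  build_temporal_network(fake_mlvar_fit(W, P, alpha = 0.5), alpha = 0.5)
}

# Shared expensive fixture: zero-random-effect world at 200 persons x 50
# days, p = 3, used by the OLS-limit and heterogeneity-recovery tests.
.fixture_cache <- new.env(parent = emptyenv())

ols_limit_fixture <- function() {
  if (!is.null(.fixture_cache$ols)) return(.fixture_cache$ols)
  B <- matrix(c(0.3, 0.1, 0.0,
                0.0, 0.2, 0.1,
                0.1, 0.0, 0.25), 3, 3, byrow = TRUE)
  params <- var_parameters(fixed_temporal = B, fixed_means = c(3, 4, 5),
                           random_mean_sd = rep(0, 3))
  ds <- simulate_esm_dataset(params, n_persons = 200, n_days = 50,
                             seed = 42, discretize = FALSE)
  design <- within_person_center(build_lagged_design(ds, "listwise"))
  fit <- fit_all_nodes(design, fit_config())
  .fixture_cache$ols <- list(params = params, design = design, fit = fit)
  .fixture_cache$ols
}
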