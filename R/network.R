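#' Assemble the temporal network from node-wise fits
#'
#' Entry `[i, j]` of `weights` is the fixed-effect coefficient of lagged
#' predictor i in the node-j regression — the directed lagged (Granger
#' predictive) effect of i at day t-1 on j at day t; the diagonal holds the
#' autocorrelations (edges pointing toward themselves). `significant` marks
#' entries with p-value below `alpha`. Each temporal edge arises from a
#' single node-wise regression, so selection is single-test thresholding;
#' the two-regression "and" rule applies to the contemporaneous network.
#'
#' @param fit an `mlvar_fit` with all nodes present.
#' @param alpha significance threshold (defaults to the fit's config).
#' @return a `temporal_network`: `weights`, `p_values`, `significant`,
#'   `alpha`, `variable_names`.
#' @export
build_temporal_network <- function(fit, alpha = NULL) {
  stopifnot(inherits(fit, "mlvar_fit"))
  if (length(fit$errors))
    stop("Cannot build temporal network; failed node(s): ",
         paste(names(fit$errors), collapse = ", "), call. = FALSE)
  if (is.null(alpha)) alpha <- fit$config$alpha
  v <- fit$variable_names
  p <- length(v)
  W <- Pm <- matrix(NA_real_, p, p, dimnames = list(v, v))
  for (j in seq_len(p)) {
    f <- fit$fits[[v[j]]]
    W[, j] <- f$fixed_coefs[v]
    Pm[, j] <- f$p_values[v]
  }
  new_temporal_network(W, Pm, alpha, v)
}

new_temporal_network <- function(weights, p_values, alpha, variable_names) {
  sig <- p_values < alpha
  obj <- structure(list(weights = weights, p_values = p_values,
                        significant = sig, alpha = alpha,
                        variable_names = variable_names),
                   class = "temporal_network")
  check_mask_consistency(obj)
  obj
}

check_mask_consistency <- function(net) {
  bad <- net$significant & !(net$p_values < net$alpha)
  if (any(bad, na.rm = TRUE))
    stop("Mask inconsistency: significant entry with p >= alpha.",
         call. = FALSE)
  invisible(net)
}

#' Significance-masked weight matrix
#'
#' Non-significant entries set to zero; this is the network used for
#' centrality (the reported edge set), while the full estimate matrix stays
#' available for sensitivity analyses.
#'
#' @param net a `temporal_network` or `contemporaneous_network`.
#' @return a p x p matrix.
#' @export
masked_weights <- function(net) {
  net$weights * ifelse(net$significant, 1, 0)
}

#' Count significant temporal edges
#'
#' @param net a `temporal_network`.
#' @param include_auto count diagonal (autocorrelation) edges too?
#' @return a list with `count`, `proportion` (denominator `p*(p-1)`
#'   candidate cross-lagged edges, or `p^2` with autocorrelations), and
#'   `percent` (proportion rounded to the nearest integer percent).
#' @export
count_significant_edges <- function(net, include_auto = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  sig <- net$significant
  p <- nrow(sig)
  if (!include_auto) diag(sig) <- FALSE
  count <- sum(sig, na.rm = TRUE)
  denom <- as.integer(if (include_auto) p * p else p * (p - 1))
  prop <- count / denom
  list(count = count, n_candidates = denom, proportion = prop,
       percent = round(100 * prop))
}

#' Enumerate feedback loops among significant temporal edges
#'
#' Finds all simple directed cycles of length 2 or 3 through the
#' significance mask (self-loops excluded): pairs of symptoms that predict
#' each other across days, and three-symptom cycles. Cycles are
#' deduplicated up to rotation and reported starting from their smallest
#' node index.
#'
#' @param net a `temporal_network`.
#' @param max_length 2 or 3.
#' @return a list of cycles, each a list with `nodes` (ordered labels,
#'   first repeated implicitly) and `weights` (ordered edge weights).
#' @export
find_feedback_loops <- function(net, max_length = 3) {
  stopifnot(inherits(net, "temporal_network"), max_length %in% c(2, 3))
  A <- net$significant
  diag(A) <- FALSE
  W <- net$weights
  v <- net$variable_names
  p <- nrow(A)
  loops <- list()
  if (p >= 2) for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (A[i, j] && A[j, i])
      loops[[length(loops) + 1]] <- list(
        nodes = v[c(i, j)], weights = c(W[i, j], W[j, i]))
  }
  if (max_length >= 3 && p >= 3) {
    for (i in 1:(p - 2)) for (j in (i + 1):p) for (k in (i + 1):p) {
      if (j == k) next
      # canonical start at smallest index i; orientation i -> j -> k -> i
      if (A[i, j] && A[j, k] && A[k, i])
        loops[[length(loops) + 1]] <- list(
          nodes = v[c(i, j, k)],
          weights = c(W[i, j], W[j, k], W[k, i]))
    }
  }
  loops
}

#' @export
print.temporal_network <- function(x, ...) {
  e <- count_significant_edges(x)
  cat("Temporal network:", length(x$variable_names), "nodes;",
      e$count, "of", e$n_candidates,
      sprintf("cross-lagged edges significant (%d%%);", e$percent),
      sum(diag(x$significant)), "significant autocorrelations\n")
  invisible(x)
}

#' @export
print.contemporaneous_network <- function(x, ...) {
  sig <- x$significant
  cat("Contemporaneous network:", length(x$variable_names), "nodes;",
      sum(sig[upper.tri(sig)]), "of", sum(upper.tri(sig)),
      "undirected edges significant (and-rule)\n")
  invisible(x)
}
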