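#' Out-strength of temporal-network nodes
#'
#' Sum of absolute weights of a node's significant outgoing cross-lagged
#' edges, excluding its autocorrelation: how strongly a symptom predicts
#' the other symptoms on the next day. Raw scores, no standardization.
#'
#' @param net a `temporal_network`.
#' @return a named nonnegative vector.
#' @export
out_strength <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  M <- abs(masked_weights(net))
  diag(M) <- 0
  rowSums(M)
}

#' In-strength of temporal-network nodes
#'
#' Sum of absolute weights of a node's significant incoming cross-lagged
#' edges, excluding its autocorrelation: how strongly a symptom is
#' predicted by the others from the previous day.
#'
#' @param net a `temporal_network`.
#' @return a named nonnegative vector.
#' @export
in_strength <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  M <- abs(masked_weights(net))
  diag(M) <- 0
  colSums(M)
}

#' Strength centrality in the contemporaneous network
#'
#' Sum of absolute weights of the significant undirected edges incident to
#' each node — the node's overall same-day connectivity.
#'
#' @param net a `contemporaneous_network` (symmetric; asymmetric input is
#'   an error).
#' @return a named nonnegative vector.
#' @export
contemporaneous_strength <- function(net) {
  W <- net$weights
  if (max(abs(W - t(W))) > 1e-10)
    stop("Contemporaneous network weights must be symmetric.", call. = FALSE)
  M <- abs(W) * ifelse(net$significant, 1, 0)
  diag(M) <- 0
  rowSums(M)
}

#' Per-symptom strength centrality table
#'
#' @param temporal a `temporal_network`.
#' @param contemporaneous optional `contemporaneous_network` over the same
#'   variables.
#' @return a `centrality_table` data.frame with `variable`, `out_strength`,
#'   `in_strength` and (when available) `contemporaneous_strength`, raw
#'   scores.
#' @export
centrality_table <- function(temporal, contemporaneous = NULL) {
  out <- data.frame(variable = temporal$variable_names,
                    out_strength = as.numeric(out_strength(temporal)),
                    in_strength = as.numeric(in_strength(temporal)))
  if (!is.null(contemporaneous)) {
    if (!identical(contemporaneous$variable_names, temporal$variable_names))
      stop("Networks are over different variable sets.", call. = FALSE)
    out$contemporaneous_strength <-
      as.numeric(contemporaneous_strength(contemporaneous))
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Rank symptoms by a centrality index
#'
#' Descending order; ties keep the table's variable order and are flagged.
#'
#' @param table a [centrality_table()].
#' @param index `"out"`, `"in"` or `"contemporaneous"`.
#' @return a data.frame with `variable`, `value`, `rank` and `tie`.
#' @export
rank_centrality <- function(table, index = c("out", "in", "contemporaneous")) {
  index <- match.arg(index)
  col <- switch(index, out = "out_strength", "in" = "in_strength",
                contemporaneous = "contemporaneous_strength")
  if (!col %in% names(table))
    stop("Centrality table has no '", col, "' column.", call. = FALSE)
  val <- table[[col]]
  ord <- order(-val) # stable: ties keep input order
  out <- data.frame(variable = table$variable[ord], value = val[ord])
  out$rank <- rank(-out$value, ties.method = "min")
  out$tie <- duplicated(out$value) | duplicated(out$value, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
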