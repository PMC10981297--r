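#' Write an ESM dataset as long-format CSV
#'
#' Columns: `person_id`, `day`, one column per symptom, `attention_pass`;
#' missing ratings are written as empty fields.
#'
#' @param dataset an [esm_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(dataset, path) {
  d <- dataset$data[c("person_id", "day", dataset$variable_names,
                      "attention_pass")]
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format ESM CSV
#'
#' @param path CSV with columns `person_id`, `day`, symptom columns, and
#'   optionally `attention_pass` (absent or empty entries are treated as
#'   failing only if the column exists; a missing column means all pass).
#' @param variable_names symptom columns to use; default: every column
#'   other than `person_id`, `day`, `attention_pass`.
#' @param likert_bounds,discretized see [esm_dataset()]; by default the
#'   data are taken as ordinal when all observed values are integers in
#'   bounds.
#' @return an [esm_dataset()].
#' @export
read_esm_csv <- function(path, variable_names = NULL,
                         likert_bounds = c(1L, 7L), discretized = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("person_id", "day") %in% names(d)))
    stop("ESM CSV must have `person_id` and `day` columns.", call. = FALSE)
  if (is.null(variable_names))
    variable_names <- setdiff(names(d), c("person_id", "day", "attention_pass"))
  if (!"attention_pass" %in% names(d)) d$attention_pass <- TRUE
  d$attention_pass <- as.logical(d$attention_pass)
  for (v in variable_names) d[[v]] <- as.numeric(d[[v]])
  if (is.null(discretized)) {
    vals <- unlist(d[variable_names], use.names = FALSE)
    vals <- vals[!is.na(vals)]
    discretized <- length(vals) > 0 && all(vals == round(vals)) &&
      min(vals) >= likert_bounds[1] && max(vals) <= likert_bounds[2]
  }
  esm_dataset(d, variable_names, likert_bounds, discretized)
}

#' Write a network as a TSV edge list
#'
#' One row per ordered pair (directed) or unordered pair (undirected) with
#' weight, p-value(s) and significance flag.
#'
#' @param net a `temporal_network` or `contemporaneous_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  v <- net$variable_names
  p <- length(v)
  rows <- list()
  if (inherits(net, "temporal_network")) {
    for (i in seq_len(p)) for (j in seq_len(p))
      rows[[length(rows) + 1]] <- data.frame(
        from = v[i], to = v[j], weight = net$weights[i, j],
        p_value = net$p_values[i, j], significant = net$significant[i, j])
  } else {
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      rows[[length(rows) + 1]] <- data.frame(
        from = v[i], to = v[j], weight = net$weights[i, j],
        significant = net$significant[i, j])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Significant edges only, with their weights; temporal networks are
#' directed (including self-loops for autocorrelations), contemporaneous
#' networks undirected.
#'
#' @param net a `temporal_network` or `contemporaneous_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  W <- masked_weights(net)
  directed <- inherits(net, "temporal_network")
  g <- igraph::graph_from_adjacency_matrix(
    W, mode = if (directed) "directed" else "undirected",
    weighted = TRUE, diag = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the fit report as JSON
#'
#' Per node: coefficient table (estimate, SE, p), random-effect SDs and fit
#' metadata.
#'
#' @param fit an `mlvar_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  report <- lapply(fit$fits, function(f) list(
    target = f$target,
    intercept = f$intercept,
    coefficients = data.frame(
      predictor = names(f$fixed_coefs),
      estimate = as.numeric(f$fixed_coefs),
      std_error = as.numeric(f$std_errors),
      p_value = as.numeric(f$p_values)),
    random_sd = as.list(f$random_sd),
    n_rows = f$n_rows, n_persons = f$n_persons,
    estimator = f$estimator, converged = f$converged))
  jsonlite::write_json(list(nodes = report, errors = fit$errors),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the loop report as TSV
#' @param loops result of [find_feedback_loops()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loops_tsv <- function(loops, path) {
  rows <- lapply(loops, function(l) data.frame(
    length = length(l$nodes),
    cycle = paste(c(l$nodes, l$nodes[1]), collapse = " -> "),
    weights = paste(format(l$weights, digits = 4), collapse = ", ")))
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(length = integer(), cycle = character(),
                        weights = character())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest listing every output file with a checksum
#' @param paths named character vector of output files.
#' @param config the pipeline configuration to record.
#' @param path manifest destination (YAML).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(paths, config, path) {
  files <- lapply(paths, function(f) list(
    path = f, md5 = unname(tools::md5sum(f))))
  manifest <- list(
    package = "esmnet",
    version = as.character(utils::packageVersion("esmnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[setdiff(names(config), "call")],
    outputs = files)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
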