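#' Long-format experience-sampling dataset
#'
#' Container for one-assessment-per-day diary data: one row per person per
#' day holding the p symptom ratings (possibly missing) and an
#' attention-check outcome. Days are strictly increasing within person and a
#' `(person, day)` pair appears at most once.
#'
#' @param data a data.frame with columns `person_id`, `day`, one numeric
#'   column per variable, and logical `attention_pass`.
#' @param variable_names character vector naming the symptom columns of
#'   `data`, in analysis order.
#' @param likert_bounds inclusive rating range; non-missing values must fall
#'   inside it when `discretized` is `TRUE`.
#' @param discretized whether ratings are ordinal (bounded integers) rather
#'   than latent continuous scores.
#' @return an object of class `esm_dataset`.
#' @export
esm_dataset <- function(data, variable_names,
                        likert_bounds = c(1L, 7L), discretized = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("person_id", "day", variable_names, "attention_pass")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("Dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$day <- as.integer(data$day)
  data <- data[order(data$person_id, data$day), , drop = FALSE]
  rownames(data) <- NULL
  obj <- structure(
    list(data = data, variable_names = variable_names,
         likert_bounds = as.numeric(likert_bounds),
         discretized = isTRUE(discretized)),
    class = "esm_dataset"
  )
  validate_esm_dataset(obj)
  obj
}

#' Validate an experience-sampling dataset
#'
#' @param dataset an `esm_dataset`.
#' @return `dataset`, invisibly; errors on duplicate person-days,
#'   non-increasing days, or (for discretized data) out-of-range ratings.
#' @export
validate_esm_dataset <- function(dataset) {
  d <- dataset$data
  key <- paste(d$person_id, d$day)
  if (anyDuplicated(key))
    stop("Duplicate (person_id, day) records.", call. = FALSE)
  ok <- tapply(d$day, d$person_id, function(x) all(diff(x) > 0))
  if (!all(unlist(ok)))
    stop("`day` must be strictly increasing within each person.", call. = FALSE)
  if (dataset$discretized) {
    vals <- unlist(d[dataset$variable_names], use.names = FALSE)
    vals <- vals[!is.na(vals)]
    lb <- dataset$likert_bounds
    if (length(vals) && (min(vals) < lb[1] || max(vals) > lb[2]))
      stop("Non-missing ratings fall outside [", lb[1], ", ", lb[2], "].",
           call. = FALSE)
  }
  invisible(dataset)
}

#' @export
print.esm_dataset <- function(x, ...) {
  d <- x$data
  n_cells <- nrow(d) * length(x$variable_names)
  n_na <- sum(is.na(d[x$variable_names]))
  cat("ESM dataset:", length(unique(d$person_id)), "persons,",
      nrow(d), "person-days,", length(x$variable_names), "variables\n")
  cat(sprintf("  missing cells: %d / %d (%.2f%%)\n",
              n_na, n_cells, if (n_cells) 100 * n_na / n_cells else 0))
  cat("  scale:", if (x$discretized) sprintf("ordinal [%g, %g]",
      x$likert_bounds[1], x$likert_bounds[2]) else "continuous (latent)", "\n")
  invisible(x)
}

#' Count scheduled, observed and missing cells
#'
#' @param dataset an `esm_dataset`.
#' @return a list with `n_cells`, `n_missing` and `prop_missing`, counting
#'   over the person-day records present in the dataset.
#' @export
missingness_summary <- function(dataset) {
  n_cells <- nrow(dataset$data) * length(dataset$variable_names)
  n_missing <- sum(is.na(dataset$data[dataset$variable_names]))
  list(n_cells = n_cells, n_missing = n_missing,
       prop_missing = if (n_cells) n_missing / n_cells else 0)
}
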