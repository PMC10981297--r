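#' Drop records that failed the attention check
#'
#' Days answered with a wrong attention-check response are deemed invalid:
#' the whole person-day record is removed, so that day becomes missing for
#' the person. Records with an absent (`NA`) attention flag are treated as
#' failing (conservative validity rule).
#'
#' @param dataset an [esm_dataset()].
#' @return the filtered `esm_dataset`.
#' @export
filter_attention_checks <- function(dataset) {
  keep <- dataset$data$attention_pass
  keep[is.na(keep)] <- FALSE
  dataset$data <- dataset$data[keep, , drop = FALSE]
  rownames(dataset$data) <- NULL
  dataset
}

#' Moving-average imputation of a single time series
#'
#' Each missing entry is replaced by the unweighted mean of the *observed*
#' values within `window` positions on either side; if no observed value
#' falls in the window, the window expands symmetrically until at least one
#' is found. Observed entries are never altered, so the operation is
#' idempotent.
#'
#' @param series ordered numeric vector, possibly with `NA`.
#' @param window half-width of the averaging window (days on each side).
#' @return `series` with every `NA` replaced.
#' @export
moving_average_impute <- function(series, window = 2) {
  stopifnot(window >= 1)
  obs <- !is.na(series)
  if (!any(obs))
    stop("Cannot impute an all-missing series.", call. = FALSE)
  n <- length(series)
  out <- series
  for (t in which(!obs)) {
    w <- window
    repeat {
      idx <- max(1, t - w):min(n, t + w)
      idx <- idx[obs[idx]]
      if (length(idx)) break
      w <- w + 1
    }
    out[t] <- mean(series[idx])
  }
  out
}

#' Impute every person-by-variable series of a dataset
#'
#' Expands each person's records to their full day calendar (missing days
#' become all-missing rows with a failed-attention-free `attention_pass =
#' TRUE` placeholder) and applies [moving_average_impute()] per variable, so
#' the result has one complete record per person per calendar day.
#'
#' @param dataset an [esm_dataset()].
#' @param window half-width passed to [moving_average_impute()].
#' @return a complete `esm_dataset` (continuous scale: imputed values are
#'   means and need not be integers).
#' @export
impute_dataset <- function(dataset, window = 2) {
  pieces <- lapply(split(dataset$data, dataset$data$person_id), function(d) {
    days <- seq(min(d$day), max(d$day))
    full <- data.frame(person_id = d$person_id[1], day = days)
    full <- merge(full, d, by = c("person_id", "day"), all.x = TRUE)
    full <- full[order(full$day), , drop = FALSE]
    full$attention_pass[is.na(full$attention_pass)] <- TRUE
    for (v in dataset$variable_names)
      full[[v]] <- moving_average_impute(full[[v]], window)
    full
  })
  dataset$data <- do.call(rbind, pieces)
  rownames(dataset$data) <- NULL
  dataset$discretized <- FALSE
  dataset
}

#' Build the lag-1 design from a diary dataset
#'
#' Creates one candidate row per person per day `t` whose calendar
#' predecessor `t - 1` also has a record, pairing the day-`t` outcomes with
#' the day-`t-1` predictors; transitions across a calendar gap are never
#' created, enforcing a constant one-day lag. In `"listwise"` mode a
#' candidate row is retained only if all p outcomes and all p lagged
#' predictors are observed (so the p node-wise regressions share one row
#' set and their residuals align); in `"imputed"` mode the dataset must
#' already be complete.
#'
#' @param dataset an [esm_dataset()].
#' @param mode `"listwise"` or `"imputed"`.
#' @param window imputation half-width used when `mode = "imputed"`.
#' @return a `lagged_design`: a list with `rows` (data.frame with
#'   `person_id`, `day` = outcome day, outcome columns `y_<var>` and lagged
#'   predictor columns `x_<var>`), `variable_names`, `centered` flag and
#'   (after centering) `person_means`.
#' @export
build_lagged_design <- function(dataset, mode = c("listwise", "imputed"),
                                window = 2) {
  mode <- match.arg(mode)
  if (mode == "imputed") dataset <- impute_dataset(dataset, window)
  v <- dataset$variable_names
  pieces <- lapply(split(dataset$data, dataset$data$person_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    prev <- match(d$day - 1L, d$day)
    keep <- which(!is.na(prev))
    if (!length(keep)) return(NULL)
    out <- data.frame(person_id = d$person_id[keep], day = d$day[keep])
    out[paste0("y_", v)] <- d[keep, v]
    out[paste0("x_", v)] <- d[prev[keep], v]
    out
  })
  rows <- do.call(rbind, pieces)
  if (is.null(rows))
    rows <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), 2 + 2 * length(v)),
      c("person_id", "day", paste0("y_", v), paste0("x_", v))))
  complete <- stats::complete.cases(rows[c(paste0("y_", v), paste0("x_", v))])
  if (mode == "listwise") rows <- rows[complete, , drop = FALSE]
  else if (!all(complete))
    stop("Imputed-mode design still contains missing values.", call. = FALSE)
  rownames(rows) <- NULL
  structure(list(rows = rows, variable_names = v, centered = FALSE,
                 person_means = NULL, mode = mode),
            class = "lagged_design")
}

#' Within-person centering of the lagged predictors
#'
#' Subtracts from each lagged predictor the person's mean over that
#' person's retained design rows, separating within-person dynamics from
#' between-person level differences as is standard for multilevel VAR.
#' Outcomes are left on their original scale; person-level differences in
#' level are absorbed by the random intercept of the node-wise model.
#'
#' @param design a `lagged_design` from [build_lagged_design()].
#' @return the design with `x_` columns centered, `person_means` recorded,
#'   and `centered = TRUE`.
#' @export
within_person_center <- function(design) {
  stopifnot(inherits(design, "lagged_design"))
  if (design$centered) return(design)
  xcols <- paste0("x_", design$variable_names)
  rows <- design$rows
  means <- stats::aggregate(rows[xcols], by = list(person_id = rows$person_id),
                            FUN = mean)
  idx <- match(rows$person_id, means$person_id)
  for (v in xcols) rows[[v]] <- rows[[v]] - means[[v]][idx]
  design$rows <- rows
  design$person_means <- means
  design$centered <- TRUE
  design
}

#' @export
print.lagged_design <- function(x, ...) {
  cat("Lag-1 design:", nrow(x$rows), "rows,",
      length(unique(x$rows$person_id)), "persons,",
      length(x$variable_names), "variables;",
      if (x$centered) "centered" else "uncentered", "\n")
  invisible(x)
}

#' KPSS level-stationarity statistic
#'
#' Computes the KPSS statistic for the null hypothesis of level
#' stationarity: with demeaned series `e_t = y_t - mean(y)`, partial sums
#' `S_t = sum_{s<=t} e_s`, and Bartlett-kernel (Newey-West) long-run
#' variance `lrv = g0 + 2 * sum_{l=1..L} (1 - l/(L+1)) g_l` where
#' `g_l = sum_t e_t e_{t-l} / T`, the statistic is
#' `eta = T^-2 sum_t S_t^2 / lrv`. A constant series has zero long-run
#' variance and is assigned `eta = 0`.
#'
#' @param series fully observed numeric vector, length >= 8.
#' @param lag_truncation Bartlett truncation L; default
#'   `floor(4 * (T/100)^0.25)`.
#' @return a `kpss_result` list with `statistic` and `lag_truncation`.
#' @export
kpss_statistic <- function(series, lag_truncation = NULL) {
  series <- as.numeric(series)
  T_ <- length(series)
  if (T_ < 8) stop("KPSS requires a series of length >= 8.", call. = FALSE)
  if (anyNA(series)) stop("KPSS requires a fully observed series.", call. = FALSE)
  if (is.null(lag_truncation)) lag_truncation <- floor(4 * (T_ / 100)^0.25)
  L <- as.integer(lag_truncation)
  e <- series - mean(series)
  S <- cumsum(e)
  g0 <- sum(e * e) / T_
  lrv <- g0
  if (L >= 1) for (l in seq_len(L)) {
    gl <- sum(e[(l + 1):T_] * e[1:(T_ - l)]) / T_
    lrv <- lrv + 2 * (1 - l / (L + 1)) * gl
  }
  stat <- if (lrv <= 0) 0 else sum(S^2) / (T_^2 * lrv)
  structure(list(statistic = stat, lag_truncation = L, n = T_),
            class = "kpss_result")
}

#' KPSS level-stationarity decision
#'
#' Compares the statistic with the tabulated level-stationarity critical
#' value (0.347, 0.463, 0.739 at the 10%, 5%, 1% levels). A statistic equal
#' to the critical value rejects stationarity (strict inequality).
#'
#' @param result a `kpss_result` from [kpss_statistic()].
#' @param level nominal size: one of 0.10, 0.05, 0.01.
#' @return `TRUE` if the series is judged level-stationary.
#' @export
kpss_decision <- function(result, level = 0.05) {
  crit <- c("0.1" = 0.347, "0.05" = 0.463, "0.01" = 0.739)
  key <- as.character(level)
  if (!key %in% names(crit))
    stop("`level` must be one of 0.10, 0.05, 0.01.", call. = FALSE)
  result$statistic < crit[[key]]
}

#' Per-person, per-variable stationarity report
#'
#' Runs the KPSS test on each person's observed (or imputed) series for
#' each variable; series shorter than 8 observed values are skipped. A
#' variable is reported as passing when at least `pass_prop` of its tested
#' person-series are judged stationary.
#'
#' @param dataset an [esm_dataset()].
#' @param level nominal size for [kpss_decision()].
#' @param pass_prop minimum proportion of stationary person-series for a
#'   variable-level pass (default 0.95).
#' @return a list with `series` (data.frame: variable, person, n, statistic,
#'   stationary) and `variables` (data.frame: variable, n_series, prop_pass,
#'   pass).
#' @export
kpss_report <- function(dataset, level = 0.05, pass_prop = 0.95) {
  rows <- list()
  for (v in dataset$variable_names) {
    for (d in split(dataset$data, dataset$data$person_id)) {
      y <- d[[v]][!is.na(d[[v]])]
      if (length(y) < 8) next
      r <- kpss_statistic(y)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, person_id = d$person_id[1], n = r$n,
        statistic = r$statistic, stationary = kpss_decision(r, level))
    }
  }
  series <- do.call(rbind, rows)
  agg <- stats::aggregate(stationary ~ variable, data = series, FUN = mean)
  names(agg)[2] <- "prop_pass"
  counts <- stats::aggregate(stationary ~ variable, data = series, FUN = length)
  agg$n_series <- counts$stationary
  agg$pass <- agg$prop_pass >= pass_prop
  agg <- agg[match(intersect(dataset$variable_names, agg$variable),
                   agg$variable), ]
  rownames(agg) <- NULL
  list(series = series, variables = agg, level = level,
       pass_prop = pass_prop)
}

#' Daily internal-consistency reliability (Cronbach's alpha)
#'
#' For each day, alpha is computed over persons with complete responses to
#' all k items that day: `alpha = k/(k-1) * (1 - sum(item variances) /
#' var(item sum))`. Days with fewer than two complete responders get `NA`.
#'
#' @param dataset an [esm_dataset()].
#' @return a data.frame with `day`, `n_complete`, `alpha`.
#' @export
cronbach_alpha_daily <- function(dataset) {
  v <- dataset$variable_names
  k <- length(v)
  days <- sort(unique(dataset$data$day))
  out <- data.frame(day = days, n_complete = NA_integer_, alpha = NA_real_)
  for (i in seq_along(days)) {
    m <- dataset$data[dataset$data$day == days[i], v, drop = FALSE]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    out$n_complete[i] <- nrow(m)
    if (nrow(m) < 2) next
    item_var <- sum(apply(m, 2, stats::var))
    total_var <- stats::var(rowSums(m))
    out$alpha[i] <- if (total_var > 0) k / (k - 1) * (1 - item_var / total_var)
                    else NA_real_
  }
  out
}
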