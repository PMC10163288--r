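# Threshold filtering, pareto-front selection and top-fraction ranking over
# design score tables. Score tables are data frames with a design_id column
# and numeric metric columns (NA = metric absent for that design).

#' Build filter criteria
#'
#' Each criterion names a metric and gives a bound, a direction (`"below"`
#' keeps values less than the bound, `"above"` greater) and a strictness.
#' The screening thresholds are written as strict inequalities by default.
#' Designs missing a criterion's metric fail closed.
#'
#' @param ... Named criteria, each a list with elements `bound` (numeric),
#'   and optionally `direction` (`"below"` default) and `strict` (`TRUE`
#'   default). A bare number is shorthand for a strict below-bound.
#' @param schema Optional character vector of permitted metric names; when
#'   supplied, a criterion naming an unknown metric is an error.
#' @return An object of class `filter_criteria`.
#' @examples
#' filter_criteria(pae_interaction = 10, af2_complex_rmsd = 5)
#' @export
filter_criteria <- function(..., schema = NULL) {
  raw <- list(...)
  if (!length(raw)) stop("at least one criterion is required")
  if (is.null(names(raw)) || any(names(raw) == ""))
    stop("every criterion must be named after a metric")
  if (!is.null(schema)) {
    unknown <- setdiff(names(raw), schema)
    if (length(unknown))
      stop("criteria reference unknown metric(s): ", paste(unknown, collapse = ", "))
  }
  crit <- lapply(raw, function(x) {
    if (is.numeric(x) && length(x) == 1L)
      x <- list(bound = x)
    if (is.null(x$bound) || !is.numeric(x$bound))
      stop("each criterion needs a numeric 'bound'")
    direction <- if (is.null(x$direction)) "below" else x$direction
    if (!direction %in% c("below", "above"))
      stop("direction must be 'below' or 'above'")
    strict <- if (is.null(x$strict)) TRUE else isTRUE(x$strict)
    list(bound = as.numeric(x$bound), direction = direction, strict = strict)
  })
  structure(crit, class = "filter_criteria")
}

#' Default two-stage screening criteria
#'
#' The production thresholds: `pae_interaction` strictly below 10 A and
#' `af2_complex_rmsd` strictly below 5 A.
#'
#' @return A [filter_criteria()] object.
#' @export
default_criteria <- function() {
  filter_criteria(pae_interaction = 10, af2_complex_rmsd = 5)
}

#' Read filter criteria from a YAML/JSON config
#'
#' The config maps metric names to either a bare bound or a mapping with
#' `bound`, `direction`, `strict` keys.
#'
#' @param path Path to a YAML (or JSON) file.
#' @param schema Optional permitted metric names; see [filter_criteria()].
#' @return A [filter_criteria()] object.
#' @export
criteria_from_yaml <- function(path, schema = NULL) {
  cfg <- yaml::read_yaml(path)
  do.call(filter_criteria, c(cfg, list(schema = schema)))
}

#' @export
print.filter_criteria <- function(x, ...) {
  for (m in names(x)) {
    op <- if (x[[m]]$direction == "below") "<" else ">"
    if (!x[[m]]$strict) op <- paste0(op, "=")
    cat(sprintf("  %s %s %g\n", m, op, x[[m]]$bound))
  }
  invisible(x)
}

criterion_passes <- function(value, crit) {
  if (crit$direction == "below") {
    if (crit$strict) value < crit$bound else value <= crit$bound
  } else {
    if (crit$strict) value > crit$bound else value >= crit$bound
  }
}

#' Apply threshold criteria to a score table
#'
#' Produces one verdict per design, in input order. A design passes iff it
#' satisfies every criterion and carries every criterion's metric; a missing
#' metric is recorded under `missing_metrics` and fails the design.
#'
#' @param records Score-table data frame (`design_id` + metric columns).
#' @param criteria A [filter_criteria()] object.
#' @return Data frame with columns `design_id`, `pass`, `failed_criteria`
#'   and `missing_metrics` (comma-separated lists, empty string when none).
#' @export
apply_filter <- function(records, criteria = default_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (!nrow(records)) stop("records must be non-empty")
  n <- nrow(records)
  failed <- vector("list", n); missing <- vector("list", n)
  for (m in names(criteria)) {
    vals <- if (m %in% names(records)) records[[m]] else rep(NA_real_, n)
    miss <- is.na(vals)
    ok <- !miss & criterion_passes(vals, criteria[[m]])
    for (i in which(miss)) missing[[i]] <- c(missing[[i]], m)
    for (i in which(!miss & !ok)) failed[[i]] <- c(failed[[i]], m)
  }
  data.frame(
    design_id = records$design_id,
    pass = vapply(seq_len(n), function(i)
      !length(failed[[i]]) && !length(missing[[i]]), logical(1)),
    failed_criteria = vapply(failed, function(x) paste(x, collapse = ","), character(1)),
    missing_metrics = vapply(missing, function(x) paste(x, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

# direction-aware "a dominates b": a at least as good everywhere and
# strictly better somewhere. obj is a numeric matrix already signed so that
# smaller is better.
dominates <- function(a, b) all(a <= b) && any(a < b)

objective_matrix <- function(records, objectives) {
  if (!length(objectives)) stop("objectives must be non-empty")
  cols <- vapply(objectives, function(o) o[[1]], character(1))
  dirs <- vapply(objectives, function(o) {
    d <- if (length(o) >= 2L) o[[2]] else "min"
    if (!d %in% c("min", "max")) stop("objective direction must be 'min' or 'max'")
    d
  }, character(1))
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("objective metric(s) absent from table: ", paste(missing_cols, collapse = ", "))
  M <- as.matrix(records[, cols, drop = FALSE])
  if (anyNA(M)) stop("every record must carry every objective metric")
  for (j in seq_along(dirs)) if (dirs[j] == "max") M[, j] <- -M[, j]
  M
}

#' Non-dominated (pareto-front) design set
#'
#' Returns the designs not dominated on every objective simultaneously by
#' any other design: a record is excluded iff some other record is at least
#' as good on every objective and strictly better on at least one.
#'
#' @param records Score-table data frame.
#' @param objectives List of objectives, each `c(metric, direction)` with
#'   direction `"min"` or `"max"` (default `"min"`).
#' @return Character vector of selected `design_id`s (input order).
#' @export
pareto_front <- function(records, objectives) {
  M <- objective_matrix(records, objectives)
  records$design_id[pareto_mask(M)]
}

# rows of the non-dominated set of M (smaller-is-better columns).
# Sort by first objective so each row need only be checked against rows
# that precede it in the sweep.
pareto_mask <- function(M) {
  n <- nrow(M)
  ord <- do.call(order, as.data.frame(M))
  keep <- logical(n)
  front <- matrix(numeric(0), ncol = ncol(M))
  for (i in ord) {
    dominated <- FALSE
    if (nrow(front)) {
      le <- front <= matrix(M[i, ], nrow(front), ncol(M), byrow = TRUE)
      lt <- front < matrix(M[i, ], nrow(front), ncol(M), byrow = TRUE)
      dominated <- any(rowSums(le) == ncol(M) & rowSums(lt) > 0)
    }
    if (!dominated) {
      keep[i] <- TRUE
      front <- rbind(front, M[i, ])
    }
  }
  keep
}

#' Pareto-front selection to a quota
#'
#' Repeatedly peels the current pareto front into the selection until adding
#' a whole front would exceed the quota; the final partial front is admitted
#' in ascending order of the tie-break metric. Returns exactly `quota` ids.
#'
#' @param records Score-table data frame.
#' @param objectives As in [pareto_front()].
#' @param quota Positive number of designs to select (at most `nrow(records)`).
#' @param tiebreak Metric used to order the final partial front; defaults to
#'   `pae_interaction` ascending, the most discriminative single metric.
#' @return Character vector of exactly `quota` design ids, front-by-front.
#' @export
pareto_select <- function(records, objectives, quota, tiebreak = "pae_interaction") {
  if (quota <= 0) stop("quota must be positive")
  if (quota > nrow(records)) stop("quota exceeds number of records")
  M <- objective_matrix(records, objectives)
  remaining <- seq_len(nrow(records))
  selected <- integer(0)
  while (length(selected) < quota) {
    mask <- pareto_mask(M[remaining, , drop = FALSE])
    front <- remaining[mask]
    if (length(selected) + length(front) <= quota) {
      selected <- c(selected, front)
      remaining <- setdiff(remaining, front)
    } else {
      need <- quota - length(selected)
      if (!tiebreak %in% names(records))
        stop("tie-break metric '", tiebreak, "' absent from table")
      tb <- records[[tiebreak]][front]
      front <- front[order(tb, records$design_id[front])]
      selected <- c(selected, front[seq_len(need)])
    }
  }
  records$design_id[selected]
}

#' Select the top fraction of designs by one metric
#'
#' Picks the best `ceiling(fraction * n)` designs by the metric in the
#' stated direction; ties are broken by `design_id` lexicographic order so
#' the selection is deterministic.
#'
#' @param records Score-table data frame.
#' @param metric Metric column name (must be present, non-NA, on all rows).
#' @param fraction Fraction in (0, 1].
#' @param direction `"min"` if smaller values are better (default), `"max"`
#'   otherwise.
#' @return Character vector of selected design ids, best first.
#' @export
select_top_fraction <- function(records, metric, fraction, direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!metric %in% names(records) || anyNA(records[[metric]]))
    stop("metric '", metric, "' must be present on all records")
  k <- ceiling(fraction * nrow(records))
  vals <- records[[metric]]
  if (direction == "max") vals <- -vals
  ord <- order(vals, records$design_id)
  records$design_id[ord[seq_len(k)]]
}
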