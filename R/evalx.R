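# Retrospective discrimination analysis (top-fraction success rates, ROC)
# and design-pipeline compute-efficiency accounting.

#' Design-pipeline efficiency
#'
#' Efficiency = success rate x throughput: the fraction of generated designs
#' passing the interface-confidence filter, divided by the per-design
#' compute cost in CPU-second equivalents. GPU time is converted at
#' `conversion` CPU-s per GPU-s (default 100, reflecting the relative
#' scarcity of GPU resources).
#'
#' @param n_pass Number of designs passing the filter.
#' @param n_total Number of designs generated.
#' @param cpu_s_per_design CPU seconds per design. May be a vector of
#'   heterogeneous per-design timings, in which case the total is divided by
#'   `n_total`.
#' @param gpu_s_per_design GPU seconds per design (vector allowed, as above).
#' @param conversion CPU-s equivalent of one GPU-s (default 100).
#' @return Object of class `efficiency_report` with fields `n_pass`,
#'   `n_total`, `cpu_s_per_design`, `gpu_s_per_design`, `conversion` and
#'   `efficiency` (passing designs per CPU-s equivalent).
#' @export
efficiency <- function(n_pass, n_total, cpu_s_per_design, gpu_s_per_design = 0,
                       conversion = 100) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_pass < 0 || n_pass > n_total) stop("n_pass must lie in [0, n_total]")
  if (any(cpu_s_per_design < 0) || any(gpu_s_per_design < 0))
    stop("compute times must be non-negative")
  if (length(cpu_s_per_design) > 1L)
    cpu_s_per_design <- sum(cpu_s_per_design) / n_total
  if (length(gpu_s_per_design) > 1L)
    gpu_s_per_design <- sum(gpu_s_per_design) / n_total
  denom <- cpu_s_per_design + conversion * gpu_s_per_design
  if (denom == 0) stop("total per-design compute time must be positive")
  structure(list(n_pass = n_pass, n_total = n_total,
                 cpu_s_per_design = cpu_s_per_design,
                 gpu_s_per_design = gpu_s_per_design,
                 conversion = conversion,
                 efficiency = (n_pass / n_total) / denom),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    "efficiency_report: %d/%d pass (%.3g%%); %.4g CPU-s + %.4g GPU-s per design (1 GPU-s = %g CPU-s)\n  efficiency = %.4g passing designs per CPU-s equivalent\n",
    x$n_pass, x$n_total, 100 * x$n_pass / x$n_total,
    x$cpu_s_per_design, x$gpu_s_per_design, x$conversion, x$efficiency))
  invisible(x)
}

#' Fold improvement between two efficiencies
#'
#' Ratio `a / b`. Given per-target vectors, returns the arithmetic mean of
#' the per-target ratios.
#'
#' @param efficiency_a,efficiency_b Numeric scalars or equal-length vectors
#'   (or `efficiency_report` objects).
#' @return Fold-improvement ratio (mean ratio for vectors).
#' @export
fold_improvement <- function(efficiency_a, efficiency_b) {
  val <- function(x) if (inherits(x, "efficiency_report")) x$efficiency else as.numeric(x)
  a <- val(efficiency_a); b <- val(efficiency_b)
  if (length(a) != length(b)) stop("efficiency vectors must have equal length")
  if (any(b <= 0)) stop("denominator efficiencies must be positive")
  mean(a / b)
}

check_labels <- function(records) {
  if (!"label" %in% names(records) || anyNA(records$label))
    stop("every record must carry a boolean 'label'")
}

#' Experimental success rate within the top fraction of a ranking
#'
#' Selects the best `fraction` of designs by a metric (via
#' [select_top_fraction()]) and reports the proportion of labelled
#' experimental binders among them. At `fraction = 1` this is the overall
#' base rate.
#'
#' @param records Labelled score table (`label` logical column).
#' @param metric Ranking metric.
#' @param fraction Fraction in (0, 1].
#' @param direction `"min"` if lower metric values indicate binding
#'   (pAE_interaction, RMSD), `"max"` otherwise (pLDDT).
#' @return Success rate in [0, 1].
#' @export
success_rate_top_fraction <- function(records, metric, fraction,
                                      direction = c("min", "max")) {
  check_labels(records)
  sel <- select_top_fraction(records, metric, fraction, direction)
  mean(records$label[match(sel, records$design_id)])
}

#' ROC curve and AUC for a screening metric
#'
#' Sweeps a threshold over every distinct metric value (ties grouped into a
#' single step) and reports (FPR, TPR) points plus the trapezoid AUC.
#' `direction` declares whether low values indicate binding; there is no
#' silent auto-flip.
#'
#' @param records Labelled score table.
#' @param metric Metric column.
#' @param direction `"min"` or `"max"`, as in [success_rate_top_fraction()].
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(records, metric, direction = c("min", "max")) {
  direction <- match.arg(direction)
  check_labels(records)
  if (!metric %in% names(records) || anyNA(records[[metric]]))
    stop("metric '", metric, "' must be present on all records")
  lab <- records$label
  if (!any(lab) || all(lab)) stop("both classes must be present")
  score <- records[[metric]]
  goodness <- if (direction == "min") -score else score
  ord <- order(goodness, decreasing = TRUE)
  g <- goodness[ord]; l <- lab[ord]
  # one step per distinct score value (ties grouped)
  last <- c(g[-1] != g[-length(g)], TRUE)
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  P <- sum(lab); N <- sum(!lab)
  pts <- data.frame(threshold = c(NA, score[ord][last]),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Tabular evaluation report for a labelled score table
#'
#' For each metric, reports the AUC and the top-fraction success rate, with
#' numbers rounded to 6 significant digits.
#'
#' @param records Labelled score table.
#' @param metrics Named character vector or list mapping metric name to
#'   direction (`"min"`/`"max"`).
#' @param fraction Top fraction for the success-rate column (default 0.01).
#' @return Data frame with columns `metric`, `direction`, `auc`,
#'   `top_fraction`, `success_rate`, `base_rate`.
#' @export
evaluation_report <- function(records, metrics, fraction = 0.01) {
  check_labels(records)
  rows <- lapply(names(metrics), function(m) {
    dir <- metrics[[m]]
    data.frame(metric = m, direction = dir,
               auc = signif(roc_curve(records, m, dir)$auc, 6),
               top_fraction = fraction,
               success_rate = signif(
                 success_rate_top_fraction(records, m, fraction, dir), 6),
               base_rate = signif(mean(records$label), 6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
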