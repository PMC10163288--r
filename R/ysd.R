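# SC50 estimation from yeast-surface-display titration sorts. A library is
# sorted at decreasing target concentrations; the frequency of each design
# at each sort is read out by deep sequencing. SC50 is the concentration at
# which half of a design's expressing cells are collected -- a display-based
# affinity surrogate (lower is better; success threshold 4 uM).

#' Construct a sort manifest
#'
#' One row per sort. The expression (reference) sort has no concentration;
#' the avidity sort uses multivalent target presentation to capture weak
#' binders and is excluded from SC50 fitting.
#'
#' @param sort_id Unique sort identifiers.
#' @param concentration_uM Target concentration per sort in micromolar; `NA`
#'   for the expression-only sort.
#' @param avidity Logical, multivalent-target sort.
#' @param total_reads Total sequencing reads per sort.
#' @param total_cells_collected Optional total cells collected per sort.
#' @return Data frame of class `sort_manifest`.
#' @export
sort_manifest <- function(sort_id, concentration_uM, avidity, total_reads,
                          total_cells_collected = NA_real_) {
  if (anyDuplicated(sort_id)) stop("sort_id values must be unique")
  if (any(concentration_uM < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  df <- data.frame(sort_id = as.character(sort_id),
                   concentration_uM = as.numeric(concentration_uM),
                   avidity = as.logical(avidity),
                   total_reads = as.numeric(total_reads),
                   total_cells_collected = as.numeric(total_cells_collected),
                   stringsAsFactors = FALSE)
  class(df) <- c("sort_manifest", "data.frame")
  df
}

#' Construct a per-design sort series
#'
#' @param design_id Design identifier.
#' @param counts Named numeric vector of read counts, names matching
#'   `sort_id`s of the accompanying manifest.
#' @param manifest A [sort_manifest()].
#' @return Object of class `sort_series`.
#' @export
sort_series <- function(design_id, counts, manifest) {
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be named by sort_id")
  unknown <- setdiff(names(counts), manifest$sort_id)
  if (length(unknown))
    stop("counts reference unknown sort(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(design_id = as.character(design_id),
                 counts = counts, sorts = manifest),
            class = "sort_series")
}

#' Collection fractions across titration sorts
#'
#' For each non-avidity titration sort, estimates the fraction of the
#' design's expressing cells that were collected:
#' `(frequency in sort * cells collected in sort) /
#'  (frequency in reference * cells collected in reference)`,
#' clipped to [0, 1] when cell totals are available. When cell totals are
#' absent the raw frequency ratio is used unclipped. Avidity sorts are an
#' upstream enrichment gate and never contribute.
#'
#' @param series A [sort_series()].
#' @param reference_sort `sort_id` of the expression reference sort.
#' @return Data frame with columns `sort_id`, `concentration_uM`, `fraction`
#'   and an attribute `status`: `"ok"`, or `"absent"` (zero reference count;
#'   zero rows returned).
#' @export
collection_fractions <- function(series, reference_sort) {
  m <- series$sorts
  if (!reference_sort %in% m$sort_id)
    stop("reference sort '", reference_sort, "' not in manifest")
  ref <- m[m$sort_id == reference_sort, ]
  ref_count <- series$counts[[reference_sort]]
  if (is.null(ref_count)) ref_count <- 0
  empty <- data.frame(sort_id = character(0), concentration_uM = numeric(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (ref_count == 0) {
    attr(empty, "status") <- "absent"
    return(empty)
  }
  tit <- m[!is.na(m$concentration_uM) & !m$avidity & m$sort_id != reference_sort, ]
  if (!nrow(tit)) {
    attr(empty, "status") <- "ok"
    return(empty)
  }
  ref_freq <- ref_count / ref$total_reads
  have_cells <- !is.na(ref$total_cells_collected) &&
    all(!is.na(tit$total_cells_collected))
  frac <- vapply(seq_len(nrow(tit)), function(i) {
    cnt <- series$counts[[tit$sort_id[i]]]
    if (is.null(cnt) || is.na(cnt)) cnt <- 0
    freq <- cnt / tit$total_reads[i]
    if (have_cells) {
      f <- (freq * tit$total_cells_collected[i]) /
        (ref_freq * ref$total_cells_collected)
      min(max(f, 0), 1)
    } else {
      freq / ref_freq
    }
  }, numeric(1))
  out <- data.frame(sort_id = tit$sort_id,
                    concentration_uM = tit$concentration_uM,
                    fraction = frac, stringsAsFactors = FALSE)
  attr(out, "status") <- "ok"
  out
}

#' One-site saturable binding isotherm
#'
#' Expected collection fraction at target concentration `c`:
#' `f(c) = f_max * c / (c + sc50)`, so `f(sc50) = f_max / 2`.
#'
#' @param conc Concentration(s), micromolar.
#' @param sc50 Half-collection concentration, micromolar.
#' @param f_max Saturating collection fraction in [0, 1].
#' @return Expected fraction(s).
#' @export
binding_isotherm <- function(conc, sc50, f_max = 1) {
  f_max * conc / (conc + sc50)
}

#' Estimate SC50 from collection fractions
#'
#' Least-squares fit of the one-site isotherm `f(c) = f_max * c / (c +
#' SC50)` with SC50 parameterised in log-concentration space (multi-start
#' quasi-Newton over a log-spaced grid spanning the tested range). The
#' one-site model matches the half-of-expressing-cells reading of SC50 with
#' the fewest parameters; `hill = TRUE` adds a free Hill slope for
#' diagnostics.
#'
#' @param fractions Data frame with `concentration_uM` and `fraction`
#'   columns (as from [collection_fractions()]), or a numeric vector of
#'   fractions named by concentration.
#' @param no_binding_max Designs whose maximal observed fraction is below
#'   this are called `no_binding` without fitting (default 0.1).
#' @param out_of_range_factor Fits with SC50 above this multiple of the
#'   highest tested concentration are called `out_of_range` (default 10).
#' @param hill Fit a free Hill slope as well (default `FALSE`).
#' @return Object of class `sc50_estimate`: `sc50` (uM, `NA` unless
#'   converged), `f_max`, `residual` (root-mean-square fit residual),
#'   `status` in `converged`/`no_binding`/`out_of_range`, and `hill_slope`
#'   when requested.
#' @export
estimate_sc50 <- function(fractions, no_binding_max = 0.1,
                          out_of_range_factor = 10, hill = FALSE) {
  if (is.data.frame(fractions)) {
    conc <- fractions$concentration_uM
    y <- fractions$fraction
  } else {
    conc <- as.numeric(names(fractions))
    y <- as.numeric(fractions)
  }
  keep <- !is.na(conc) & conc > 0 & !is.na(y)
  conc <- conc[keep]; y <- y[keep]
  if (length(unique(conc)) < 3L)
    stop("at least 3 distinct nonzero concentrations are required")
  est <- structure(list(sc50 = NA_real_, f_max = NA_real_,
                        residual = NA_real_, status = "no_binding"),
                   class = "sc50_estimate")
  if (max(y) < no_binding_max) return(est)
  lc <- log(conc)
  obj <- function(par) {
    k <- exp(par[1]); fm <- par[2]
    h <- if (hill) par[3] else 1
    pred <- fm * conc^h / (conc^h + k^h)
    sum((pred - y)^2)
  }
  # multi-start: log-spaced SC50 grid spanning the tested range (extended
  # one decade each side), f_max started at the plateau estimate
  starts <- seq(min(lc) - log(10), max(lc) + log(10), length.out = 7)
  fm0 <- min(max(max(y), 0.05), 1)
  best <- NULL
  for (s in starts) {
    p0 <- c(s, fm0); lo <- c(min(lc) - 20, 1e-3); hi <- c(max(lc) + 20, 1)
    if (hill) { p0 <- c(p0, 1); lo <- c(lo, 0.2); hi <- c(hi, 5) }
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(est)
  sc50 <- exp(best$par[1])
  est$f_max <- best$par[2]
  est$residual <- sqrt(best$value / length(y))
  if (hill) est$hill_slope <- best$par[3]
  if (sc50 > out_of_range_factor * max(conc)) {
    est$status <- "out_of_range"
  } else {
    est$status <- "converged"
    est$sc50 <- sc50
  }
  est
}

#' @export
print.sc50_estimate <- function(x, ...) {
  if (x$status == "converged")
    cat(sprintf("SC50 = %.4g uM (f_max %.3f, rms residual %.3g)\n",
                x$sc50, x$f_max, x$residual))
  else
    cat("SC50: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Call experimental success from an SC50 estimate
#'
#' A design succeeds iff its fit converged and the SC50 is strictly better
#' (lower) than the threshold.
#'
#' @param estimate An `sc50_estimate`.
#' @param threshold Success threshold in micromolar (default 4).
#' @return Logical.
#' @export
call_success <- function(estimate, threshold = 4) {
  identical(estimate$status, "converged") && estimate$sc50 < threshold
}

#' Read a sort count matrix and manifest from TSV
#'
#' The count matrix has designs as rows (`design_id` column) and sorts as
#' columns; the manifest follows the [sort_manifest()] schema.
#'
#' @param counts_tsv,manifest_tsv Paths (or TSV text).
#' @return List of [sort_series()] objects, one per design.
#' @export
read_sort_counts <- function(counts_tsv, manifest_tsv) {
  cm <- read_score_table(counts_tsv)
  mf <- utils::read.delim(
    if (length(manifest_tsv) == 1L && !grepl("[\t\n]", manifest_tsv) &&
        file.exists(manifest_tsv)) manifest_tsv else textConnection(manifest_tsv),
    check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- sort_manifest(mf$sort_id, mf$concentration_uM, mf$avidity,
                            mf$total_reads, mf$total_cells_collected)
  sorts <- intersect(names(cm), manifest$sort_id)
  lapply(seq_len(nrow(cm)), function(i) {
    counts <- as.numeric(cm[i, sorts]); names(counts) <- sorts
    counts[is.na(counts)] <- 0
    sort_series(cm$design_id[i], counts, manifest)
  })
}

#' Write a sort count matrix and manifest to TSV
#'
#' @param series_list List of [sort_series()] sharing one manifest.
#' @param counts_path,manifest_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_sort_counts <- function(series_list, counts_path, manifest_path) {
  manifest <- series_list[[1]]$sorts
  rows <- lapply(series_list, function(s) {
    v <- s$counts[manifest$sort_id]
    v[is.na(v)] <- 0
    c(design_id = s$design_id, stats::setNames(as.character(v), manifest$sort_id))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(manifest), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, manifest_path))
}
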