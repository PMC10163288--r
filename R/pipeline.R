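# Campaign orchestration: the prediction-request payload for initial-guess
# complex prediction, the inverse-folding/relax design cycle with pluggable
# stages, and the end-to-end score -> filter -> evaluate runner.

aa_321 <- function(three) {
  out <- bio3d::aa321(three)
  if (any(out == "X")) stop("unknown residue name(s): ",
                            paste(unique(three[out == "X"]), collapse = ", "))
  paste(out, collapse = "")
}

aa_123 <- function(one) {
  bio3d::aa123(strsplit(one, "")[[1]])
}

#' Build an initial-guess prediction request
#'
#' Assembles the payload handed to an external structure predictor for
#' complex evaluation: per-chain sequences, the full design Calpha
#' coordinates as the initial guess (the predictor's first recycle starts
#' from these instead of zeros), and template flags marking the target
#' chains to be provided as structural templates. No inference is performed
#' here; the request is a serializable contract only.
#'
#' @param designed A [complex_structure()].
#' @param sequences Optional named character vector of one-letter sequences
#'   per chain; defaults to the sequences stored in the structure. Lengths
#'   must match chain lengths.
#' @param reduced_extra_msa Annotation only: request the predictor's reduced
#'   extra-MSA configuration for speed (default `TRUE`).
#' @return Object of class `prediction_request`.
#' @export
build_prediction_request <- function(designed, sequences = NULL,
                                     reduced_extra_msa = TRUE) {
  chain_ids <- names(designed$chains)
  if (is.null(sequences)) {
    sequences <- vapply(designed$chains, function(ch) aa_321(ch$residue_names),
                        character(1))
  }
  missing <- setdiff(chain_ids, names(sequences))
  if (length(missing))
    stop("no sequence supplied for chain(s): ", paste(missing, collapse = ", "))
  for (cid in chain_ids) {
    if (nchar(sequences[[cid]]) != nrow(designed$chains[[cid]]$ca_coords))
      stop("sequence length for chain '", cid, "' (", nchar(sequences[[cid]]),
           ") does not match structure (",
           nrow(designed$chains[[cid]]$ca_coords), ")")
  }
  target_template <- stats::setNames(chain_ids %in% designed$target_chain_ids,
                                     chain_ids)
  if (!any(target_template))
    warning("binder-only structure: no target chains to template")
  structure(list(
    sequences = as.list(sequences[chain_ids]),
    initial_guess_coords = lapply(designed$chains, function(ch) ch$ca_coords),
    target_template = as.list(target_template),
    recycle_init = TRUE,
    reduced_extra_msa = isTRUE(reduced_extra_msa)),
    class = "prediction_request")
}

#' Serialize / parse a prediction request
#'
#' @param request A `prediction_request`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
write_prediction_request <- function(request, path = NULL) {
  txt <- as.character(jsonlite::toJSON(unclass(request), digits = I(17),
                                       auto_unbox = TRUE, matrix = "rowmajor"))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_prediction_request
#' @param json JSON text or path produced by [write_prediction_request()].
#' @export
read_prediction_request <- function(json) {
  src <- if (length(json) == 1L && !grepl("[{\n]", json) && file.exists(json))
    json else paste(json, collapse = "\n")
  p <- jsonlite::fromJSON(src, simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  p$initial_guess_coords <- lapply(p$initial_guess_coords, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  })
  p$sequences <- lapply(p$sequences, as.character)
  p$target_template <- lapply(p$target_template, as.logical)
  structure(p[c("sequences", "initial_guess_coords", "target_template",
                "recycle_init", "reduced_extra_msa")],
            class = "prediction_request")
}

#' Deterministic mock sequence designer
#'
#' Stage contract: a designer receives the complex with the binder sequence
#' masked and must return a binder sequence of identical length. This mock
#' samples a uniform random sequence from its own seeded stream, advancing
#' deterministically per call.
#'
#' @param seed Integer seed for the designer's private stream.
#' @return A function `(complex) -> one-letter sequence string`.
#' @export
mock_designer <- function(seed = 1) {
  calls <- 0L
  aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  function(cx) {
    calls <<- calls + 1L
    n <- nrow(cx$chains[[cx$binder_chain_id]]$ca_coords)
    with_seed(child_seed(seed, calls),
              paste(sample(aa1, n, replace = TRUE), collapse = ""))
  }
}

#' Deterministic mock structure relaxer
#'
#' Stage contract: a relaxer receives a complex and returns a complex with
#' identical chain topology. This mock applies a small seeded coordinate
#' jitter to every chain, advancing deterministically per call.
#'
#' @param seed Integer seed.
#' @param sd Jitter standard deviation in Angstrom (default 0.05).
#' @return A function `(complex) -> complex`.
#' @export
mock_relaxer <- function(seed = 1, sd = 0.05) {
  calls <- 0L
  function(cx) {
    calls <<- calls + 1L
    with_seed(child_seed(seed, calls), {
      for (cid in names(cx$chains)) {
        n <- nrow(cx$chains[[cid]]$ca_coords)
        cx$chains[[cid]]$ca_coords <- cx$chains[[cid]]$ca_coords +
          matrix(stats::rnorm(3 * n, sd = sd), ncol = 3)
      }
      cx
    })
  }
}

#' Alternating sequence-design / relax cycle
#'
#' Runs `n_cycles` of design -> thread -> relax: the designer assigns the
#' binder a new sequence (binder masked, target fixed), the sequence is
#' threaded onto the binder chain, and the relaxer refines the whole
#' complex. Target chain sequences and the chain topology are asserted
#' unchanged every iteration; the binder sequence length is constant.
#'
#' @param initial A [complex_structure()].
#' @param designer Function `(complex) -> binder one-letter sequence`; see
#'   [mock_designer()].
#' @param relaxer Function `(complex) -> complex`; see [mock_relaxer()].
#' @param n_cycles Number of cycles (default 3).
#' @return Object of class `cycle_state`: `iteration`, `structure` (final
#'   complex), `binder_sequence`, and `log` (one row per iteration with the
#'   assigned sequence and a post-relax structure digest).
#' @export
mpnn_fr_cycle <- function(initial, designer, relaxer, n_cycles = 3) {
  if (n_cycles < 0) stop("n_cycles must be non-negative")
  bid <- initial$binder_chain_id
  binder_len <- nrow(initial$chains[[bid]]$ca_coords)
  target_seqs <- lapply(initial$chains[initial$target_chain_ids],
                        function(ch) ch$residue_names)
  lens <- vapply(initial$chains, function(ch) nrow(ch$ca_coords), integer(1))
  cx <- initial
  log <- vector("list", n_cycles)
  for (it in seq_len(n_cycles)) {
    masked <- cx
    masked$chains[[bid]]$residue_names <- rep("UNK", binder_len)
    seq1 <- designer(masked)
    if (!is.character(seq1) || length(seq1) != 1L || nchar(seq1) != binder_len)
      stop("designer returned a sequence of length ",
           if (is.character(seq1)) nchar(seq1) else NA,
           " (binder length is ", binder_len, ")")
    cx$chains[[bid]]$residue_names <- aa_123(seq1)   # thread
    relaxed <- relaxer(cx)
    new_lens <- vapply(relaxed$chains, function(ch) nrow(ch$ca_coords), integer(1))
    if (!identical(names(new_lens), names(lens)) || !identical(new_lens, lens))
      stop("relaxer altered chain topology at iteration ", it)
    for (tc in initial$target_chain_ids) {
      if (!identical(relaxed$chains[[tc]]$residue_names, target_seqs[[tc]]))
        stop("target chain '", tc, "' sequence modified at iteration ", it)
    }
    cx <- relaxed
    log[[it]] <- data.frame(
      iteration = it, sequence = seq1,
      structure_digest = sprintf("%.6f", sum(ca_matrix(cx)^2)),
      stringsAsFactors = FALSE)
  }
  structure(list(
    iteration = n_cycles,
    structure = cx,
    binder_sequence = aa_321(cx$chains[[bid]]$residue_names),
    log = if (n_cycles) do.call(rbind, log) else
      data.frame(iteration = integer(0), sequence = character(0),
                 structure_digest = character(0))),
    class = "cycle_state")
}

#' Run a full scoring/filtering/evaluation campaign
#'
#' Scores every design, applies the filter criteria, and (when labels are
#' available) produces a discrimination report. Inputs come either from a
#' synthetic benchmark (`config$synth`, a [benchmark_spec()]) or from a
#' directory of per-design files (`config$input_dir` containing
#' `<id>.pdb` predicted complexes, `<id>_design.pdb` design models and
#' `<id>_confidence.json` bundles; `config$binder_chain` and
#' `config$target_chains` name the roles). A design with structures but no
#' confidence bundle is scored with missing metrics and fails closed; a
#' malformed file is logged, the run continues, and the returned status is
#' nonzero. Given identical inputs the outputs are byte-identical.
#'
#' @param config Named list (or path to a YAML file): `synth` or
#'   `input_dir`, optional `criteria` (metric -> bound or full criterion
#'   spec), optional `output_dir` to write `scores.tsv`, `verdicts.tsv` and
#'   `evaluation.tsv`, optional `top_fraction` (default 0.01).
#' @return List of class `campaign_result`: `scores`, `verdicts`,
#'   `evaluation` (or `NULL`), `errors` (character), `status` (0 = clean).
#' @export
run_campaign <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  criteria <- if (is.null(config$criteria)) default_criteria()
              else do.call(filter_criteria, config$criteria)
  errors <- character(0)
  if (!is.null(config$synth)) {
    spec <- if (inherits(config$synth, "benchmark_spec")) config$synth
            else do.call(benchmark_spec, config$synth)
    scores <- make_benchmark(spec)
  } else if (!is.null(config$input_dir)) {
    scores <- score_directory(config)
    errors <- attr(scores, "errors") %||% character(0)
  } else stop("config must supply 'synth' or 'input_dir'")
  if (!nrow(scores)) stop("no designs found")
  verdicts <- apply_filter(scores, criteria)
  evaluation <- NULL
  if ("label" %in% names(scores) && !anyNA(scores$label)) {
    dirs <- list(pae_interaction = "min", binder_plddt = "max",
                 monomer_rmsd = "min", af2_complex_rmsd = "min")
    dirs <- dirs[names(dirs) %in% names(scores)]
    evaluation <- evaluation_report(scores, dirs,
                                    fraction = config$top_fraction %||% 0.01)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_score_table(scores, file.path(config$output_dir, "scores.tsv"))
    write_score_table(verdicts, file.path(config$output_dir, "verdicts.tsv"))
    if (!is.null(evaluation))
      utils::write.table(evaluation,
                         file.path(config$output_dir, "evaluation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(scores = scores, verdicts = verdicts, evaluation = evaluation,
                 errors = errors, status = if (length(errors)) 1L else 0L),
            class = "campaign_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Score a directory of per-design structure/confidence files.
score_directory <- function(config) {
  dir <- config$input_dir
  binder <- config$binder_chain %||% "A"
  targets <- config$target_chains %||% "B"
  pdbs <- sort(list.files(dir, pattern = "\\.pdb$"))
  pdbs <- pdbs[!grepl("_design\\.pdb$", pdbs)]
  ids <- sub("\\.pdb$", "", pdbs)
  if (!length(ids)) stop("no designs found in ", dir)
  errors <- character(0)
  rows <- lapply(ids, function(id) {
    row <- data.frame(design_id = id, pae_interaction = NA_real_,
                      binder_plddt = NA_real_, monomer_rmsd = NA_real_,
                      af2_complex_rmsd = NA_real_, stringsAsFactors = FALSE)
    pred <- tryCatch(
      read_structure(file.path(dir, paste0(id, ".pdb")), binder, targets),
      error = function(e) {
        errors <<- c(errors, paste0(id, ": ", conditionMessage(e))); NULL
      })
    if (is.null(pred)) return(row)
    conf_file <- file.path(dir, paste0(id, "_confidence.json"))
    if (file.exists(conf_file)) {
      bundle <- tryCatch(read_confidence(conf_file, chain_map(pred)),
                         error = function(e) {
                           errors <<- c(errors, paste0(id, ": ", conditionMessage(e)))
                           NULL
                         })
      if (!is.null(bundle)) {
        row$pae_interaction <- pae_interaction(bundle, binder)
        row$binder_plddt <- binder_plddt(bundle, binder)
      }
    }
    des_file <- file.path(dir, paste0(id, "_design.pdb"))
    if (file.exists(des_file)) {
      des <- tryCatch(read_structure(des_file, binder, targets),
                      error = function(e) {
                        errors <<- c(errors, paste0(id, ": ", conditionMessage(e)))
                        NULL
                      })
      if (!is.null(des)) {
        row$monomer_rmsd <- monomer_ca_rmsd(pred$chains[[binder]],
                                            des$chains[[binder]])
        row$af2_complex_rmsd <- complex_aligned_rmsd(pred, des, "all_residues")
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errors
  out
}
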