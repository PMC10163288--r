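# Core coordinate and record types plus readers/writers for the three
# on-disk dialects used throughout the package: PDB ATOM records for
# structures, JSON for confidence bundles, TSV for score tables.

#' Construct a single-chain Calpha trace
#'
#' A `chain_structure` holds one chain of a design or prediction reduced to
#' its Calpha coordinates. Residues are paired by order downstream, so the
#' residue numbering must be strictly increasing.
#'
#' @param chain_id Single-character chain label.
#' @param residue_numbers Integer vector of residue numbers, strictly
#'   increasing.
#' @param residue_names Character vector of 3-letter amino-acid codes.
#' @param ca_coords Numeric matrix (n x 3) of Calpha coordinates in Angstrom.
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, residue_numbers, residue_names, ca_coords) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L, nchar(chain_id) == 1L)
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L)
    stop("ca_coords must be an n x 3 matrix")
  n <- nrow(ca_coords)
  if (length(residue_numbers) != n || length(residue_names) != n)
    stop("residue_numbers, residue_names and ca_coords must have equal length")
  residue_numbers <- as.integer(residue_numbers)
  if (n > 1L && any(diff(residue_numbers) <= 0L))
    stop("residue_numbers must be strictly increasing within chain ", chain_id)
  storage.mode(ca_coords) <- "double"
  dimnames(ca_coords) <- NULL
  structure(
    list(chain_id = chain_id,
         residue_numbers = residue_numbers,
         residue_names = as.character(residue_names),
         ca_coords = ca_coords),
    class = "chain_structure")
}

#' Construct a binder-target complex
#'
#' A `complex_structure` is an ordered set of chains with one chain marked
#' as the designed binder and the remainder as target chains. Chains are
#' stored binder-first, then target chains in their declared order; this
#' fixed ordering is the residue-indexing convention shared with
#' [confidence_bundle()] matrices.
#'
#' @param chains List of [chain_structure()] objects.
#' @param binder_chain_id Label of the binder chain.
#' @param target_chain_ids Labels of the target chain(s); may be empty for a
#'   binder-only monomer (most metrics then do not apply).
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(chains, binder_chain_id, target_chain_ids = character()) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate chain identifiers: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (sum(ids == binder_chain_id) != 1L)
    stop("binder chain '", binder_chain_id, "' must refer to exactly one chain")
  if (binder_chain_id %in% target_chain_ids)
    stop("binder chain cannot also be a target chain")
  missing <- setdiff(target_chain_ids, ids)
  if (length(missing))
    stop("target chain(s) not present: ", paste(missing, collapse = ", "))
  ord <- c(binder_chain_id, target_chain_ids)
  chains <- chains[match(ord, ids)]
  names(chains) <- ord
  structure(
    list(chains = chains,
         binder_chain_id = binder_chain_id,
         target_chain_ids = as.character(target_chain_ids)),
    class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  lens <- vapply(x$chains, function(ch) length(ch$residue_numbers), integer(1))
  cat("complex_structure: binder '", x$binder_chain_id, "' + ",
      length(x$target_chain_ids), " target chain(s); residues per chain: ",
      paste(sprintf("%s=%d", names(lens), lens), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total residue count of a complex
#' @param x A `complex_structure`.
#' @return Integer residue count summed over chains.
#' @export
n_residues <- function(x) {
  sum(vapply(x$chains, function(ch) length(ch$residue_numbers), integer(1)))
}

#' Per-residue chain labels in matrix order
#'
#' Expands a complex into the per-residue chain-label vector that indexes
#' rows/columns of its confidence matrices (binder chain first, then target
#' chains in declared order).
#' @param x A `complex_structure`.
#' @return Character vector of chain labels, one per residue.
#' @export
chain_map <- function(x) {
  unlist(lapply(x$chains, function(ch)
    rep(ch$chain_id, length(ch$residue_numbers))), use.names = FALSE)
}

#' Stacked Calpha coordinates of a complex
#' @param x A `complex_structure`.
#' @param chains Optional chain labels to restrict to (declared order kept).
#' @return Numeric matrix (n x 3).
#' @export
ca_matrix <- function(x, chains = NULL) {
  keep <- if (is.null(chains)) names(x$chains) else chains
  do.call(rbind, lapply(x$chains[keep], function(ch) ch$ca_coords))
}

#' Construct a prediction-confidence bundle
#'
#' Holds the per-residue pLDDT vector and the pairwise predicted-aligned-error
#' (pAE) matrix emitted alongside a structure prediction, with a per-residue
#' chain map aligned to matrix order. pAE is generally asymmetric:
#' `pae[i, j]` is the expected error of residue j when aligned on residue i's
#' frame. pLDDT supplied on the [0, 1] scale is rescaled to 0-100 with a
#' warning.
#'
#' @param plddt Numeric vector of per-residue pLDDT values in [0, 100].
#' @param pae Square numeric matrix of non-negative pAE values in Angstrom.
#' @param chain_map Character vector of per-residue chain labels.
#' @return An object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(plddt, pae, chain_map) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stop("pae matrix must be square, got ", nrow(pae), " x ", ncol(pae))
  n <- nrow(pae)
  if (length(plddt) != n)
    stop("plddt length (", length(plddt), ") does not match pae side (", n, ")")
  if (length(chain_map) != n)
    stop("chain_map length (", length(chain_map), ") does not match pae side (", n, ")")
  plddt <- as.numeric(plddt)
  if (all(plddt >= 0 & plddt <= 1) && any(plddt > 0)) {
    warning("pLDDT appears to be on the [0,1] scale; rescaling to 0-100")
    plddt <- plddt * 100
  }
  if (any(plddt < 0 | plddt > 100))
    stop("pLDDT values must lie in [0, 100]")
  if (any(pae < 0))
    stop("pAE values must be non-negative")
  storage.mode(pae) <- "double"
  dimnames(pae) <- NULL
  structure(list(plddt = plddt, pae = pae, chain_map = as.character(chain_map)),
            class = "confidence_bundle")
}

#' @export
print.confidence_bundle <- function(x, ...) {
  cat("confidence_bundle: ", length(x$plddt), " residues (chains ",
      paste(unique(x$chain_map), collapse = ", "), "); mean pLDDT ",
      sprintf("%.1f", mean(x$plddt)), "\n", sep = "")
  invisible(x)
}

# Resolve a 'text or path' argument into a file path bio3d can read.
as_pdb_file <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
  tf
}

#' Read a binder-target complex from PDB ATOM records
#'
#' Retains Calpha atoms only. Alternate locations are resolved by taking the
#' first-listed record for each residue; insertion codes are rejected.
#'
#' @param pdb Path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @param binder_chain Label of the binder chain.
#' @param target_chains Character vector of target chain labels.
#' @return A [complex_structure()].
#' @export
read_structure <- function(pdb, binder_chain, target_chains) {
  file <- as_pdb_file(pdb)
  p <- suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE))
  at <- p$atom[p$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  wanted <- c(binder_chain, target_chains)
  for (cid in wanted) {
    if (!any(at$chain == cid, na.rm = TRUE))
      stop("chain '", cid, "' not found in PDB input")
  }
  build_chain <- function(cid) {
    rows <- at[!is.na(at$chain) & at$chain == cid, , drop = FALSE]
    if (any(!is.na(rows$insert)))
      stop("insertion codes are not supported (chain ", cid, ", residue(s) ",
           paste(unique(rows$resno[!is.na(rows$insert)]), collapse = ", "), ")")
    # first-listed alternate location wins, per atom name within a residue
    key <- paste(rows$resno, rows$elety)
    rows <- rows[!duplicated(key), , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    no_ca <- setdiff(unique(rows$resno), ca$resno)
    if (length(no_ca))
      stop("residue(s) lacking a CA atom in chain ", cid, ": ",
           paste(no_ca, collapse = ", "))
    ca <- ca[order(ca$resno), , drop = FALSE]
    chain_structure(cid, ca$resno, ca$resid,
                    cbind(ca$x, ca$y, ca$z))
  }
  chains <- lapply(wanted, build_chain)
  complex_structure(chains, binder_chain, target_chains)
}

#' Write a complex as PDB ATOM records
#'
#' Emits one CA ATOM record per residue at standard PDB precision (0.001 A),
#' chains in stored order.
#'
#' @param x A [complex_structure()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure <- function(x, path = NULL) {
  serial <- 0L
  lines <- unlist(lapply(x$chains, function(ch) {
    n <- length(ch$residue_numbers)
    out <- character(n)
    for (i in seq_len(n)) {
      serial <<- serial + 1L
      out[i] <- sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, ch$residue_names[i], ch$chain_id, ch$residue_numbers[i],
        ch$ca_coords[i, 1], ch$ca_coords[i, 2], ch$ca_coords[i, 3])
    }
    out
  }), use.names = FALSE)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a confidence bundle from JSON
#'
#' The payload must carry a `plddt` array and a square `pae` matrix whose
#' side equals the length of `chain_map`.
#'
#' @param json Path to a JSON file or JSON text.
#' @param chain_map Character vector of per-residue chain labels.
#' @return A [confidence_bundle()].
#' @export
read_confidence <- function(json, chain_map) {
  src <- if (length(json) == 1L && !grepl("[{\n]", json) && file.exists(json))
    json else paste(json, collapse = "\n")
  payload <- jsonlite::fromJSON(src)
  if (is.null(payload$plddt) || is.null(payload$pae))
    stop("confidence JSON must contain 'plddt' and 'pae'")
  pae <- payload$pae
  if (is.list(pae)) {
    lens <- lengths(pae)
    if (length(unique(lens)) != 1L) stop("pae matrix rows have unequal length")
    pae <- do.call(rbind, pae)
  }
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stop("pae matrix must be square, got ", nrow(pae), " x ", ncol(pae))
  confidence_bundle(payload$plddt, pae, chain_map)
}

#' Write a confidence bundle to JSON
#'
#' @param bundle A [confidence_bundle()].
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
write_confidence <- function(bundle, path = NULL) {
  txt <- jsonlite::toJSON(list(plddt = bundle$plddt, pae = bundle$pae),
                          digits = I(17), matrix = "rowmajor")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a design score table from TSV
#'
#' Score tables are tab-delimited with a header naming a `design_id` column;
#' remaining columns are numeric metrics, except an optional `target_name`
#' (character) and `label` (logical experimental-binder flag). Empty metric
#' cells become `NA` (an absent metric), never zero.
#'
#' @param tsv Path to a TSV file or TSV text.
#' @return A data frame with one row per design.
#' @export
read_score_table <- function(tsv) {
  src_is_file <- length(tsv) == 1L && !grepl("[\t\n]", tsv) && file.exists(tsv)
  df <- if (src_is_file)
    utils::read.delim(tsv, check.names = FALSE, colClasses = "character",
                      na.strings = NULL)
  else
    utils::read.delim(text = paste(tsv, collapse = "\n"), check.names = FALSE,
                      colClasses = "character", na.strings = NULL)
  if (!"design_id" %in% names(df))
    stop("score table must have a 'design_id' column")
  dup <- df$design_id[duplicated(df$design_id)]
  if (length(dup))
    stop("duplicate design_id: ", paste(unique(dup), collapse = ", "))
  logical_tokens <- c("TRUE", "True", "true", "FALSE", "False", "false")
  for (col in names(df)) {
    if (col %in% c("design_id", "target_name")) next
    vals <- df[[col]]
    nonempty <- !(vals %in% c("", "NA"))
    if (all(vals[nonempty] %in% logical_tokens) && any(nonempty)) {
      parsed <- rep(NA, length(vals))
      parsed[nonempty] <- vals[nonempty] %in% c("TRUE", "True", "true")
      df[[col]] <- parsed
      next
    }
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(nonempty & is.na(num))
    if (length(bad) && length(bad) < sum(nonempty))
      stop("non-numeric cell in column '", col, "', row ", bad[1],
           " (design ", df$design_id[bad[1]], ")")
    # a column with no numeric cells at all is a string annotation column
    df[[col]] <- if (length(bad)) ifelse(nonempty, vals, NA_character_) else num
  }
  df
}

#' Write a design score table to TSV
#'
#' Numeric metrics are written with up to 10 significant digits so that a
#' write/read cycle is lossless well past the 6 significant digits the
#' format guarantees; `NA` cells are written empty.
#'
#' @param records Data frame with a `design_id` column.
#' @param path Optional output file; when `NULL` the TSV text is returned.
#' @return Character scalar of TSV text (invisibly when `path` is given).
#' @export
write_score_table <- function(records, path = NULL) {
  stopifnot("design_id" %in% names(records))
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- formatC(out[[col]], format = "g", digits = 10)
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    } else {
      v <- as.character(out[[col]])
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}
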