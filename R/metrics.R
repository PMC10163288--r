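# Optimal superposition and the structure/confidence metrics used to screen
# designed binders: monomer Calpha RMSD (Type-I failures), target-aligned
# complex RMSD and interface pAE (Type-II failures), binder pLDDT.

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform (rotation + translation, reflections
#' excluded) minimising the RMSD between paired coordinate sets. The
#' returned transform maps `moving` onto `reference`:
#' `x' = x %*% t(rotation) + translation`.
#'
#' @param moving Numeric matrix (n x 3) of coordinates to transform.
#' @param reference Numeric matrix (n x 3) of coordinates to fit onto.
#' @return An object of class `superposition` with elements `rotation`
#'   (3 x 3, determinant +1), `translation` (length-3) and `rmsd` (Angstrom
#'   over the fitted atoms).
#' @export
kabsch_superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference))
    stop("coordinate sets differ in size: ", nrow(moving), " vs ", nrow(reference))
  if (nrow(moving) < 3L)
    stop("at least 3 points are required for superposition")
  mu_m <- colMeans(moving); mu_r <- colMeans(reference)
  M <- sweep(moving, 2, mu_m); R0 <- sweep(reference, 2, mu_r)
  C <- crossprod(M, R0)                      # 3x3 cross-covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                         # degenerate: either branch optimal
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(mu_r - rot %*% mu_m)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords Numeric matrix (n x 3).
#' @return Transformed coordinates.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over fitted set\n", x$rmsd))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "chain_structure")) x$ca_coords else as.matrix(x)
}

#' Monomer Calpha RMSD between a prediction and its design
#'
#' RMSD after optimal superposition of the predicted chain on the designed
#' chain, residues paired strictly by order. Disagreement flags a possible
#' Type-I failure (the sequence does not fold to the designed monomer).
#'
#' @param predicted,designed [chain_structure()] objects (or n x 3 matrices)
#'   with equal residue counts.
#' @return RMSD in Angstrom.
#' @export
monomer_ca_rmsd <- function(predicted, designed) {
  a <- coords_of(predicted); b <- coords_of(designed)
  if (nrow(a) != nrow(b))
    stop("residue counts differ: ", nrow(a), " vs ", nrow(b))
  kabsch_superpose(a, b)$rmsd
}

#' Target-aligned complex Calpha RMSD
#'
#' Superposes the predicted complex onto the designed complex using the
#' target-chain Calpha atoms only, then evaluates the RMSD over the
#' requested scope without refitting. Fitting on the target (never the
#' binder) measures whether the binder lands correctly relative to the
#' target; large values flag Type-II failures.
#'
#' @param predicted,designed [complex_structure()] objects with matching
#'   chain labels and per-chain residue counts.
#' @param scope `"all_residues"` (default) or `"binder_only"`.
#' @return RMSD in Angstrom.
#' @export
complex_aligned_rmsd <- function(predicted, designed,
                                 scope = c("all_residues", "binder_only")) {
  scope <- match.arg(scope)
  for (cid in names(designed$chains)) {
    if (!cid %in% names(predicted$chains))
      stop("predicted complex lacks chain '", cid, "'")
    if (nrow(predicted$chains[[cid]]$ca_coords) !=
        nrow(designed$chains[[cid]]$ca_coords))
      stop("residue count mismatch in chain '", cid, "'")
  }
  tchains <- designed$target_chain_ids
  if (!length(tchains)) stop("designed complex has no target chains to align on")
  sp <- kabsch_superpose(ca_matrix(predicted, tchains),
                         ca_matrix(designed, tchains))
  keep <- if (scope == "binder_only") designed$binder_chain_id
          else names(designed$chains)
  pred <- apply_superposition(sp, ca_matrix(predicted, keep))
  des <- ca_matrix(designed, keep)
  sqrt(mean(rowSums((pred - des)^2)))
}

#' Mean binder pLDDT
#'
#' Arithmetic mean of the per-residue pLDDT over the binder chain; target
#' residues never contribute. High values indicate the predictor is
#' confident the binder sequence folds as designed.
#'
#' @param bundle A [confidence_bundle()].
#' @param binder_chain Binder chain label.
#' @return Mean pLDDT in [0, 100].
#' @export
binder_plddt <- function(bundle, binder_chain) {
  sel <- bundle$chain_map == binder_chain
  if (!any(sel))
    stop("no residues for binder chain '", binder_chain, "' in chain map")
  mean(bundle$plddt[sel])
}

#' Interface predicted aligned error (pAE_interaction)
#'
#' The mean of the two interchain block means of the pAE matrix: the mean
#' over entries `pae[binder, target]` and the mean over `pae[target,
#' binder]`, averaged. With equal block cardinalities this equals the grand
#' mean over all ordered interchain residue pairs; intrachain entries and
#' the diagonal never contribute, and the result is invariant to
#' transposing the matrix. Low values are the single most discriminative
#' predictor that a designed binder actually binds.
#'
#' @param bundle A [confidence_bundle()].
#' @param binder_chain Binder chain label; all other chains are treated as
#'   target.
#' @return pAE_interaction in Angstrom.
#' @export
pae_interaction <- function(bundle, binder_chain) {
  b <- bundle$chain_map == binder_chain
  if (!any(b))
    stop("no residues for binder chain '", binder_chain, "' in chain map")
  if (all(b))
    stop("bundle contains only the binder chain; no interchain pairs")
  (mean(bundle$pae[b, !b]) + mean(bundle$pae[!b, b])) / 2
}
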