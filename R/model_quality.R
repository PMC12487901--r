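#' Mean pLDDT of a predicted model file
#'
#' Structure prediction pipelines store the per-residue pLDDT in the
#' B-factor column of the deposited coordinates. This reads a model in PDB
#' format and averages the B-factor over C-alpha atoms (one value per
#' residue), per chain and overall. Models without C-alpha atoms (e.g.
#' coarse or non-protein stubs) fall back to averaging over all atoms.
#'
#' @param path Path to a PDB-format model file.
#' @return A list with `chain_mean_plddt` (named numeric, one entry per
#'   chain in file order), `mean_plddt` (mean over all residues) and
#'   `n_residues`.
#' @export
mean_plddt_from_model <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("no ATOM records in model file: ", path, call. = FALSE)
  }
  if (all(is.na(atoms$b))) {
    stop("model file has no B-factor values: ", path, call. = FALSE)
  }
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) ca <- atoms
  chains <- unique(ca$chain)
  chain_means <- vapply(chains, function(ch) mean(ca$b[ca$chain == ch]),
                        numeric(1))
  list(chain_mean_plddt = setNames(chain_means, chains),
       mean_plddt = mean(ca$b),
       n_residues = nrow(ca))
}

#' Confidence tier of a homodimer prediction
#'
#' Homodimer models are tiered on their interface predicted template
#' modeling score (ipTM): `"good"` at ipTM >= 0.8, `"confident"` at
#' ipTM >= 0.5, otherwise `"none"`. Boundaries are inclusive by default.
#'
#' @param iptm Numeric vector of ipTM scores in \[0, 1\].
#' @param confident_min,good_min Tier cutoffs.
#' @param inclusive Whether a score exactly at a cutoff attains the tier.
#' @return An ordered factor with levels `none < confident < good`.
#' @export
tier_homodimer <- function(iptm, confident_min = 0.5, good_min = 0.8,
                           inclusive = TRUE) {
  if (anyNA(iptm)) stop("missing ipTM score", call. = FALSE)
  stopifnot(all(iptm >= 0 & iptm <= 1))
  cmp <- if (inclusive) `>=` else `>`
  tier <- ifelse(cmp(iptm, good_min), "good",
                 ifelse(cmp(iptm, confident_min), "confident", "none"))
  factor(tier, levels = c("none", "confident", "good"), ordered = TRUE)
}

#' Detect a pLDDT gain of the homodimer over the monomer
#'
#' The gain is the maximum of the two dimer chain-mean pLDDTs minus the
#' monomer mean pLDDT; a prediction is flagged when the gain strictly
#' exceeds `delta` units. Such gains indicate folds that only become
#' confident in the dimeric arrangement.
#'
#' @param monomer_plddt Monomer mean pLDDT (single value, 0-100).
#' @param dimer_chain_plddt Numeric vector of length 2: per-chain mean
#'   pLDDT of the homodimer.
#' @param delta Gain threshold in pLDDT units (strict).
#' @return A list with `gain` and `flagged`.
#' @export
dimer_gain <- function(monomer_plddt, dimer_chain_plddt, delta = 5) {
  if (length(dimer_chain_plddt) != 2) {
    stop("homodimer must have exactly two chains", call. = FALSE)
  }
  stopifnot(length(monomer_plddt) == 1,
            monomer_plddt >= 0, monomer_plddt <= 100,
            all(dimer_chain_plddt >= 0 & dimer_chain_plddt <= 100))
  gain <- max(dimer_chain_plddt) - monomer_plddt
  list(gain = gain, flagged = gain > delta)
}

#' Matched-pair model quality comparison between two databases
#'
#' For pairs of near-identical proteins modelled in two databases (matched
#' upstream, e.g. at >90% sequence identity and coverage), reports the
#' fraction of pairs where this database's model scores higher, and the
#' fraction where it scores more than `delta` pLDDT units higher.
#'
#' @param plddt_ours,plddt_theirs Numeric vectors of matched mean pLDDT
#'   scores (equal length, non-empty).
#' @param delta Unit threshold for the large-gain fraction (strict).
#' @return A list with `n_pairs`, `frac_higher` and `frac_gain_over_delta`.
#' @export
matched_pair_compare <- function(plddt_ours, plddt_theirs, delta = 5) {
  if (length(plddt_ours) == 0) stop("no matched pairs", call. = FALSE)
  stopifnot(length(plddt_ours) == length(plddt_theirs))
  diff <- plddt_ours - plddt_theirs
  list(n_pairs = length(diff),
       frac_higher = mean(diff > 0),
       frac_gain_over_delta = mean(diff > delta))
}
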