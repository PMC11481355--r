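#' @name pocketselect
#' @title Ligand-guided main-pocket selection
#'
#' @description
#' The main binding pocket is the pocket that holds the bound ligand.
#' Coverage of a pocket is the fraction of ligand heavy atoms lying inside
#' at least one of its alpha spheres. Three selection scenarios are
#' distinguished: a single pocket with non-zero coverage; a pocket dominating
#' the runner-up by at least the dominance margin (default 10 percentage
#' points of coverage); and a near-tie, resolved towards the highest
#' druggability score among the pockets within the margin of the maximum.
NULL

#' Ligand coverage of a pocket
#'
#' Fraction of ligand heavy atoms whose center lies inside at least one
#' alpha sphere of the pocket (within `inclusion_margin` of the sphere
#' radius).
#'
#' @param pocket an `enz_pocket`.
#' @param ligand an `enz_ligand`.
#' @param inclusion_margin extra allowance in angstroms added to each sphere
#'   radius (default 0: strictly inside).
#' @return fraction in [0,1].
#' @export
ligand_coverage <- function(pocket, ligand, inclusion_margin = 0) {
  la <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  stopifnot(nrow(la) >= 1)
  cen <- as.matrix(pocket$spheres[, c("x", "y", "z")])
  r <- pocket$spheres$radius + inclusion_margin
  nn <- RANN::nn2(cen, la, k = min(30L, nrow(cen)))
  inside <- rowSums(nn$nn.dists <= matrix(r[nn$nn.idx], nrow = nrow(la))) > 0
  mean(inside)
}

#' Select the main (ligand-defined) pocket
#'
#' @param pockets non-empty list of `enz_pocket` with computed features.
#' @param ligand an `enz_ligand`.
#' @param dominance_margin coverage-difference margin separating the
#'   dominant-coverage scenario from the druggability tie-break, in absolute
#'   coverage fraction (default 0.10). A difference of exactly the margin
#'   counts as dominant.
#' @param inclusion_margin passed to [ligand_coverage()].
#' @return a `SelectionResult` list: `pocket_id`, `scenario` (one of
#'   `"single_pocket"`, `"dominant_coverage"`, `"druggability_tiebreak"`)
#'   and `coverage_by_pocket` (named numeric).
#' @export
select_main_pocket <- function(pockets, ligand, dominance_margin = 0.10,
                               inclusion_margin = 0) {
  stopifnot(length(pockets) >= 1)
  cov <- vapply(pockets, ligand_coverage, numeric(1), ligand = ligand,
                inclusion_margin = inclusion_margin)
  ids <- vapply(pockets, function(p) p$pocket_id, integer(1))
  names(cov) <- ids
  if (all(cov == 0))
    stop_enzport("enzport_ligand_outside_pockets",
                 "ligand not present in any pocket")
  nonzero <- which(cov > 0)
  if (length(nonzero) == 1) {
    return(list(pocket_id = ids[nonzero], scenario = "single_pocket",
                coverage_by_pocket = cov))
  }
  ord <- order(-cov)
  top <- ord[1]; runner <- ord[2]
  # a gap of exactly the margin counts as dominant (1e-9 guards rounding)
  if (cov[top] - cov[runner] >= dominance_margin - 1e-9) {
    return(list(pocket_id = ids[top], scenario = "dominant_coverage",
                coverage_by_pocket = cov))
  }
  near <- which(cov > cov[top] - dominance_margin + 1e-9 & cov > 0)
  drug <- vapply(pockets[near], function(p)
    p$features[["druggability_score"]], numeric(1))
  pick <- near[which.max(drug)]
  list(pocket_id = ids[pick], scenario = "druggability_tiebreak",
       coverage_by_pocket = cov)
}

#' Overlap between pocket lining and essential-residue annotations
#'
#' @param pocket an `enz_pocket`.
#' @param essential_residues data frame with columns `chain_id` and
#'   `residue_number` (see [read_essential_residues()]).
#' @return list: `matched` (TRUE when the intersection is non-empty) and
#'   `n_matched` (its size). An empty annotation set yields
#'   `matched = FALSE` with a warning (the "no annotation" case).
#' @export
annotation_overlap <- function(pocket, essential_residues) {
  if (is.null(essential_residues) || nrow(essential_residues) == 0) {
    warning("empty essential-residue set: no annotation available")
    return(list(matched = FALSE, n_matched = 0L))
  }
  lin <- paste(pocket$lining_residues$chain_id,
               pocket$lining_residues$residue_number)
  ess <- unique(paste(essential_residues$chain_id,
                      essential_residues$residue_number))
  n <- sum(ess %in% lin)
  list(matched = n > 0, n_matched = as.integer(n))
}

#' Read essential residues from CSV
#'
#' Expected columns: `chain` (or `chain_id`), `resnum` (or
#' `residue_number`), optional `source`.
#'
#' @param path CSV path.
#' @return data frame with `chain_id`, `residue_number`, `source`.
#' @export
read_essential_residues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  chain <- df[["chain_id"]] %||% df[["chain"]]
  resno <- df[["residue_number"]] %||% df[["resnum"]]
  if (is.null(chain) || is.null(resno))
    stop_enzport("enzport_config_error",
                 "essential-residue CSV needs chain and resnum columns")
  data.frame(chain_id = as.character(chain),
             residue_number = as.integer(resno),
             source = df[["source"]] %||% rep(NA_character_, nrow(df)))
}

#' Write a selection result as JSON
#'
#' @param selection result of [select_main_pocket()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(list(
    pocket_id = unname(selection$pocket_id),
    scenario = selection$scenario,
    coverage_by_pocket = as.list(selection$coverage_by_pocket)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
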