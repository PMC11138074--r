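# Residue-level contact analysis of a multi-chain complex structure:
# which residues of the assayed subunit sit close to its binding partners,
# and how that interface overlaps with mutational intolerance.

#' Minimum heavy-atom distances from each query-chain residue to partner chains
#'
#' Reads a PDB (or mmCIF) structure, keeps the first model, resolves
#' alternate locations by highest occupancy, drops hydrogens, and computes
#' for every residue of the query chain the minimum Euclidean distance over
#' atom pairs to each partner chain. A residue is in contact with a partner
#' when that minimum is strictly below `cutoff` angstroms.
#'
#' @param structure Path to a PDB/mmCIF file, or a `bio3d` `pdb` object.
#' @param query_chain Chain identifier of the assayed subunit.
#' @param partner_chains Character vector of partner chain identifiers.
#' @param cutoff Contact cutoff in angstroms (default 5, strict `<`).
#' @return Data frame with `resno`, `resid`, one `dist_<chain>` and
#'   `contact_<chain>` column per partner, and `any_contact`.
#' @export
min_residue_distances <- function(structure, query_chain, partner_chains,
                                  cutoff = 5) {
  pdb <- if (inherits(structure, "pdb")) {
    structure
  } else if (grepl("\\.cif$", structure, ignore.case = TRUE)) {
    bio3d::read.cif(structure, multi = FALSE)
  } else {
    bio3d::read.pdb(structure, multi = FALSE)
  }
  atoms <- pdb$atom
  atoms <- atoms[is.na(atoms$elesy) | atoms$elesy != "H", , drop = FALSE]
  # resolve altlocs: keep the highest-occupancy copy of each atom
  alt <- !is.na(atoms$alt) & atoms$alt != ""
  if (any(alt)) {
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    ord <- order(key, -replace(atoms$o, is.na(atoms$o), 1))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  }
  missing <- setdiff(c(query_chain, partner_chains), unique(atoms$chain))
  if (length(missing)) {
    stop("chain(s) not in structure: ", paste(missing, collapse = ", "))
  }
  q <- atoms[atoms$chain == query_chain, , drop = FALSE]
  if (!nrow(q)) stop("query chain has no heavy atoms")
  qxyz <- as.matrix(q[, c("x", "y", "z")])
  residues <- sort(unique(q$resno))
  out <- data.frame(resno = residues,
                    resid = q$resid[match(residues, q$resno)])
  for (pc in partner_chains) {
    p <- atoms[atoms$chain == pc, , drop = FALSE]
    pxyz <- as.matrix(p[, c("x", "y", "z")])
    # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
    cross <- outer(rowSums(qxyz^2), rowSums(pxyz^2), "+") -
      2 * tcrossprod(qxyz, pxyz)
    atom_min <- sqrt(pmax(apply(cross, 1, min), 0))
    res_min <- vapply(residues,
                      function(r) min(atom_min[q$resno == r]), numeric(1))
    out[[paste0("dist_", pc)]] <- res_min
    out[[paste0("contact_", pc)]] <- res_min < cutoff
  }
  contact_cols <- grep("^contact_", names(out), value = TRUE)
  out$any_contact <- rowSums(as.matrix(out[contact_cols])) > 0
  out
}

#' Overlap between interface contacts and mutational intolerance
#'
#' @param contacts Output of [min_residue_distances()].
#' @param intolerance Output of [residue_intolerance()] (joined on
#'   `position`/`resno`).
#' @return A list with `n_intolerant`, `n_contact`,
#'   `n_intolerant_in_contact`, `fraction_intolerant_in_contact`, and
#'   `n_tolerant_in_contact` (the complementary check that tolerant
#'   residues avoid the interface).
#' @export
intolerance_contact_overlap <- function(contacts, intolerance) {
  common <- intersect(contacts$resno, intolerance$position)
  if (!length(common)) stop("no shared residue indices")
  in_contact <- contacts$any_contact[match(common, contacts$resno)]
  intol <- intolerance$intolerant[match(common, intolerance$position)]
  tol <- intolerance$tolerant[match(common, intolerance$position)]
  list(n_intolerant = sum(intol, na.rm = TRUE),
       n_contact = sum(in_contact, na.rm = TRUE),
       n_intolerant_in_contact = sum(intol & in_contact, na.rm = TRUE),
       fraction_intolerant_in_contact =
         sum(intol & in_contact, na.rm = TRUE) / max(1, sum(intol, na.rm = TRUE)),
       n_tolerant_in_contact = sum(tol & in_contact, na.rm = TRUE))
}
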