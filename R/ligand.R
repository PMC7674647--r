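#' @title Nucleotide ligand extraction
#' @name ligand
#' @description Extraction of (p)ppGpp ligands from structure models with
#'   canonical atom naming, completeness bookkeeping and moiety mapping.
NULL

#' Canonical atom groups of the (p)ppGpp ligands
#'
#' Guanine ring, ribose, 5'-phosphate chain (alpha/beta and, for pppGpp,
#' gamma) and 3'-phosphate chain, in PDB component naming.
#' @return Named list of character vectors.
#' @export
ligand_atom_groups <- function() {
  list(
    guanine = c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6",
                "N7", "C8", "N9"),
    ribose = c("C1'", "C2'", "C3'", "C4'", "C5'",
               "O2'", "O3'", "O4'", "O5'"),
    phosphate_5prime = c("PA", "O1A", "O2A", "O3A",
                         "PB", "O1B", "O2B", "O3B"),
    gamma_phosphate = c("PG", "O1G", "O2G", "O3G"),
    phosphate_3prime = c("PC", "O1C", "O2C", "O3C",
                         "PD", "O1D", "O2D", "O3D"))
}

#' Moiety of each canonical ligand atom
#'
#' Maps canonical atom names to one of `guanine`, `ribose`,
#' `phosphate_5prime`, `phosphate_3prime` (the gamma phosphate rolls up
#' into `phosphate_5prime`).
#'
#' @param atom_names Character vector of canonical atom names.
#' @return Character vector of moiety labels.
#' @export
moiety_of <- function(atom_names) {
  g <- ligand_atom_groups()
  map <- c(stats::setNames(rep("guanine", length(g$guanine)), g$guanine),
           stats::setNames(rep("ribose", length(g$ribose)), g$ribose),
           stats::setNames(rep("phosphate_5prime",
                               length(g$phosphate_5prime) +
                                 length(g$gamma_phosphate)),
                           c(g$phosphate_5prime, g$gamma_phosphate)),
           stats::setNames(rep("phosphate_3prime",
                               length(g$phosphate_3prime)),
                           g$phosphate_3prime))
  out <- map[atom_names]
  if (anyNA(out)) {
    stop("atom(s) outside all moieties: ",
         paste(atom_names[is.na(out)], collapse = ", "))
  }
  unname(out)
}

#' Known (p)ppGpp ligand residue codes
#' @return Character vector (uppercase).
#' @export
ppgpp_ligand_codes <- function() c("G4P", "C1Z", "0O2")

#' Extract nucleotide ligands from a structure model
#'
#' One `ligand_instance` is returned per matching hetero residue (multiple
#' copies, e.g. in different chains, give multiple instances). Residue
#' code matching is case-insensitive, so `0o2` and `0O2` are equivalent.
#' Instances with missing ribose ring atoms are flagged incomplete but
#' still returned.
#'
#' @param model A `structure_model`.
#' @param codes Ligand residue codes to extract (default: the (p)ppGpp
#'   codes plus any residue named `LIG`).
#' @return List of `ligand_instance` objects; empty list when no residue
#'   matches. Each instance carries `ligand_code`, `chain`, `resseq`,
#'   `atoms` (data.frame) and `completeness` (named logical per group).
#' @export
extract_ligands <- function(model, codes = ppgpp_ligand_codes()) {
  atoms <- model$atoms
  codes <- toupper(codes)
  sel <- atoms$hetero & toupper(atoms$resname) %in% codes
  if (!any(sel)) return(list())
  sub <- atoms[sel, , drop = FALSE]
  key <- paste(sub$chain, sub$resseq, sub$icode, toupper(sub$resname))
  lapply(split(seq_len(nrow(sub)), factor(key, unique(key))), function(idx) {
    ligand_instance(sub[idx, , drop = FALSE], pdb_id = model$pdb_id)
  }) |> unname()
}

#' Construct a ligand instance from an atom table
#'
#' @param atoms Atom data.frame of one residue.
#' @param pdb_id Parent structure identifier.
#' @return A `ligand_instance`.
#' @export
ligand_instance <- function(atoms, pdb_id = "model") {
  groups <- ligand_atom_groups()
  code <- toupper(atoms$resname[1])
  completeness <- vapply(groups, function(g) all(g %in% atoms$name),
                         logical(1))
  out <- list(ligand_code = code,
              pdb_id = pdb_id,
              chain = atoms$chain[1],
              resseq = atoms$resseq[1],
              atoms = atoms,
              completeness = completeness)
  class(out) <- "ligand_instance"
  out
}

#' @export
print.ligand_instance <- function(x, ...) {
  miss <- names(x$completeness)[!x$completeness]
  cat(sprintf("<ligand_instance %s %s/%s%d: %d atoms%s>\n",
              x$ligand_code, x$pdb_id, x$chain, x$resseq, nrow(x$atoms),
              if (length(miss)) paste0("; missing: ",
                                       paste(miss, collapse = ", "))
              else ""))
  invisible(x)
}

#' Does the ligand carry a gamma phosphate?
#' @param ligand A `ligand_instance`.
#' @return Logical.
#' @export
has_gamma_phosphate <- function(ligand) {
  any(ligand_atom_groups()$gamma_phosphate %in% ligand$atoms$name)
}

lig_xyz <- function(ligand, name) {
  i <- match(name, ligand$atoms$name)
  if (is.na(i)) stop("ligand atom not present: ", name)
  c(ligand$atoms$x[i], ligand$atoms$y[i], ligand$atoms$z[i])
}

#' Count hydrogen-bond-capable nitrogen and oxygen atoms
#'
#' Counts the ligand's N and O atoms whose template typing carries donor
#' or acceptor capability. For a complete ppGpp this census is (5, 17):
#' all five guanine nitrogens and all seventeen oxygens (carbonyl,
#' hydroxyl, ring, ester-bridge and phosphate) are polar.
#'
#' @param ligand A `ligand_instance`.
#' @param require_complete Error when a canonical atom group is missing
#'   (default). With `FALSE` the census runs on the atoms present, e.g.
#'   for a bare guanine base.
#' @return Named integer vector `c(n_nitrogen, n_oxygen)`.
#' @export
count_hbond_capable_atoms <- function(ligand, require_complete = TRUE) {
  required <- c("guanine", "ribose", "phosphate_5prime", "phosphate_3prime")
  missing <- required[!ligand$completeness[required]]
  if (require_complete && length(missing) > 0) {
    stop("ligand incomplete; missing group(s): ",
         paste(missing, collapse = ", "))
  }
  typed <- assign_atom_types(ligand$atoms, quiet = TRUE)
  capable <- typed$donor | typed$acceptor
  c(n_nitrogen = sum(capable & typed$element == "N"),
    n_oxygen = sum(capable & typed$element == "O"))
}

#' Check geometric invariants of a ligand instance
#'
#' Guanine ring atoms (when present) must be planar within 0.2 Angstrom
#' RMS of the best-fit plane, and consecutive ribose ring bonds must fall
#' in [1.3, 1.7] Angstrom.
#'
#' @param ligand A `ligand_instance`.
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_ligand <- function(ligand) {
  gat <- intersect(ligand_atom_groups()$guanine, ligand$atoms$name)
  if (length(gat) >= 4) {
    X <- do.call(rbind, lapply(gat, lig_xyz, ligand = ligand))
    Xc <- sweep(X, 2, colMeans(X))
    rms <- sqrt(mean((Xc %*% svd(Xc)$v[, 3])^2))
    if (rms > 0.2) stop(sprintf("guanine ring not planar: %.3f A RMS", rms))
  }
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  if (all(ring %in% ligand$atoms$name)) {
    for (i in seq_along(ring)) {
      a <- lig_xyz(ligand, ring[i])
      b <- lig_xyz(ligand, ring[if (i == length(ring)) 1 else i + 1])
      d <- vnorm(a - b)
      if (d < 1.3 || d > 1.7) {
        stop(sprintf("ribose ring bond %s-%s out of range: %.3f A",
                     ring[i], ring[if (i == length(ring)) 1 else i + 1], d))
      }
    }
  }
  code <- ligand$ligand_code
  if (code %in% c("C1Z", "0O2") && ligand$completeness["phosphate_5prime"] &&
      !has_gamma_phosphate(ligand)) {
    stop("pppGpp ligand code without gamma phosphate")
  }
  if (code == "G4P" && has_gamma_phosphate(ligand)) {
    stop("ppGpp ligand code with gamma phosphate present")
  }
  invisible(TRUE)
}
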