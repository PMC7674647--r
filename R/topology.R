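#' @title Covalent topology of the canonical ligands
#' @name topology
#' @description Bond list over canonical (p)ppGpp atom names, used for
#'   hydrogen-bond angle proxies (donor antecedents), the intramolecular
#'   hydrogen-bond bond-separation filter and the rotatable-bond counter.
NULL

LIGAND_BONDS <- local({
  b <- rbind(
    # guanine
    c("N9", "C8"), c("C8", "N7"), c("N7", "C5"), c("C5", "C4"),
    c("C4", "N9"), c("C4", "N3"), c("N3", "C2"), c("C2", "N1"),
    c("N1", "C6"), c("C6", "C5"), c("C6", "O6"), c("C2", "N2"),
    # glycosidic + ribose
    c("C1'", "N9"),
    c("C1'", "C2'"), c("C2'", "C3'"), c("C3'", "C4'"),
    c("C4'", "O4'"), c("O4'", "C1'"),
    c("C2'", "O2'"), c("C3'", "O3'"), c("C4'", "C5'"), c("C5'", "O5'"),
    # 5' chain (alpha, beta, optional gamma)
    c("O5'", "PA"), c("PA", "O1A"), c("PA", "O2A"), c("PA", "O3A"),
    c("O3A", "PB"), c("PB", "O1B"), c("PB", "O2B"), c("PB", "O3B"),
    c("O3B", "PG"), c("PG", "O1G"), c("PG", "O2G"), c("PG", "O3G"),
    # 3' chain
    c("O3'", "PC"), c("PC", "O1C"), c("PC", "O2C"), c("PC", "O3C"),
    c("O3C", "PD"), c("PD", "O1D"), c("PD", "O2D"), c("PD", "O3D"))
  data.frame(a = b[, 1], b = b[, 2], stringsAsFactors = FALSE)
})

#' Bond list restricted to the atoms actually present
#' @param atom_names Character vector of canonical atom names.
#' @return data.frame with columns `a`, `b`.
#' @export
ligand_bond_list <- function(atom_names) {
  keep <- LIGAND_BONDS$a %in% atom_names & LIGAND_BONDS$b %in% atom_names
  LIGAND_BONDS[keep, , drop = FALSE]
}

#' Minimum covalent bond separation between ligand atoms
#'
#' Breadth-first shortest path counts over the canonical bond graph.
#'
#' @param atom_names Atoms present.
#' @return Integer matrix of bond counts (Inf when disconnected), with
#'   dimnames.
#' @export
ligand_bond_separation <- function(atom_names) {
  bonds <- ligand_bond_list(atom_names)
  n <- length(atom_names)
  adj <- lapply(stats::setNames(atom_names, atom_names), function(a) {
    c(bonds$b[bonds$a == a], bonds$a[bonds$b == a])
  })
  D <- matrix(Inf, n, n, dimnames = list(atom_names, atom_names))
  for (s in atom_names) {
    D[s, s] <- 0
    frontier <- s
    k <- 0
    while (length(frontier) > 0) {
      k <- k + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- k
      frontier <- nxt
    }
  }
  D
}

# donor antecedents (the bonded heavy atom defining the proxy angle) for
# the standard protein residues; ligand antecedents come from LIGAND_BONDS
PROTEIN_ANTECEDENTS <- c(
  "N" = "CA", "OXT" = "C", "O" = "C",
  "ARG|NE" = "CZ", "ARG|NH1" = "CZ", "ARG|NH2" = "CZ",
  "LYS|NZ" = "CE", "SER|OG" = "CB", "THR|OG1" = "CB", "TYR|OH" = "CZ",
  "HIS|ND1" = "CG", "HIS|NE2" = "CE1", "ASN|ND2" = "CG",
  "GLN|NE2" = "CD", "TRP|NE1" = "CE2", "CYS|SG" = "CB")

#' Position of the antecedent (bonded heavy atom) of a donor/acceptor
#'
#' Used as the vertex for the hydrogen-free angle proxy: with no explicit
#' hydrogens the angle antecedent-donor...acceptor stands in for the
#' D-H...A angle. Returns `NULL` when no antecedent can be located (the
#' angle criterion is then treated as satisfied).
#'
#' @param atoms Atom data.frame holding the donor's residue.
#' @param i Row index of the donor atom.
#' @return Numeric 3-vector or `NULL`.
#' @export
antecedent_position <- function(atoms, i) {
  nm <- atoms$name[i]
  res <- toupper(atoms$resname[i])
  same_res <- which(atoms$chain == atoms$chain[i] &
                      atoms$resseq == atoms$resseq[i] &
                      toupper(atoms$resname) == res)
  find <- function(target) {
    j <- same_res[match(target, atoms$name[same_res])]
    if (length(j) == 0 || is.na(j)) NULL else c(atoms$x[j], atoms$y[j], atoms$z[j])
  }
  if (res %in% c("G4P", "C1Z", "0O2") || nm %in% LIGAND_BONDS$a ||
      nm %in% LIGAND_BONDS$b) {
    nb <- c(LIGAND_BONDS$b[LIGAND_BONDS$a == nm],
            LIGAND_BONDS$a[LIGAND_BONDS$b == nm])
    for (t in nb) {
      p <- find(t)
      if (!is.null(p)) return(p)
    }
    return(NULL)
  }
  key <- paste(res, nm, sep = "|")
  t <- unname(PROTEIN_ANTECEDENTS[key])
  if (is.na(t)) t <- unname(PROTEIN_ANTECEDENTS[nm])
  if (is.na(t)) return(NULL)
  find(t)
}
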