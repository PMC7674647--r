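#' @title Synthetic nucleotide construction
#' @name synthetic-ligand
#' @description Builds ppGpp/pppGpp ligands at prescribed conformations
#'   (sugar pucker P and nu_max, glycosidic chi, backbone gamma) from
#'   idealized internal coordinates, for ground-truth testing of the
#'   conformational and interaction analyses.
NULL

# planar guanine template (x, y, Angstrom; z = 0), derived from an
# MMFF94-optimised 9-methylguanine projected onto its best-fit plane.
# C1X marks the glycosidic attachment direction and is not emitted.
GUANINE_TEMPLATE <- local({
  m <- matrix(c(
    -0.8484, -1.1617,
     0.0000,  0.0000,
    -0.4094,  1.3078,
     0.6099,  2.1444,
     1.7158,  1.3311,
     1.3639,  0.0000,
     2.1740, -1.0856,
     3.4431, -0.7777,
     4.3778, -1.7618,
     3.9230,  0.5167,
     3.1256,  1.6538,
     3.6069,  2.7826), ncol = 2, byrow = TRUE)
  rownames(m) <- c("C1X", "N9", "C8", "N7", "C5", "C4", "N3", "C2",
                   "N2", "N1", "C6", "O6")
  cbind(m, z = 0)
})

# substituent internal coordinates measured on an idealized guanosine:
# torsion offsets (degrees) fix the D-ribose/beta-anomer chirality
RIBOSE_SUBST <- list(
  off_N9 = 120.4, off_O2p = -121.7, off_O3p = 116.6, off_C5p = -117.8,
  b_N9 = 1.455, b_O2p = 1.42, b_O3p = 1.43, b_C5p = 1.53, b_O5p = 1.43,
  a_N9 = 112.9, a_O2p = 110.0, a_O3p = 109.5, a_C5p = 112.7, a_O5p = 110.0)

RING_ORDER <- c("C1'", "C2'", "C3'", "C4'", "O4'")
RING_BOND_TARGETS <- c(1.528, 1.528, 1.528, 1.430, 1.430)

#' Build a closed ribose ring at a prescribed pucker
#'
#' Starts from a planar pentagon displaced out of plane along the
#' pseudorotation mode and refines atom positions by least squares
#' against the ideal endocyclic torsions `nu_j = nu_max cos(P + 144(j-2))`
#' and the target ring bond lengths. The measured pseudorotation of the
#' result is required to be within 2 degrees of the request (ring closure
#' makes the ideal torsions only approximately attainable).
#'
#' @param P_target Phase angle, degrees.
#' @param nu_max_target Puckering amplitude, degrees; must lie in (5, 60).
#' @param seed Unused source of determinism, kept for interface stability;
#'   the construction is fully deterministic.
#' @return 5 x 3 coordinate matrix with rownames C1', C2', C3', C4', O4'.
#' @export
build_ribose <- function(P_target, nu_max_target, seed = 1L) {
  if (!is.finite(P_target) || !is.finite(nu_max_target)) {
    stop("build_ribose: targets must be finite")
  }
  if (nu_max_target <= 5 || nu_max_target >= 60) {
    stop("build_ribose: nu_max_target must lie in (5, 60) degrees")
  }
  nu_t <- ideal_ring_torsions(P_target, nu_max_target)
  radius <- mean(RING_BOND_TARGETS) / (2 * sin(pi / 5))
  q <- nu_max_target / 102.5   # empirical amplitude conversion, degrees -> A
  best <- NULL
  for (phase in c(0, 90, 180, 270)) {
    th <- 2 * pi * (0:4) / 5
    X0 <- cbind(radius * cos(th), radius * sin(th),
                q * sqrt(2 / 5) * cos(deg2rad(P_target + phase) + 2 * 2 * pi * (0:4) / 5))
    fit <- stats::optim(as.vector(X0), ring_objective, nu_t = nu_t,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    # residual ~0.1-0.6 deg^2 is the inherent closure/ideal-torsion gap;
    # alternative phase starts only matter if a start fell into a poor
    # local minimum
    if (best$value < 2) break
  }
  X <- matrix(best$par, 5, 3)
  rownames(X) <- RING_ORDER
  meas <- ring_torsions(X)
  ps <- pseudorotation(meas)
  dP <- abs(wrap180(ps$P - P_target))
  dA <- abs(ps$nu_max - nu_max_target)
  if (dP > 2 || dA > 2) {
    stop(sprintf(paste0("build_ribose: closure refinement missed targets ",
                        "(P %.2f vs %.2f, nu_max %.2f vs %.2f, obj %.3g)"),
                 ps$P, P_target, ps$nu_max, nu_max_target, best$value))
  }
  X
}

ring_torsions <- function(X) {
  idx <- stats::setNames(seq_len(5), RING_ORDER)
  vapply(RIBOSE_TORSION_ATOMS, function(atoms) {
    dihedral(X[idx[atoms[1]], ], X[idx[atoms[2]], ],
             X[idx[atoms[3]], ], X[idx[atoms[4]], ])
  }, numeric(1))
}

ring_objective <- function(par, nu_t) {
  X <- matrix(par, 5, 3)
  d <- vapply(1:5, function(i) {
    j <- if (i == 5) 1 else i + 1
    sqrt(sum((X[i, ] - X[j, ])^2))
  }, numeric(1))
  tors <- tryCatch(ring_torsions(X), error = function(e) NULL)
  if (is.null(tors)) return(1e6)
  sum(((d - RING_BOND_TARGETS) * 200)^2) + sum(wrap180(tors - nu_t)^2)
}

#' Specification of a synthetic (p)ppGpp ligand
#'
#' @param P_target,nu_max_target Ribose pseudorotation targets (degrees).
#' @param chi_target Glycosidic torsion target (degrees).
#' @param gamma_target Backbone gamma torsion target (degrees).
#' @param include_gamma_phosphate `TRUE` builds pppGpp (code C1Z), `FALSE`
#'   ppGpp (code G4P).
#' @param ligand_code Override the residue code.
#' @return A `ligand_spec` list.
#' @export
ligand_spec <- function(P_target = 188.23, nu_max_target = 36.24,
                        chi_target = -99.58, gamma_target = -172.55,
                        include_gamma_phosphate = FALSE,
                        ligand_code = NULL) {
  stopifnot(is.finite(chi_target), is.finite(gamma_target))
  if (is.null(ligand_code)) {
    ligand_code <- if (include_gamma_phosphate) "C1Z" else "G4P"
  }
  structure(list(P_target = P_target, nu_max_target = nu_max_target,
                 chi_target = chi_target, gamma_target = gamma_target,
                 include_gamma_phosphate = include_gamma_phosphate,
                 ligand_code = toupper(ligand_code)),
            class = "ligand_spec")
}

#' Build a complete synthetic nucleotide at a prescribed conformation
#'
#' Assembles ribose (via [build_ribose()]), guanine (rigid planar template
#' attached at the requested chi), the free 2'-OH oxygen, and the 5'- and
#' 3'-phosphate chains from ideal internal coordinates. The result passes
#' the ligand geometric invariants and round-trips through
#' [compute_torsions()]/[pseudorotation()] within the declared tolerances
#' (2 degrees for the ring, 0.5 for chi).
#'
#' @param spec A `ligand_spec`.
#' @param chain,resseq Residue identifiers for the emitted atoms.
#' @return A `ligand_instance`.
#' @export
build_nucleotide <- function(spec = ligand_spec(), chain = "L", resseq = 1L) {
  S <- RIBOSE_SUBST
  ring <- build_ribose(spec$P_target, spec$nu_max_target)
  pos <- list()
  for (nm in rownames(ring)) pos[[nm]] <- ring[nm, ]
  tor_ref <- function(a, b, c, d) dihedral(pos[[a]], pos[[b]], pos[[c]], pos[[d]])
  put <- function(nm, a, b, c, bond, angle, torsion) {
    pos[[nm]] <<- place_atom(pos[[a]], pos[[b]], pos[[c]], bond, angle, torsion)
  }
  # exocyclic sugar substituents; torsion offsets encode chirality
  put("O2'", "C4'", "C3'", "C2'", S$b_O2p, S$a_O2p,
      tor_ref("C4'", "C3'", "C2'", "C1'") + S$off_O2p)
  put("O3'", "C1'", "C2'", "C3'", S$b_O3p, S$a_O3p,
      tor_ref("C1'", "C2'", "C3'", "C4'") + S$off_O3p)
  put("C5'", "C2'", "C3'", "C4'", S$b_C5p, S$a_C5p,
      tor_ref("C2'", "C3'", "C4'", "O4'") + S$off_C5p)
  put("O5'", "C3'", "C4'", "C5'", S$b_O5p, S$a_O5p, spec$gamma_target)
  put("N9", "C3'", "C2'", "C1'", S$b_N9, S$a_N9,
      tor_ref("C3'", "C2'", "C1'", "O4'") + S$off_N9)
  # guanine anchors from chi, then rigid template fit on N9/C4/C8
  tpl <- GUANINE_TEMPLATE
  d_N9C4 <- vnorm(tpl["C4", ] - tpl["N9", ])
  d_N9C8 <- vnorm(tpl["C8", ] - tpl["N9", ])
  a_C4 <- vector_angle(tpl["C1X", ], tpl["N9", ], tpl["C4", ])
  a_C8 <- vector_angle(tpl["C1X", ], tpl["N9", ], tpl["C8", ])
  anchor_C4 <- place_atom(pos[["O4'"]], pos[["C1'"]], pos[["N9"]],
                          d_N9C4, a_C4, spec$chi_target)
  anchor_C8 <- place_atom(pos[["O4'"]], pos[["C1'"]], pos[["N9"]],
                          d_N9C8, a_C8, wrap180(spec$chi_target + 180))
  fit <- kabsch_superpose(tpl[c("N9", "C4", "C8"), ],
                          rbind(pos[["N9"]], anchor_C4, anchor_C8))
  gua <- sweep(tpl %*% fit$rotation, 2, fit$translation, `+`)
  for (nm in setdiff(rownames(tpl), c("C1X", "N9"))) pos[[nm]] <- gua[nm, ]
  # 5' phosphate chain (alpha, beta, optionally gamma)
  put("PA", "C4'", "C5'", "O5'", 1.60, 120, 180)
  put("O3A", "C5'", "O5'", "PA", 1.60, 104, 180)
  put("O1A", "C5'", "O5'", "PA", 1.48, 110, 60)
  put("O2A", "C5'", "O5'", "PA", 1.48, 110, -60)
  put("PB", "O5'", "PA", "O3A", 1.60, 125, 180)
  b_O3B <- if (spec$include_gamma_phosphate) 1.60 else 1.48
  put("O3B", "PA", "O3A", "PB", b_O3B, 109, 180)
  put("O1B", "PA", "O3A", "PB", 1.48, 109, 60)
  put("O2B", "PA", "O3A", "PB", 1.48, 109, -60)
  if (spec$include_gamma_phosphate) {
    put("PG", "O3A", "PB", "O3B", 1.60, 125, 180)
    put("O1G", "PB", "O3B", "PG", 1.48, 109, 60)
    put("O2G", "PB", "O3B", "PG", 1.48, 109, -60)
    put("O3G", "PB", "O3B", "PG", 1.48, 109, 180)
  }
  # 3' phosphate chain
  put("PC", "C2'", "C3'", "O3'", 1.60, 120, 140)
  put("O3C", "C3'", "O3'", "PC", 1.60, 104, 180)
  put("O1C", "C3'", "O3'", "PC", 1.48, 110, 60)
  put("O2C", "C3'", "O3'", "PC", 1.48, 110, -60)
  put("PD", "O3'", "PC", "O3C", 1.60, 125, 180)
  put("O1D", "PC", "O3C", "PD", 1.48, 109, 60)
  put("O2D", "PC", "O3C", "PD", 1.48, 109, -60)
  put("O3D", "PC", "O3C", "PD", 1.48, 109, 180)
  X <- do.call(rbind, pos)
  atoms <- data.frame(
    serial = seq_len(nrow(X)),
    name = names(pos),
    altloc = "",
    resname = spec$ligand_code,
    chain = chain,
    resseq = as.integer(resseq),
    icode = "",
    x = X[, 1], y = X[, 2], z = X[, 3],
    occ = 1, bfac = 0,
    element = vapply(names(pos), guess_element, character(1)),
    hetero = TRUE,
    stringsAsFactors = FALSE)
  atoms$water <- FALSE
  atoms$metal <- FALSE
  lig <- ligand_instance(atoms, pdb_id = "synthetic")
  validate_ligand(lig)
  lig
}
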