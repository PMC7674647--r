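#' @title Nucleotide conformational analysis
#' @name conformation
#' @description Glycosidic and backbone torsions, ribose pseudorotation
#'   (phase angle P and puckering amplitude nu_max), sugar pucker classes
#'   and syn/anti classification.
NULL

# endocyclic torsion definitions nu0..nu4, each a quadruple of ring atoms
RIBOSE_TORSION_ATOMS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'"))

PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                    "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                    "C1'-endo", "C2'-exo")

#' Compute the glycosidic, gamma and endocyclic torsions of a ligand
#'
#' chi is O4'-C1'-N9-C4 (purine convention), gamma is O5'-C5'-C4'-C3',
#' and nu0..nu4 are the five ribose ring torsions.
#'
#' @param ligand A `ligand_instance` with the required atoms present.
#' @return Named numeric vector `chi`, `gamma`, `nu0`..`nu4`, degrees in
#'   (-180, 180].
#' @export
compute_torsions <- function(ligand) {
  defs <- c(list(chi = c("O4'", "C1'", "N9", "C4"),
                 gamma = c("O5'", "C5'", "C4'", "C3'")),
            RIBOSE_TORSION_ATOMS)
  vapply(names(defs), function(tn) {
    atoms <- defs[[tn]]
    missing <- setdiff(atoms, ligand$atoms$name)
    if (length(missing) > 0) {
      stop(sprintf("cannot compute torsion %s: missing atom(s) %s",
                   tn, paste(missing, collapse = ", ")))
    }
    ps <- lapply(atoms, lig_xyz, ligand = ligand)
    dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

#' Ribose pseudorotation parameters from endocyclic torsions
#'
#' Classical Altona-Sundaralingam treatment:
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' with 180 degrees added when `nu2 < 0`, P wrapped to \[0, 360), and
#' `nu_max = nu2 / cos P`. The pucker class is the 36-degree bin of P,
#' starting with C3'-endo at \[0, 36); the hemisphere is north for
#' P in \[270, 360) or \[0, 90), south otherwise.
#'
#' @param nu Numeric vector of the five torsions `nu0..nu4` in degrees, or
#'   a named vector/list containing elements `nu0`..`nu4` (extra elements
#'   such as `chi` are ignored).
#' @return List with `P`, `nu_max` (degrees), `pucker_class`,
#'   `hemisphere`.
#' @export
pseudorotation <- function(nu) {
  if (!is.null(names(nu)) && all(paste0("nu", 0:4) %in% names(nu))) {
    nu <- as.numeric(unlist(nu[paste0("nu", 0:4)]))
  }
  nu <- as.numeric(nu)
  stopifnot(length(nu) == 5)
  if (all(abs(nu) < 1e-9)) stop("pseudorotation undefined for a planar ring")
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  if (abs(nu[3]) < 1e-12) {
    # nu2 = 0: the phase sits on the P = 90/270 meridian
    P <- if (num >= 0) 90 else 270
    nu_max <- abs(num) / (2 * (sin(deg2rad(36)) + sin(deg2rad(72))))
  } else {
    P <- rad2deg(atan(num / den))
    if (nu[3] < 0) P <- P + 180
    P <- P %% 360
    nu_max <- nu[3] / cos(deg2rad(P))
  }
  list(P = P,
       nu_max = nu_max,
       pucker_class = PUCKER_CLASSES[floor(P / 36) %% 10 + 1],
       hemisphere = if (P >= 270 || P < 90) "north" else "south")
}

#' Classify a glycosidic torsion as syn or anti
#'
#' anti for chi (mod 360) in \[90, 270), syn otherwise; the boundaries are
#' half-open, so exactly 90 is anti and exactly 270 (= -90) is syn.
#'
#' @param chi Glycosidic torsion(s) in degrees.
#' @return Character vector `"syn"`/`"anti"`.
#' @export
classify_glycosidic <- function(chi) {
  stopifnot(all(is.finite(chi)))
  m <- chi %% 360
  ifelse(m >= 90 & m < 270, "anti", "syn")
}

#' Percentage frequency distribution of a torsion series
#'
#' Bins cover (-180, 180] with right-closed bins of width `bin_width`
#' (which must divide 360); percentages sum to 100.
#'
#' @param series Torsion angles in degrees.
#' @param bin_width Bin width in degrees.
#' @return data.frame with `lower`, `upper`, `mid` (degrees) and
#'   `percent`.
#' @export
torsion_distribution <- function(series, bin_width = 10) {
  if (length(series) == 0) stop("torsion_distribution: empty series")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop("bin_width must divide 360")
  }
  x <- wrap180(series)
  nb <- round(360 / bin_width)
  idx <- ceiling((x + 180) / bin_width)   # right-closed bins over (-180, 180]
  idx[idx < 1] <- 1
  counts <- tabulate(idx, nbins = nb)
  lower <- -180 + bin_width * (seq_len(nb) - 1)
  data.frame(lower = lower,
             upper = lower + bin_width,
             mid = lower + bin_width / 2,
             percent = 100 * counts / length(x))
}

#' Full conformational summary of one ligand
#'
#' @param ligand A `ligand_instance`.
#' @param id Row identifier (defaults to pdb id / code).
#' @return One-row data.frame with `id`, `chi`, `gamma`, `nu0`..`nu4`,
#'   `P`, `nu_max`, `pucker_class`, `glycosidic_class`.
#' @export
conformation_summary <- function(ligand,
                                 id = paste(ligand$pdb_id,
                                            ligand$ligand_code, sep = "_")) {
  tor <- compute_torsions(ligand)
  ps <- pseudorotation(tor)
  data.frame(id = id,
             chi = tor[["chi"]], gamma = tor[["gamma"]],
             nu0 = tor[["nu0"]], nu1 = tor[["nu1"]], nu2 = tor[["nu2"]],
             nu3 = tor[["nu3"]], nu4 = tor[["nu4"]],
             P = ps$P, nu_max = ps$nu_max,
             pucker_class = ps$pucker_class,
             glycosidic_class = classify_glycosidic(tor[["chi"]]),
             stringsAsFactors = FALSE)
}

#' Pucker/torsion table from a torsion TSV
#'
#' Reads a table with columns `id`, `nu0`..`nu4` and optional `chi`,
#' `gamma`, and appends `P`, `nu_max`, `pucker_class` and (when `chi` is
#' present) `glycosidic_class`.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return Augmented data.frame.
#' @export
pucker_table <- function(path) {
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- paste0("nu", 0:4)
  if (!all(need %in% names(tab))) {
    stop("torsion table must have columns ", paste(need, collapse = ", "))
  }
  ps <- lapply(seq_len(nrow(tab)), function(i) {
    pseudorotation(as.numeric(tab[i, need]))
  })
  tab$P <- vapply(ps, `[[`, numeric(1), "P")
  tab$nu_max <- vapply(ps, `[[`, numeric(1), "nu_max")
  tab$pucker_class <- vapply(ps, `[[`, character(1), "pucker_class")
  tab$hemisphere <- vapply(ps, `[[`, character(1), "hemisphere")
  if ("chi" %in% names(tab)) {
    tab$glycosidic_class <- classify_glycosidic(tab$chi)
  }
  tab
}

#' Ideal endocyclic torsions for a given pseudorotation state
#'
#' `nu_j = nu_max * cos(P + 144 (j - 2))`, j = 0..4.
#'
#' @param P Phase angle, degrees.
#' @param nu_max Puckering amplitude, degrees.
#' @return Numeric vector `nu0..nu4`.
#' @export
ideal_ring_torsions <- function(P, nu_max) {
  j <- 0:4
  stats::setNames(nu_max * cos(deg2rad(P + 144 * (j - 2))), paste0("nu", j))
}

#' Count freely rotatable single bonds of a (p)ppGpp ligand
#'
#' Simple convention: acyclic single bonds between heavy atoms where both
#' ends carry at least one further heavy-atom neighbour (terminal P-O
#' bonds to one-coordinate oxygens are not counted, ring bonds are not
#' counted). The convention is exposed, not asserted against any
#' published count.
#'
#' @param ligand A `ligand_instance`.
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(ligand) {
  bonds <- ligand_bond_list(ligand$atoms$name)
  nm <- ligand$atoms$name
  ring_atoms <- list(c("C1'", "C2'", "C3'", "C4'", "O4'"),
                     c("N9", "C8", "N7", "C5", "C4"),
                     c("C4", "C5", "C6", "N1", "C2", "N3"))
  in_same_ring <- function(a, b) {
    any(vapply(ring_atoms, function(r) a %in% r && b %in% r, logical(1)))
  }
  deg <- table(c(bonds$a, bonds$b))
  n <- 0L
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    if (!(a %in% nm) || !(b %in% nm)) next
    if (in_same_ring(a, b)) next
    if (deg[[a]] < 2 || deg[[b]] < 2) next
    n <- n + 1L
  }
  n
}
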