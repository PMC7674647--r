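#' @title Conformer ensemble descriptors
#' @name ensemble
#' @description Per-atom fluctuation (RMSF), per-frame RMSD, radius of
#'   gyration, solvent-accessible surface area (Shrake-Rupley) and
#'   intramolecular hydrogen-bond counts over ordered coordinate sets,
#'   e.g. trajectory frames stored as multi-model PDB.
NULL

#' Construct a conformer ensemble
#'
#' @param frames List of n_atoms x 3 coordinate matrices (identical atom
#'   ordering), or a 3-d array `[atom, xyz, frame]`.
#' @param atoms Atom data.frame describing the shared atom list.
#' @param labels Optional per-frame labels (times, temperatures).
#' @return A `conformer_ensemble`.
#' @export
conformer_ensemble <- function(frames, atoms = NULL, labels = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  n <- unique(vapply(frames, nrow, integer(1)))
  if (length(n) != 1) stop("conformers must share one atom list")
  structure(list(frames = frames, atoms = atoms, labels = labels),
            class = "conformer_ensemble")
}

#' Read a multi-model PDB as a conformer ensemble
#' @param source Path or PDB text (see [parse_pdb()]).
#' @return A `conformer_ensemble`.
#' @export
read_ensemble_pdb <- function(source) {
  models <- parse_pdb(source)
  conformer_ensemble(lapply(models, coords), atoms = models[[1]]$atoms)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble: %d frames x %d atoms>\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

ens_frames <- function(ens) {
  if (inherits(ens, "conformer_ensemble")) ens$frames else ens
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF is computed on the supplied coordinates as provided (no implicit
#' superposition; set `superpose = TRUE` to least-squares fit each frame
#' to the reference first), against either the ensemble mean or the
#' first frame.
#'
#' @param ens A `conformer_ensemble` (at least two frames).
#' @param reference `"mean"` or `"frame0"`.
#' @param superpose Kabsch-fit each frame onto the reference first.
#' @return Numeric vector, per-atom RMSF in Angstrom.
#' @export
rmsf <- function(ens, reference = c("mean", "frame0"), superpose = FALSE) {
  reference <- match.arg(reference)
  frames <- ens_frames(ens)
  if (length(frames) < 2) stop("rmsf needs at least two conformers")
  ref <- if (reference == "mean") {
    Reduce(`+`, frames) / length(frames)
  } else frames[[1]]
  if (superpose) {
    frames <- lapply(frames, function(X) kabsch_superpose(X, ref)$coords)
    if (reference == "mean") ref <- Reduce(`+`, frames) / length(frames)
  }
  dev2 <- lapply(frames, function(X) rowSums((X - ref)^2))
  sqrt(Reduce(`+`, dev2) / length(frames))
}

#' Per-frame RMSD against a reference frame
#'
#' @param ens A `conformer_ensemble`.
#' @param reference Frame index used as reference (default 1).
#' @param superpose Kabsch-fit each frame first (default `TRUE`).
#' @return Numeric vector of per-frame RMSD in Angstrom.
#' @export
rmsd_series <- function(ens, reference = 1L, superpose = TRUE) {
  frames <- ens_frames(ens)
  ref <- frames[[reference]]
  vapply(frames, function(X) {
    if (superpose) {
      kabsch_superpose(X, ref)$rmsd
    } else {
      sqrt(mean(rowSums((X - ref)^2)))
    }
  }, numeric(1))
}

#' Radius of gyration
#'
#' Mass-weighted (unit masses by default)
#' `sqrt(sum m_i |r_i - r_com|^2 / sum m_i)`.
#'
#' @param X n x 3 coordinate matrix.
#' @param masses Optional per-atom masses.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(X, masses = NULL) {
  X <- as.matrix(X)
  if (is.null(masses)) masses <- rep(1, nrow(X))
  com <- colSums(X * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(X, 2, com)^2)) / sum(masses))
}

#' Per-frame radius of gyration
#' @param ens A `conformer_ensemble`.
#' @param masses Optional per-atom masses.
#' @return Numeric vector.
#' @export
rgyr_series <- function(ens, masses = NULL) {
  vapply(ens_frames(ens), radius_of_gyration, numeric(1), masses = masses)
}

# deterministic quasi-uniform unit sphere points (golden-section spiral)
sasa_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a deterministic golden-spiral point set, so
#' results are exactly reproducible for a given `n_points`.
#'
#' @param X n x 3 coordinate matrix.
#' @param elements Element symbols (for Bondi radii), or `radii` given
#'   directly.
#' @param radii Optional per-atom radii in Angstrom.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return List with `atom_area` (per-atom, Angstrom^2) and `total`.
#' @export
sasa <- function(X, elements = NULL, radii = NULL, probe = 1.4,
                 n_points = 960) {
  X <- as.matrix(X)
  if (is.null(radii)) {
    if (is.null(elements)) stop("sasa: provide elements or radii")
    radii <- vdw_radius(elements)
  }
  if (length(radii) != nrow(X)) stop("sasa: one radius per atom required")
  S <- sasa_sphere_points(n_points)
  n <- nrow(X)
  R <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(S * R[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (dij >= R[i] + R[j]) next
      if (dij < 1e-9 && abs(R[i] - R[j]) < 1e-9) {
        # exactly coincident equal spheres: count the surface once
        # (lowest atom index keeps it)
        if (j < i) { acc[] <- FALSE; break } else next
      }
      d2 <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
        (pts[, 3] - X[j, 3])^2
      acc <- acc & d2 > R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  list(atom_area = area, total = sum(area))
}

#' Per-frame SASA series
#' @param ens A `conformer_ensemble` with an atom table (for elements).
#' @param ... Passed to [sasa()].
#' @return Numeric vector of total SASA per frame.
#' @export
sasa_series <- function(ens, ...) {
  el <- ens$atoms$element
  vapply(ens_frames(ens), function(X) sasa(X, elements = el, ...)$total,
         numeric(1))
}

#' Count intramolecular hydrogen bonds in one conformer
#'
#' Donor-acceptor pairs of the ligand within the hydrogen-bond distance
#' window (angle proxy applied where an antecedent exists), excluding
#' pairs fewer than `min_separation` covalent bonds apart.
#'
#' @param ligand A `ligand_instance` (its coordinates define the
#'   conformer), or a typed atom table.
#' @param criteria An `interaction_criteria` list.
#' @param min_separation Minimum covalent bond count (default 3).
#' @return Integer count.
#' @export
count_intramolecular_hbonds <- function(ligand,
                                        criteria = interaction_criteria(),
                                        min_separation = 3) {
  at <- if (inherits(ligand, "ligand_instance")) {
    assign_atom_types(ligand$atoms, quiet = TRUE)
  } else ligand
  sep <- ligand_bond_separation(at$name)
  n <- nrow(at)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sep[at$name[i], at$name[j]] < min_separation) next
      dir1 <- at$donor[i] && at$acceptor[j]
      dir2 <- at$donor[j] && at$acceptor[i]
      if (!dir1 && !dir2) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d < criteria$hbond_dist_min || d > criteria$hbond_dist_max) next
      angs <- c()
      if (dir1) angs <- c(angs, donor_angle_proxy(
        at, i, c(at$x[j], at$y[j], at$z[j])))
      if (dir2) angs <- c(angs, donor_angle_proxy(
        at, j, c(at$x[i], at$y[i], at$z[i])))
      eff <- ifelse(is.na(angs), 180, angs)
      if (max(eff) >= criteria$hbond_angle_min) count <- count + 1L
    }
  }
  count
}

#' Per-frame intramolecular hydrogen-bond series
#' @param ens A `conformer_ensemble` whose atom table is a ligand.
#' @param criteria An `interaction_criteria` list.
#' @return Integer vector.
#' @export
intra_hb_series <- function(ens, criteria = interaction_criteria()) {
  at0 <- assign_atom_types(ens$atoms, quiet = TRUE)
  vapply(ens_frames(ens), function(X) {
    at <- at0
    at$x <- X[, 1]; at$y <- X[, 2]; at$z <- X[, 3]
    count_intramolecular_hbonds(at, criteria)
  }, integer(1))
}

#' Summary descriptors of a conformer ensemble
#'
#' @param ens A `conformer_ensemble` with atom table.
#' @param criteria An `interaction_criteria` list.
#' @param sasa_points Sphere points for the SASA series.
#' @return An `ensemble_summary` list with `rmsf`, `rmsd_series`,
#'   `rgyr_series`, `intra_hb_series`, `sasa_series`.
#' @export
ensemble_summary <- function(ens, criteria = interaction_criteria(),
                             sasa_points = 240) {
  structure(list(
    rmsf = rmsf(ens),
    rmsd_series = rmsd_series(ens),
    rgyr_series = rgyr_series(ens),
    intra_hb_series = intra_hb_series(ens, criteria),
    sasa_series = sasa_series(ens, n_points = sasa_points)),
    class = "ensemble_summary")
}
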