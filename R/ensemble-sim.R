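#' @title Glycosidic-torsion ensemble simulation
#' @name ensemble-sim
#' @description Samples syn/anti torsion ensembles from a von Mises
#'   mixture with known weights, emulating the bimodal occupancy of the
#'   glycosidic angle in solution, and produces noisy coordinate
#'   ensembles for descriptor testing.
NULL

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` degenerates to the uniform
#' circular distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap180(stats::runif(n, -180, 180)))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1
      u3 <- stats::runif(1)
      out[i] <- mu_r + sign(u3 - 0.5) * acos(f)
    }
  }
  wrap180(rad2deg(out))
}

#' Specify a syn/anti glycosidic ensemble
#'
#' @param n_frames Number of frames to draw.
#' @param syn_fraction Weight of the syn mode in \[0, 1\].
#' @param centers Mode centers in degrees, named `syn` and `anti`. The
#'   defaults sit well inside the syn (-90, 90) and anti \[90, 270) windows
#'   so that, at the default concentrations, essentially no probability
#'   mass leaks across the classification boundaries and the mixture
#'   weight is identifiable from range occupancy.
#' @param kappa Concentrations per mode (recycled).
#' @param seed Integer seed.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_frames = 1000, syn_fraction = 0.7,
                          centers = c(syn = 45, anti = -150),
                          kappa = c(12, 12), seed = 1L) {
  stopifnot(syn_fraction >= 0, syn_fraction <= 1,
            all(c("syn", "anti") %in% names(centers)))
  kappa <- rep(kappa, length.out = 2)
  structure(list(n_frames = as.integer(n_frames),
                 syn_fraction = syn_fraction, centers = centers,
                 kappa = kappa, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Sample a glycosidic torsion series from a von Mises mixture
#'
#' Reproducible for a given spec seed; the global RNG state is restored
#' on exit.
#'
#' @param spec An `ensemble_spec`.
#' @return Numeric vector of chi angles in degrees.
#' @export
sample_chi_ensemble <- function(spec = ensemble_spec()) {
  old <- local_rng(spec$seed)
  on.exit(restore_rng(old))
  comp <- stats::rbinom(spec$n_frames, 1, spec$syn_fraction)
  out <- numeric(spec$n_frames)
  n_syn <- sum(comp == 1)
  if (n_syn > 0) {
    out[comp == 1] <- rvonmises(n_syn, spec$centers[["syn"]],
                                spec$kappa[1])
  }
  if (n_syn < spec$n_frames) {
    out[comp == 0] <- rvonmises(spec$n_frames - n_syn,
                                spec$centers[["anti"]], spec$kappa[2])
  }
  out
}

#' Noisy coordinate ensemble around a ligand conformer
#'
#' Adds isotropic Gaussian displacement to every atom in every frame
#' (frame 1 is the unperturbed conformer), emulating thermal fluctuation
#' for descriptor tests with known per-atom noise.
#'
#' @param ligand A `ligand_instance`.
#' @param n_frames Number of frames.
#' @param sd Per-coordinate noise, Angstrom (recycled per atom).
#' @param seed Integer seed.
#' @return A `conformer_ensemble`.
#' @export
perturb_ensemble <- function(ligand, n_frames = 50, sd = 0.3, seed = 1L) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  X0 <- coords(ligand$atoms)
  sd <- rep(sd, length.out = nrow(X0))
  frames <- c(list(X0), lapply(seq_len(n_frames - 1), function(k) {
    X0 + matrix(stats::rnorm(length(X0), sd = sd), nrow(X0), 3)
  }))
  conformer_ensemble(frames, atoms = ligand$atoms)
}
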