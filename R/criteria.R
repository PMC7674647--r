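#' Geometric criteria for contact typing
#'
#' All thresholds of the nine-category interaction typing are explicit
#' and overridable. Hydrogen bonds: donor-acceptor distance in
#' `[hbond_dist_min, hbond_dist_max]` Angstrom with angle in
#' `[hbond_angle_min, 180]` degrees; weak hydrogen bonds are shorter than
#' `weak_hbond_dist_max` with angle below `weak_hbond_angle_max`. Van der
#' Waals contacts use Bondi radii with `vdw_slack` allowance, clashes an
#' overlap beyond `clash_overlap`. Ionic, metal-coordination, aromatic
#' (ring centroid) and polar/weak-polar distances follow the conventions
#' of structural interaction databases.
#'
#' @param ... Named overrides of the default thresholds.
#' @return An `interaction_criteria` list.
#' @export
interaction_criteria <- function(...) {
  crit <- list(
    hbond_dist_min = 2.8,
    hbond_dist_max = 3.5,
    hbond_angle_min = 120,
    weak_hbond_dist_max = 2.8,
    weak_hbond_angle_max = 120,
    vdw_slack = 0.1,
    clash_overlap = 0.4,
    ionic_dist_max = 4.0,
    metal_dist_max = 3.0,
    aromatic_centroid_max = 4.5,
    polar_dist_max = 3.5,
    weak_polar_dist_max = 4.0,
    environment_cutoff = 5.0)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(crit))
  if (length(bad) > 0) {
    stop("unknown criteria key(s): ", paste(bad, collapse = ", "))
  }
  crit[names(over)] <- over
  dists <- c("hbond_dist_min", "hbond_dist_max", "weak_hbond_dist_max",
             "vdw_slack", "clash_overlap", "ionic_dist_max",
             "metal_dist_max", "aromatic_centroid_max", "polar_dist_max",
             "weak_polar_dist_max", "environment_cutoff")
  stopifnot(all(unlist(crit[dists]) > 0),
            crit$hbond_angle_min >= 0, crit$hbond_angle_min <= 180,
            crit$weak_hbond_angle_max >= 0,
            crit$weak_hbond_angle_max <= 180)
  structure(crit, class = "interaction_criteria")
}

#' Read interaction criteria from a YAML config
#'
#' Recognised keys are exactly the fields of [interaction_criteria()];
#' an unknown key is a config error naming the key.
#'
#' @param path YAML file path.
#' @return An `interaction_criteria` list.
#' @export
read_criteria <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(interaction_criteria, vals)
}

#' Write interaction criteria to YAML
#' @param criteria An `interaction_criteria` list.
#' @param path Output path.
#' @export
write_criteria <- function(criteria, path) {
  yaml::write_yaml(unclass(criteria), path)
}

#' The nine contact categories
#' @return Character vector in canonical order.
#' @export
contact_categories <- function() {
  c("vdw_clash", "vdw", "hbond", "weak_hbond", "ionic", "metal",
    "aromatic", "polar", "weak_polar")
}
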