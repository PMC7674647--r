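#' @title Synthetic complex corpus
#' @name corpus
#' @description Generates an annotated corpus of synthetic complexes
#'   whose planted interaction patterns follow the characteristic
#'   binding-site chemistry of the four major functional classes of
#'   (p)ppGpp-binding proteins: synthetases (tyrosine stacking, arginine
#'   ionic pairs, magnesium), nucleotide-metabolic enzymes (stacking,
#'   guanine-edge hydrogen bonds, water bridges), GTPases (no stacking,
#'   no metals, O6-centred hydrogen bonding) and RNA polymerase
#'   (phosphate-centred polar and ionic contacts with magnesium).
NULL

#' Planted-contact recipes per functional class
#' @return Named list: per class, a list with `plants`, `water_bridges`
#'   and the ligand conformation (`P`, `nu_max`, `chi`, `gamma`,
#'   `gamma_phosphate`).
#' @export
class_recipes <- function() {
  list(
    synthetase = list(
      conformation = c(P = 31.47, nu_max = 36.96, chi = 171.65,
                       gamma = 61.18),
      gamma_phosphate = TRUE,
      plants = list(
        planted_contact("hbond", "O6", "SER", 3.0, 150),
        planted_contact("hbond", "O2'", "ASN", 3.0, 150,
                        donor_side = "ligand"),
        planted_contact("ionic", "O1B", "ARG", 3.8, NA),
        planted_contact("metal", "O1A", "MG", 2.1, NA),
        planted_contact("aromatic", "guanine_ring6", "TYR", 3.6, 0),
        planted_contact("vdw", "C8", "LEU", 3.25, NA)),
      water_bridges = list()),
    nucleotide_metabolic = list(
      conformation = c(P = 151.01, nu_max = 44.27, chi = 65.89,
                       gamma = -143.14),
      gamma_phosphate = FALSE,
      plants = list(
        planted_contact("hbond", "O6", "SER", 3.0, 150),
        planted_contact("hbond", "N7", "SER", 3.0, 150),
        planted_contact("ionic", "O1B", "ARG", 3.8, NA),
        planted_contact("metal", "O1A", "MG", 2.1, NA),
        planted_contact("aromatic", "guanine_ring6", "TYR", 3.6, 0),
        planted_contact("polar", "O2C", "SER", 3.3, 95)),
      water_bridges = list("O1C")),
    gtpase = list(
      conformation = c(P = 158.59, nu_max = 34.92, chi = -112.79,
                       gamma = 53.43),
      gamma_phosphate = FALSE,
      plants = list(
        planted_contact("hbond", "O6", "SER", 3.0, 150),
        planted_contact("vdw", "C8", "LEU", 3.25, NA),
        planted_contact("polar", "O2C", "SER", 3.3, 95),
        planted_contact("weak_polar", "O3D", "SER", 3.8, NA)),
      water_bridges = list()),
    rna_polymerase = list(
      conformation = c(P = 170.36, nu_max = 28.23, chi = -116.08,
                       gamma = -177.02),
      gamma_phosphate = TRUE,
      plants = list(
        planted_contact("hbond", "O6", "SER", 3.0, 150),
        planted_contact("hbond", "O1G", "SER", 3.0, 150),
        planted_contact("ionic", "O1D", "LYS", 3.8, NA),
        planted_contact("metal", "O1A", "MG", 2.1, NA),
        planted_contact("vdw", "C8", "LEU", 3.25, NA)),
      water_bridges = list()))
}

#' Build an annotated synthetic corpus
#'
#' `n_per_class` complexes per functional class, each with the class
#' recipe's planted contacts and a class-typical ligand conformation
#' (pucker and glycosidic angle jittered a few degrees around the class
#' anchor). Deterministic given `seed`.
#'
#' @param n_per_class Complexes per class (default 2).
#' @param seed Integer seed.
#' @param classes Which classes to build (default all four).
#' @param decoys Decoy atoms per complex.
#' @return List with `complexes` (each: `model`, `ligand`, `truth`,
#'   `pdb_id`, `functional_class`), `annotations` (data.frame) and
#'   `manifest` (data.frame incl. planted-truth JSON).
#' @export
build_corpus <- function(n_per_class = 2L, seed = 1L,
                         classes = names(class_recipes()), decoys = 5L) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  recipes <- class_recipes()[classes]
  complexes <- list()
  for (cl in names(recipes)) {
    rec <- recipes[[cl]]
    for (k in seq_len(n_per_class)) {
      cf <- rec$conformation
      spec <- ligand_spec(
        P_target = cf[["P"]] + stats::runif(1, -4, 4),
        nu_max_target = cf[["nu_max"]] + stats::runif(1, -2, 2),
        chi_target = cf[["chi"]] + stats::runif(1, -5, 5),
        gamma_target = cf[["gamma"]] + stats::runif(1, -5, 5),
        include_gamma_phosphate = rec$gamma_phosphate)
      lig <- build_nucleotide(spec)
      pdb_id <- sprintf("SYN_%s_%02d", toupper(substr(cl, 1, 4)), k)
      model <- build_site(
        lig,
        site_spec(plants = rec$plants, water_bridges = rec$water_bridges,
                  decoys = decoys,
                  seed = seed * 1000L + length(complexes)),
        pdb_id = pdb_id)
      complexes[[length(complexes) + 1]] <- list(
        model = model, ligand = extract_ligands(model)[[1]],
        truth = attr(model, "planted"), pdb_id = pdb_id,
        functional_class = cl)
    }
  }
  annotations <- data.frame(
    pdb_id = vapply(complexes, `[[`, character(1), "pdb_id"),
    functional_class = vapply(complexes, `[[`, character(1),
                              "functional_class"),
    stringsAsFactors = FALSE)
  manifest <- annotations
  manifest$ligand_code <- vapply(complexes, function(x)
    x$ligand$ligand_code, character(1))
  manifest$planted <- vapply(complexes, function(x) {
    as.character(jsonlite::toJSON(x$truth, digits = NA))
  }, character(1))
  list(complexes = complexes, annotations = annotations,
       manifest = manifest)
}

#' Write a corpus to PDB files plus a manifest TSV
#'
#' @param corpus Result of [build_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cx in corpus$complexes) {
    write_pdb(cx$model, file.path(dir, paste0(cx$pdb_id, ".pdb")),
              header = paste("synthetic complex", cx$pdb_id,
                             cx$functional_class))
  }
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(corpus$manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
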