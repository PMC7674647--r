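#' @title Physicochemical atom typing
#' @name atom-types
#' @description Deterministic per-atom flags (hydrogen-bond donor/acceptor,
#'   aromatic ring member, cationic, anionic, metal, hydrophobic) assigned
#'   from a bundled residue template table; unknown residues fall back to
#'   an element heuristic (N/O treated as donor+acceptor) with a warning.
NULL

.ppgpp_cache <- new.env(parent = emptyenv())

#' Load the bundled residue template table
#'
#' Columns: `residue`, `atom`, `donor`, `acceptor`, `aromatic`, `cationic`,
#' `anionic` (0/1 flags).
#'
#' @param path Optional path to an alternative template TSV.
#' @return data.frame of templates.
#' @export
load_atom_templates <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ppgpp_cache$templates)) return(.ppgpp_cache$templates)
    path <- system.file("extdata", "atom_templates.tsv", package = "ppgpp",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .ppgpp_cache$templates <- tab
  tab
}

#' Load the Bondi van der Waals radius table
#'
#' @param path Optional path to an alternative radius TSV.
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
load_bondi_radii <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ppgpp_cache$radii)) return(.ppgpp_cache$radii)
    path <- system.file("extdata", "bondi_radii.tsv", package = "ppgpp",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  r <- stats::setNames(tab$radius, toupper(tab$element))
  .ppgpp_cache$radii <- r
  r
}

vdw_radius <- function(element) {
  r <- load_bondi_radii()[toupper(element)]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Assign physicochemical types to every atom of a model
#'
#' Typing is a pure function of `(residue name, atom name, element)`.
#' Ligand residue codes `0o2` and `0O2` are treated equivalently.
#'
#' @param model A `structure_model` or atom data.frame.
#' @param templates Template table (defaults to the bundled one).
#' @param quiet Suppress the unknown-residue warning.
#' @return The atom data.frame with logical columns `donor`, `acceptor`,
#'   `aromatic`, `cationic`, `anionic`, `hydrophobic` appended (`metal` is
#'   already flagged by the parser).
#' @export
assign_atom_types <- function(model, templates = load_atom_templates(),
                              quiet = FALSE) {
  atoms <- if (inherits(model, "structure_model")) model$atoms else model
  if (!"metal" %in% names(atoms)) {
    atoms$metal <- atoms$element %in% METAL_ELEMENTS
  }
  resn <- toupper(atoms$resname)
  key <- paste(resn, atoms$name, sep = "|")
  tkey <- paste(toupper(templates$residue), templates$atom, sep = "|")
  idx <- match(key, tkey)
  flag <- function(col) {
    v <- templates[[col]][idx] == 1
    v[is.na(v)] <- FALSE
    v
  }
  atoms$donor <- flag("donor")
  atoms$acceptor <- flag("acceptor")
  atoms$aromatic <- flag("aromatic")
  atoms$cationic <- flag("cationic")
  atoms$anionic <- flag("anionic")
  # element heuristic for residues absent from the template table
  known_res <- resn %in% toupper(templates$residue)
  unk <- !known_res & !atoms$metal
  if (any(unk)) {
    if (!quiet) {
      warning("atom typing fell back to element heuristic for residue(s): ",
              paste(unique(atoms$resname[unk]), collapse = ", "))
    }
    atoms$donor[unk & atoms$element == "N"] <- TRUE
    atoms$acceptor[unk & atoms$element %in% c("N", "O")] <- TRUE
    atoms$donor[unk & atoms$element == "O"] <- TRUE
  }
  atoms$hydrophobic <- atoms$element == "C" & !atoms$donor &
    !atoms$acceptor & !atoms$cationic & !atoms$anionic
  atoms
}
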