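#' @title Corpus-level aggregation of interaction fingerprints
#' @name aggregation
#' @description Summaries across a corpus of complexes: counts per
#'   interaction category, per ligand atom, per moiety and per functional
#'   protein class. All counts are exact marginals of the underlying
#'   contact lists, so totals are conserved at every level.
NULL

FUNCTIONAL_CLASSES <- c("synthetase", "nucleotide_metabolic", "gtpase",
                        "rna_polymerase", "other", "riboswitch")

#' Load a pdb-to-functional-class map
#'
#' The bundled map covers the known (p)ppGpp complex entries; the closed
#' class vocabulary is synthetase, nucleotide_metabolic, gtpase,
#' rna_polymerase, other, riboswitch.
#'
#' @param path TSV with columns `pdb_id`, `functional_class`; default the
#'   bundled table.
#' @return data.frame.
#' @export
load_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_map.tsv", package = "ppgpp",
                        mustWork = TRUE)
  }
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pdb_id", "functional_class") %in% names(map)))
  bad <- setdiff(map$functional_class, FUNCTIONAL_CLASSES)
  if (length(bad) > 0) {
    stop("unknown functional class(es): ", paste(unique(bad), collapse = ", "))
  }
  dup <- map$pdb_id[duplicated(map$pdb_id)]
  if (length(dup) > 0) {
    conflict <- vapply(unique(dup), function(id) {
      length(unique(map$functional_class[map$pdb_id == id])) > 1
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting duplicate pdb_id in class map: ",
           paste(unique(dup)[conflict], collapse = ", "))
    }
    map <- map[!duplicated(map$pdb_id), ]
  }
  map
}

#' Total contact counts per interaction category
#'
#' @param fingerprints List of `fingerprint` objects.
#' @return Named integer vector over the nine categories.
#' @export
aggregate_by_category <- function(fingerprints) {
  if (length(fingerprints) == 0) stop("empty corpus")
  counts <- Reduce(`+`, lapply(fingerprints, `[[`, "counts_by_category"))
  counts
}

#' Contact counts per ligand atom
#'
#' The full canonical atom axis is reported, atoms without contacts as 0;
#' ring pseudo-atoms (`guanine_ring5`/`guanine_ring6`) carry the aromatic
#' contacts.
#'
#' @param fingerprints List of `fingerprint` objects.
#' @param category Optional single category filter.
#' @return Named integer vector over the atom axis.
#' @export
aggregate_by_atom <- function(fingerprints, category = NULL) {
  if (length(fingerprints) == 0) stop("empty corpus")
  axis <- c(unlist(ligand_atom_groups(), use.names = FALSE),
            names(LIGAND_RINGS))
  out <- stats::setNames(integer(length(axis)), axis)
  for (fp in fingerprints) {
    ct <- fp$contacts
    if (!is.null(category)) ct <- ct[ct$category %in% category, , drop = FALSE]
    if (nrow(ct) == 0) next
    unknown <- setdiff(unique(ct$ligand_atom), axis)
    if (length(unknown) > 0) {
      stop("unknown ligand atom name(s): ", paste(unknown, collapse = ", "))
    }
    tab <- table(ct$ligand_atom)
    out[names(tab)] <- out[names(tab)] + as.integer(tab)
  }
  out
}

#' Roll contact counts up to ligand moieties
#'
#' Moieties are guanine, ribose, phosphate_5prime (including the gamma
#' phosphate) and phosphate_3prime; counts partition the atom-level
#' counts exactly.
#'
#' @param fp A single `fingerprint` or list of them.
#' @return Matrix moiety x category.
#' @export
moiety_rollup <- function(fp) {
  fps <- if (inherits(fp, "fingerprint")) list(fp) else fp
  moieties <- c("guanine", "ribose", "phosphate_5prime", "phosphate_3prime")
  cats <- contact_categories()
  M <- matrix(0L, length(moieties), length(cats),
              dimnames = list(moieties, cats))
  for (f in fps) {
    ct <- f$contacts
    if (nrow(ct) == 0) next
    nm <- ct$ligand_atom
    nm[nm %in% names(LIGAND_RINGS)] <- "C4"  # ring pseudo-atoms are guanine
    mo <- moiety_of(nm)
    tab <- table(factor(mo, levels = moieties),
                 factor(ct$category, levels = cats))
    M <- M + as.matrix(tab)
  }
  M
}

#' Aggregate fingerprints into per-functional-class profiles
#'
#' @param fingerprints List of `fingerprint` objects.
#' @param annotations data.frame with `pdb_id` and `functional_class`
#'   (default: the bundled class map). Complexes without an annotation
#'   fall into class "other" with a warning.
#' @param include_riboswitch Keep riboswitch entries in the profile
#'   (default `FALSE`: the protein-class profiles exclude RNA receptors).
#' @param normalize `"none"` for raw occurrence counts, `"per_complex"`
#'   to divide each class by its number of member complexes.
#' @return A `class_profile`: list with `category_counts`
#'   (class x category), `guanine_atom_hbonds` (class x guanine atom,
#'   hydrogen bonds only), `moiety_counts` (class x moiety), `n_complexes`
#'   per class.
#' @export
aggregate_by_class <- function(fingerprints,
                               annotations = load_class_map(),
                               include_riboswitch = FALSE,
                               normalize = c("none", "per_complex")) {
  normalize <- match.arg(normalize)
  if (length(fingerprints) == 0) stop("empty corpus")
  ids <- vapply(fingerprints, `[[`, character(1), "pdb_id")
  cls <- annotations$functional_class[match(ids, annotations$pdb_id)]
  if (anyNA(cls)) {
    warning("unannotated complex(es) assigned to class 'other': ",
            paste(ids[is.na(cls)], collapse = ", "))
    cls[is.na(cls)] <- "other"
  }
  keep <- if (include_riboswitch) rep(TRUE, length(cls))
          else cls != "riboswitch"
  fps <- fingerprints[keep]
  cls <- cls[keep]
  classes <- intersect(FUNCTIONAL_CLASSES, unique(cls))
  cats <- contact_categories()
  gua <- ligand_atom_groups()$guanine
  moieties <- c("guanine", "ribose", "phosphate_5prime", "phosphate_3prime")
  category_counts <- matrix(0, length(classes), length(cats),
                            dimnames = list(classes, cats))
  gua_hb <- matrix(0, length(classes), length(gua),
                   dimnames = list(classes, gua))
  moiety_counts <- matrix(0, length(classes), length(moieties),
                          dimnames = list(classes, moieties))
  n_complexes <- stats::setNames(integer(length(classes)), classes)
  for (k in seq_along(fps)) {
    cl <- cls[k]
    fp <- fps[[k]]
    n_complexes[cl] <- n_complexes[cl] + 1L
    category_counts[cl, ] <- category_counts[cl, ] + fp$counts_by_category
    ct <- fp$contacts
    hb <- ct[ct$category == "hbond" & ct$ligand_atom %in% gua, , drop = FALSE]
    if (nrow(hb) > 0) {
      tab <- table(factor(hb$ligand_atom, levels = gua))
      gua_hb[cl, ] <- gua_hb[cl, ] + as.integer(tab)
    }
    moiety_counts[cl, ] <- moiety_counts[cl, ] + rowSums(moiety_rollup(fp))
  }
  if (normalize == "per_complex") {
    category_counts <- category_counts / n_complexes[rownames(category_counts)]
    gua_hb <- gua_hb / n_complexes[rownames(gua_hb)]
    moiety_counts <- moiety_counts / n_complexes[rownames(moiety_counts)]
  }
  structure(list(category_counts = category_counts,
                 guanine_atom_hbonds = gua_hb,
                 moiety_counts = moiety_counts,
                 n_complexes = n_complexes,
                 normalize = normalize),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat("<class_profile over", sum(x$n_complexes), "complexes>\n")
  print(x$category_counts)
  invisible(x)
}

#' Write a class profile to TSV and JSON
#' @param profile A `class_profile`.
#' @param prefix Output path prefix; writes `<prefix>_categories.tsv`,
#'   `<prefix>_guanine_hbonds.tsv`, `<prefix>.json`.
#' @return Invisibly, the paths written.
#' @export
write_class_profile <- function(profile, prefix) {
  p1 <- paste0(prefix, "_categories.tsv")
  p2 <- paste0(prefix, "_guanine_hbonds.tsv")
  p3 <- paste0(prefix, ".json")
  utils::write.table(profile$category_counts, p1, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(profile$guanine_atom_hbonds, p2, sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(lapply(profile[1:4], function(m) {
    if (is.matrix(m)) as.data.frame(m) else as.list(m)
  }), p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
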