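#' @title PDB structure input/output
#' @name pdb-io
#' @description Minimal fixed-column PDB reader/writer tailored to the
#'   needs of ligand conformational and interaction analysis: ATOM/HETATM,
#'   MODEL/ENDMDL (multi-model files double as conformer ensembles),
#'   alternate-location resolution, and water/metal flagging.
NULL

METAL_ELEMENTS <- c("MG", "MN", "ZN", "NA", "K", "CA", "FE", "NI", "CU", "CO")

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into one structure model per MODEL block (a
#' single model when no MODEL records are present). Alternate locations of
#' the same atom are resolved by keeping the highest-occupancy copy; on a
#' tie the altloc that sorts first alphabetically (i.e. 'A') wins.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param pdb_id Identifier attached to the returned models; defaults to
#'   the file basename or `"model"`.
#' @param keep_altlocs If `TRUE`, skip altloc resolution and return every
#'   alternate location.
#' @return A list of `structure_model` objects. Each has `pdb_id`,
#'   `model_index` and an `atoms` data.frame with columns `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`,
#'   `bfac`, `element`, `hetero`, `water`, `metal`.
#' @export
parse_pdb <- function(source, pdb_id = NULL, keep_altlocs = FALSE) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(pdb_id)) pdb_id <- sub("\\.pdb$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(pdb_id)) pdb_id <- "model"
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("parse_pdb: empty input")
  }
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  cur_index <- 0L
  seen_model_rec <- FALSE
  flush <- function() {
    if (length(cur) > 0) {
      atoms <- do.call(rbind, cur)
      models[[length(models) + 1]] <<- structure_model(
        atoms, pdb_id = pdb_id, model_index = cur_index,
        keep_altlocs = keep_altlocs)
      cur <<- list()
    }
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush()
      seen_model_rec <- TRUE
      cur_index <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      if (is.na(cur_index)) cur_index <- length(models) + 1L
    } else if (r == "ENDMDL") {
      flush()
    } else if (r == "ATOM  " || r == "HETATM") {
      cur[[length(cur) + 1]] <- parse_atom_record(lines[i], i)
    }
  }
  flush()
  if (length(models) == 0) stop("parse_pdb: no ATOM/HETATM records found")
  if (!seen_model_rec) models[[1]]$model_index <- 0L
  models
}

parse_atom_record <- function(line, lineno) {
  line <- sprintf("%-80s", line)
  num <- function(from, to, what) {
    s <- trimws(substr(line, from, to))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) && nzchar(s)) {
      stop(sprintf("parse_pdb: malformed %s field on line %d: '%s'",
                   what, lineno, s))
    }
    v
  }
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  if (anyNA(c(x, y, z))) {
    stop(sprintf("parse_pdb: missing coordinate on line %d", lineno))
  }
  occ <- num(55, 60, "occupancy"); if (is.na(occ)) occ <- 1
  bfac <- num(61, 66, "B-factor"); if (is.na(bfac)) bfac <- 0
  name <- trimws(substr(line, 13, 16))
  element <- trimws(substr(line, 77, 78))
  if (!nzchar(element)) element <- guess_element(name)
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    altloc = trimws(substr(line, 17, 17)),
    resname = trimws(substr(line, 18, 20)),
    chain = trimws(substr(line, 22, 22)),
    resseq = as.integer(num(23, 26, "residue number")),
    icode = trimws(substr(line, 27, 27)),
    x = x, y = y, z = z, occ = occ, bfac = bfac,
    element = toupper(element),
    hetero = substr(line, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
}

guess_element <- function(name) {
  # PDB names like "MG", "C1'", "O2A", "1HB'" -> element symbol
  s <- sub("^[0-9]+", "", name)
  if (toupper(s) %in% METAL_ELEMENTS && nchar(s) <= 2) return(toupper(s))
  substr(s, 1, 1)
}

#' Construct a structure model from an atom table
#'
#' @param atoms Atom data.frame (see [parse_pdb()]).
#' @param pdb_id Structure identifier.
#' @param model_index Zero-based model number.
#' @param keep_altlocs Skip altloc resolution when `TRUE`.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, pdb_id = "model", model_index = 0L,
                            keep_altlocs = FALSE) {
  if (!keep_altlocs && any(nzchar(atoms$altloc))) {
    atoms <- resolve_altlocs(atoms)
  }
  if (anyDuplicated(atoms$serial)) {
    atoms$serial <- seq_len(nrow(atoms))
  }
  atoms$water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  atoms$metal <- atoms$hetero & atoms$element %in% METAL_ELEMENTS &
    !atoms$water
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  out <- list(pdb_id = pdb_id, model_index = as.integer(model_index),
              atoms = atoms)
  class(out) <- "structure_model"
  out
}

resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname,
               atoms$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    best <- idx[order(-sub$occ, sub$altloc)][1]
    best
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s model %d: %d atoms (%d hetero, %d water, %d metal)>\n",
              x$pdb_id, x$model_index, nrow(x$atoms), sum(x$atoms$hetero),
              sum(x$atoms$water), sum(x$atoms$metal)))
  invisible(x)
}

#' Coordinates of a model or atom table as a matrix
#' @param x A `structure_model` or atom data.frame.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(x) {
  if (inherits(x, "structure_model")) x <- x$atoms
  cbind(x = x$x, y = x$y, z = x$z)
}

#' Write models to PDB format
#'
#' Multi-model lists are written with MODEL/ENDMDL blocks, so a conformer
#' ensemble round-trips through the standard format. Coordinates are
#' written with three decimals.
#'
#' @param models A `structure_model` or list of them.
#' @param path Output path; when `NULL` the lines are returned invisibly
#'   instead of written.
#' @param header Optional character vector of REMARK lines (without the
#'   leading "REMARK" tag).
#' @return Invisibly, the character vector of lines written.
#' @export
write_pdb <- function(models, path = NULL, header = NULL) {
  if (inherits(models, "structure_model")) models <- list(models)
  lines <- character()
  if (!is.null(header)) {
    lines <- c(lines, sprintf("REMARK %s", header))
  }
  multi <- length(models) > 1
  for (m in models) {
    if (multi) lines <- c(lines, sprintf("MODEL %8d", m$model_index))
    lines <- c(lines, format_atom_records(m$atoms))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_atom_records <- function(atoms) {
  rec <- ifelse(atoms$hetero, "HETATM", "ATOM  ")
  # PDB name field: element right-aligned into cols 13-14 for short names
  nm <- vapply(seq_len(nrow(atoms)), function(i) {
    n <- atoms$name[i]
    if (nchar(n) >= 4) sprintf("%-4s", substr(n, 1, 4))
    else if (nchar(atoms$element[i]) == 2) sprintf("%-4s", n)
    else sprintf(" %-3s", n)
  }, character(1))
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000, nm,
          ifelse(nzchar(atoms$altloc), atoms$altloc, " "),
          atoms$resname,
          ifelse(nzchar(atoms$chain), atoms$chain, "A"),
          atoms$resseq,
          ifelse(nzchar(atoms$icode), atoms$icode, " "),
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$bfac,
          atoms$element)
}

#' Select the protein environment of a ligand
#'
#' Returns every atom of `model` that is not part of the ligand itself and
#' lies within `cutoff` Angstrom of any ligand atom. Waters and metals are
#' included (their `water`/`metal` flags travel with the rows); the
#' distance of each environment atom to its nearest ligand atom is
#' appended as column `min_dist`.
#'
#' @param model A `structure_model`.
#' @param ligand A `ligand_instance` (see [extract_ligands()]) or an atom
#'   data.frame.
#' @param cutoff Radial cutoff in Angstrom (default 5.0).
#' @return Atom data.frame of environment atoms with `min_dist`.
#' @export
select_environment <- function(model, ligand, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  lat <- if (inherits(ligand, "ligand_instance")) ligand$atoms else ligand
  A <- coords(model)
  L <- coords(lat)
  lig_key <- paste(lat$chain, lat$resseq, lat$icode, lat$name)
  mod_key <- paste(model$atoms$chain, model$atoms$resseq,
                   model$atoms$icode, model$atoms$name)
  not_lig <- !(mod_key %in% lig_key)
  # pairwise min distance to ligand
  d2min <- rep(Inf, nrow(A))
  for (j in seq_len(nrow(L))) {
    dx <- A[, 1] - L[j, 1]; dy <- A[, 2] - L[j, 2]; dz <- A[, 3] - L[j, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    d2min <- pmin(d2min, d2)
  }
  sel <- not_lig & d2min <= cutoff^2
  env <- model$atoms[sel, , drop = FALSE]
  env$min_dist <- sqrt(d2min[sel])
  env
}
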