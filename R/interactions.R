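#' @title Non-covalent contact detection
#' @name interactions
#' @description Geometric typing of ligand-protein contacts in nine
#'   categories. Assignment per atom pair is hierarchical -- metal >
#'   ionic > hbond > weak_hbond > polar > weak_polar > vdw_clash > vdw --
#'   so every pair contributes to at most one category and marginal
#'   counts are well defined. Aromatic (ring-ring) contacts are detected
#'   on ring centroids, and water-mediated hydrogen bonds are reported as
#'   a separate bridge list.
NULL

empty_contacts <- function() {
  data.frame(ligand_atom = character(), chain = character(),
             resseq = integer(), resname = character(),
             atom = character(), category = character(),
             distance = numeric(), angle = numeric(),
             water_mediated = logical(), stringsAsFactors = FALSE)
}

#' Hydrogen-free hydrogen-bond angle proxy
#'
#' Without explicit hydrogens the D-H...A angle is approximated by the
#' angle antecedent-donor...acceptor, the antecedent being the donor's
#' bonded heavy atom. When no antecedent can be located (isolated water
#' oxygens, chain breaks) the angle criterion is treated as satisfied.
#'
#' @param atoms Atom table holding the donor.
#' @param i Donor row index.
#' @param acc Acceptor coordinates (3-vector).
#' @return Angle in degrees, or `NA` when no antecedent exists.
#' @export
donor_angle_proxy <- function(atoms, i, acc) {
  ante <- antecedent_position(atoms, i)
  if (is.null(ante)) return(NA_real_)
  vector_angle(ante, c(atoms$x[i], atoms$y[i], atoms$z[i]), acc)
}

# classify one ligand-atom / environment-atom pair; returns NULL or a
# list(category, angle)
classify_pair <- function(lig, i, env, j, d, crit) {
  if (d > crit$environment_cutoff) return(NULL)
  le <- lig$element[i]; ee <- env$element[j]
  # metal coordination: metal centre to ligand N/O
  if (isTRUE(env$metal[j])) {
    if (le %in% c("N", "O") && d <= crit$metal_dist_max) {
      return(list(category = "metal", angle = NA_real_))
    }
    return(NULL)
  }
  # ionic: cation-anion within cutoff
  if (((lig$anionic[i] && env$cationic[j]) ||
       (lig$cationic[i] && env$anionic[j])) && d <= crit$ionic_dist_max) {
    return(list(category = "ionic", angle = NA_real_))
  }
  # hydrogen-bond family: one donor, one acceptor
  dir1 <- lig$donor[i] && env$acceptor[j]   # ligand donates
  dir2 <- env$donor[j] && lig$acceptor[i]   # environment donates
  if (dir1 || dir2) {
    angles <- c()
    if (dir1) {
      angles <- c(angles, donor_angle_proxy(
        lig, i, c(env$x[j], env$y[j], env$z[j])))
    }
    if (dir2) {
      angles <- c(angles, donor_angle_proxy(
        env, j, c(lig$x[i], lig$y[i], lig$z[i])))
    }
    eff <- ifelse(is.na(angles), 180, angles)  # no antecedent: criterion passes
    best <- max(eff)
    if (d >= crit$hbond_dist_min && d <= crit$hbond_dist_max &&
        best >= crit$hbond_angle_min) {
      return(list(category = "hbond", angle = best))
    }
    if (d < crit$weak_hbond_dist_max &&
        any(eff < crit$weak_hbond_angle_max)) {
      return(list(category = "weak_hbond",
                  angle = min(eff[eff < crit$weak_hbond_angle_max])))
    }
    if (d <= crit$polar_dist_max) {
      return(list(category = "polar", angle = best))
    }
    if (d <= crit$weak_polar_dist_max) {
      return(list(category = "weak_polar", angle = best))
    }
    return(NULL)
  }
  # van der Waals on the remainder (non-hydrogen-bonding pairs)
  if (le == "H" || ee == "H") return(NULL)
  rsum <- vdw_radius(le) + vdw_radius(ee)
  if (d < rsum - crit$clash_overlap) {
    return(list(category = "vdw_clash", angle = NA_real_))
  }
  if (d <= rsum + crit$vdw_slack) {
    return(list(category = "vdw", angle = NA_real_))
  }
  NULL
}

pair_contacts <- function(lig, env, crit) {
  rows <- list()
  for (i in seq_len(nrow(lig))) {
    dx <- env$x - lig$x[i]; dy <- env$y - lig$y[i]; dz <- env$z - lig$z[i]
    dd <- sqrt(dx * dx + dy * dy + dz * dz)
    for (j in which(dd <= crit$environment_cutoff)) {
      cl <- classify_pair(lig, i, env, j, dd[j], crit)
      if (is.null(cl)) next
      rows[[length(rows) + 1]] <- data.frame(
        ligand_atom = lig$name[i], chain = env$chain[j],
        resseq = env$resseq[j], resname = env$resname[j],
        atom = env$name[j], category = cl$category,
        distance = dd[j], angle = cl$angle, water_mediated = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_contacts())
  do.call(rbind, rows)
}

#' Detect hydrogen bonds and weak hydrogen bonds
#'
#' Donor-acceptor pairs with distance in the hydrogen-bond window and
#' proxy angle at least `hbond_angle_min` are hydrogen bonds; pairs
#' shorter than `weak_hbond_dist_max` with angle below
#' `weak_hbond_angle_max` are weak hydrogen bonds.
#'
#' @param ligand_typed,env_typed Typed atom tables
#'   (see [assign_atom_types()]).
#' @param criteria An `interaction_criteria` list.
#' @return Contact data.frame.
#' @export
detect_hbonds <- function(ligand_typed, env_typed,
                          criteria = interaction_criteria()) {
  ct <- pair_contacts(ligand_typed, env_typed, criteria)
  ct[ct$category %in% c("hbond", "weak_hbond"), , drop = FALSE]
}

#' Detect van der Waals contacts and clashes
#'
#' Non-hydrogen-bonding atom pairs within the sum of their Bondi radii
#' (plus `vdw_slack`); overlap beyond `clash_overlap` is a clash.
#'
#' @inheritParams detect_hbonds
#' @return Contact data.frame.
#' @export
detect_vdw <- function(ligand_typed, env_typed,
                       criteria = interaction_criteria()) {
  ct <- pair_contacts(ligand_typed, env_typed, criteria)
  ct[ct$category %in% c("vdw", "vdw_clash"), , drop = FALSE]
}

#' Detect ionic contacts (cation-anion pairs)
#' @inheritParams detect_hbonds
#' @return Contact data.frame.
#' @export
detect_ionic <- function(ligand_typed, env_typed,
                         criteria = interaction_criteria()) {
  ct <- pair_contacts(ligand_typed, env_typed, criteria)
  ct[ct$category == "ionic", , drop = FALSE]
}

#' Detect metal coordination contacts
#'
#' Metal centres within `metal_dist_max` of ligand N/O atoms. The
#' returned frame carries an attribute `bridges`: protein-side partners
#' of the same metal (metal to protein N/O within the same cutoff),
#' reporting ligand-metal-protein bridging.
#'
#' @inheritParams detect_hbonds
#' @return Contact data.frame with attribute `bridges`.
#' @export
detect_metal <- function(ligand_typed, env_typed,
                         criteria = interaction_criteria()) {
  ct <- pair_contacts(ligand_typed, env_typed, criteria)
  ct <- ct[ct$category == "metal", , drop = FALSE]
  bridges <- list()
  metals <- which(env_typed$metal)
  for (m in metals) {
    dlig <- sqrt((ligand_typed$x - env_typed$x[m])^2 +
                   (ligand_typed$y - env_typed$y[m])^2 +
                   (ligand_typed$z - env_typed$z[m])^2)
    lig_near <- which(dlig <= criteria$metal_dist_max &
                        ligand_typed$element %in% c("N", "O"))
    if (length(lig_near) == 0) next
    denv <- sqrt((env_typed$x - env_typed$x[m])^2 +
                   (env_typed$y - env_typed$y[m])^2 +
                   (env_typed$z - env_typed$z[m])^2)
    prot <- which(denv <= criteria$metal_dist_max & !env_typed$metal &
                    !env_typed$water & env_typed$element %in% c("N", "O"))
    for (p in prot) {
      for (l in lig_near) {
        bridges[[length(bridges) + 1]] <- data.frame(
          metal = env_typed$name[m], metal_resseq = env_typed$resseq[m],
          ligand_atom = ligand_typed$name[l],
          partner_resname = env_typed$resname[p],
          partner_atom = env_typed$name[p],
          partner_resseq = env_typed$resseq[p],
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(ct, "bridges") <- if (length(bridges)) do.call(rbind, bridges)
                         else NULL
  ct
}

#' Detect polar and weak polar contacts
#'
#' Donor/acceptor pairs within `polar_dist_max` that do not meet the
#' hydrogen-bond or weak-hydrogen-bond geometry are polar; pairs out to
#' `weak_polar_dist_max` are weak polar. Pairs already classified in the
#' hydrogen-bond family are excluded.
#'
#' @inheritParams detect_hbonds
#' @return Contact data.frame.
#' @export
detect_polar <- function(ligand_typed, env_typed,
                         criteria = interaction_criteria()) {
  ct <- pair_contacts(ligand_typed, env_typed, criteria)
  ct[ct$category %in% c("polar", "weak_polar"), , drop = FALSE]
}

# ring definitions -------------------------------------------------------

LIGAND_RINGS <- list(
  guanine_ring5 = c("N9", "C8", "N7", "C5", "C4"),
  guanine_ring6 = c("C4", "C5", "C6", "N1", "C2", "N3"))

PROTEIN_RINGS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

ring_centroid_normal <- function(X) {
  c0 <- colMeans(X)
  Xc <- sweep(X, 2, c0)
  n <- svd(Xc)$v[, 3]
  list(centroid = c0, normal = n / vnorm(n))
}

#' Detect aromatic ring-ring (stacking) contacts
#'
#' Guanine 5- and 6-ring centroids against Phe/Tyr/His/Trp side-chain
#' rings of environment residues. Contacts within
#' `aromatic_centroid_max` are subclassed parallel (inter-normal angle at
#' most 30 degrees), T-shaped (at least 60) or intermediate.
#'
#' @param ligand A `ligand_instance` or typed ligand atom table.
#' @param model_atoms Full atom table of the complex (ring residues may
#'   extend beyond the selected environment).
#' @param env_typed Environment atom table defining which residues are in
#'   range.
#' @param criteria An `interaction_criteria` list.
#' @return Contact data.frame with `subclass` column.
#' @export
detect_aromatic <- function(ligand, model_atoms, env_typed,
                            criteria = interaction_criteria()) {
  lat <- if (inherits(ligand, "ligand_instance")) ligand$atoms else ligand
  out <- empty_contacts()
  out$subclass <- character()
  env_res <- unique(paste(env_typed$chain, env_typed$resseq,
                          toupper(env_typed$resname)))
  for (lr in names(LIGAND_RINGS)) {
    nm <- LIGAND_RINGS[[lr]]
    if (!all(nm %in% lat$name)) next
    LX <- do.call(rbind, lapply(nm, function(a) {
      i <- match(a, lat$name); c(lat$x[i], lat$y[i], lat$z[i])
    }))
    lg <- ring_centroid_normal(LX)
    for (key in env_res) {
      parts <- strsplit(key, " ")[[1]]
      resn <- parts[3]
      if (!resn %in% names(PROTEIN_RINGS)) next
      sel <- model_atoms$chain == parts[1] &
        model_atoms$resseq == as.integer(parts[2]) &
        toupper(model_atoms$resname) == resn
      res_atoms <- model_atoms[sel, , drop = FALSE]
      for (ring in PROTEIN_RINGS[[resn]]) {
        if (!all(ring %in% res_atoms$name)) next
        RX <- do.call(rbind, lapply(ring, function(a) {
          i <- match(a, res_atoms$name)
          c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
        }))
        pg <- ring_centroid_normal(RX)
        d <- vnorm(pg$centroid - lg$centroid)
        if (d > criteria$aromatic_centroid_max) next
        ang <- acos(min(1, abs(sum(lg$normal * pg$normal)))) * 180 / pi
        sub <- if (ang <= 30) "parallel" else if (ang >= 60) "t-shaped"
               else "intermediate"
        out <- rbind(out, data.frame(
          ligand_atom = lr, chain = parts[1],
          resseq = as.integer(parts[2]), resname = resn,
          atom = "ring", category = "aromatic", distance = d,
          angle = ang, water_mediated = FALSE, subclass = sub,
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Detect water-mediated hydrogen bonds
#'
#' A water oxygen hydrogen-bonded (hydrogen-bond distance window; angle
#' criterion vacuous for water, checked on protein donors) to both a
#' ligand atom and a protein atom yields one bridge per
#' (ligand atom, water, protein atom) triple.
#'
#' @inheritParams detect_hbonds
#' @return data.frame with one row per bridge.
#' @export
water_mediated_hbonds <- function(ligand_typed, env_typed,
                                  criteria = interaction_criteria()) {
  out <- list()
  waters <- which(env_typed$water & env_typed$element == "O")
  for (w in waters) {
    wpos <- c(env_typed$x[w], env_typed$y[w], env_typed$z[w])
    dlig <- sqrt((ligand_typed$x - wpos[1])^2 +
                   (ligand_typed$y - wpos[2])^2 +
                   (ligand_typed$z - wpos[3])^2)
    lig_ok <- which(dlig >= criteria$hbond_dist_min &
                      dlig <= criteria$hbond_dist_max &
                      (ligand_typed$donor | ligand_typed$acceptor))
    if (length(lig_ok) == 0) next
    denv <- sqrt((env_typed$x - wpos[1])^2 + (env_typed$y - wpos[2])^2 +
                   (env_typed$z - wpos[3])^2)
    prot_ok <- which(denv >= criteria$hbond_dist_min &
                       denv <= criteria$hbond_dist_max &
                       !env_typed$water & !env_typed$metal &
                       (env_typed$donor | env_typed$acceptor))
    for (l in lig_ok) {
      for (p in prot_ok) {
        out[[length(out) + 1]] <- data.frame(
          ligand_atom = ligand_typed$name[l],
          water_resseq = env_typed$resseq[w],
          chain = env_typed$chain[p], resseq = env_typed$resseq[p],
          resname = env_typed$resname[p], atom = env_typed$name[p],
          dist_ligand_water = dlig[l], dist_water_partner = denv[p],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ligand_atom = character(), water_resseq = integer(),
                      chain = character(), resseq = integer(),
                      resname = character(), atom = character(),
                      dist_ligand_water = numeric(),
                      dist_water_partner = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Full interaction fingerprint of one complex
#'
#' Runs every detector inside the environment cutoff and assembles the
#' contact list (deterministically ordered by ligand atom, then partner),
#' exact marginal counts per category and per (ligand atom, category),
#' the water-bridge list and the metal-bridge report.
#'
#' @param model A `structure_model` of the complex.
#' @param ligand A `ligand_instance` (default: first (p)ppGpp ligand in
#'   the model).
#' @param criteria An `interaction_criteria` list.
#' @return A `fingerprint` object.
#' @export
fingerprint_complex <- function(model, ligand = NULL,
                                criteria = interaction_criteria()) {
  if (is.null(ligand)) {
    ligs <- extract_ligands(model)
    if (length(ligs) == 0) stop("no (p)ppGpp ligand in model ", model$pdb_id)
    ligand <- ligs[[1]]
  }
  env <- select_environment(model, ligand, criteria$environment_cutoff)
  lig_typed <- assign_atom_types(ligand$atoms, quiet = TRUE)
  contacts <- empty_contacts()
  bridges <- NULL
  waterb <- water_mediated_hbonds(lig_typed,
                                  assign_atom_types(env, quiet = TRUE),
                                  criteria)
  if (nrow(env) > 0) {
    env_typed <- assign_atom_types(env, quiet = TRUE)
    contacts <- pair_contacts(lig_typed, env_typed, criteria)
    met <- detect_metal(lig_typed, env_typed, criteria)
    bridges <- attr(met, "bridges")
    arom <- detect_aromatic(ligand, model$atoms, env_typed, criteria)
    if (nrow(arom) > 0) {
      contacts <- rbind(contacts,
                        arom[, names(contacts), drop = FALSE])
    }
  }
  ord <- order(contacts$ligand_atom, contacts$chain, contacts$resseq,
               contacts$atom, contacts$category)
  contacts <- contacts[ord, , drop = FALSE]
  rownames(contacts) <- NULL
  cats <- contact_categories()
  counts <- stats::setNames(integer(length(cats)), cats)
  tab <- table(factor(contacts$category, levels = cats))
  counts[names(tab)] <- as.integer(tab)
  by_atom <- as.data.frame(table(
    ligand_atom = contacts$ligand_atom,
    category = factor(contacts$category, levels = cats)),
    stringsAsFactors = FALSE)
  names(by_atom)[3] <- "count"
  structure(list(pdb_id = model$pdb_id,
                 ligand_code = ligand$ligand_code,
                 contacts = contacts,
                 counts_by_category = counts,
                 counts_by_atom = by_atom,
                 water_bridges = waterb,
                 metal_bridges = bridges),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s %s: %d contacts>\n", x$pdb_id,
              x$ligand_code, nrow(x$contacts)))
  nz <- x$counts_by_category[x$counts_by_category > 0]
  if (length(nz)) {
    cat(" ", paste(names(nz), nz, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a contact list as TSV
#'
#' Columns mirror the tabular export of the analysis protocol:
#' pdb_id, ligand_code, ligand_atom, chain, resseq, resname, atom,
#' category, distance, angle, water_mediated.
#'
#' @param fp A `fingerprint`.
#' @param path Output TSV path.
#' @param criteria Criteria echoed into the header comment.
#' @return Invisibly, the written data.frame.
#' @export
write_contacts_tsv <- function(fp, path, criteria = NULL) {
  df <- cbind(pdb_id = fp$pdb_id, ligand_code = fp$ligand_code,
              fp$contacts)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(criteria)) {
    writeLines(paste0("# criteria: ",
                      paste(names(criteria), unlist(criteria),
                            sep = "=", collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
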