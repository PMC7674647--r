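# shared fixtures built in code

# minimal PDB text with n ATOM records on a line
tiny_pdb_lines <- function(coordmat, names = NULL, resname = "GLY",
                           hetero = FALSE, element = NULL) {
  n <- nrow(coordmat)
  if (is.null(names)) names <- paste0("C", seq_len(n))
  if (is.null(element)) element <- substr(names, 1, 1)
  rec <- if (hetero) "HETATM" else "ATOM  "
  sprintf("%s%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(n), names, resname, seq_len(n),
          coordmat[, 1], coordmat[, 2], coordmat[, 3], 1, 0, element)
}

# the shipped reference torsion table (curated crystal/minimised values)
reference_torsions <- function() {
  utils::read.delim(system.file("extdata", "reference_torsions.tsv",
                                package = "ppgpp"))
}

# independent brute-force contact oracle: re-checks every geometric rule
# with straight-line code, no shared helpers with the package detectors
oracle_contacts <- function(model, ligand, crit = interaction_criteria()) {
  lig <- assign_atom_types(ligand$atoms, quiet = TRUE)
  env <- assign_atom_types(
    select_environment(model, ligand, crit$environment_cutoff),
    quiet = TRUE)
  if (nrow(env) == 0) return(character(0))
  out <- character(0)
  radii <- load_bondi_radii()
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(env))) {
      d <- sqrt((lig$x[i] - env$x[j])^2 + (lig$y[i] - env$y[j])^2 +
                  (lig$z[i] - env$z[j])^2)
      if (d > crit$environment_cutoff) next
      cat_ij <- NA_character_
      if (env$metal[j]) {
        if (lig$element[i] %in% c("N", "O") && d <= crit$metal_dist_max) {
          cat_ij <- "metal"
        }
      } else if (((lig$anionic[i] && env$cationic[j]) ||
                    (lig$cationic[i] && env$anionic[j])) &&
                   d <= crit$ionic_dist_max) {
        cat_ij <- "ionic"
      } else if ((lig$donor[i] && env$acceptor[j]) ||
                   (env$donor[j] && lig$acceptor[i])) {
        angs <- c()
        if (lig$donor[i] && env$acceptor[j]) {
          a <- antecedent_position(lig, i)
          angs <- c(angs, if (is.null(a)) 180 else
            vector_angle(a, c(lig$x[i], lig$y[i], lig$z[i]),
                         c(env$x[j], env$y[j], env$z[j])))
        }
        if (env$donor[j] && lig$acceptor[i]) {
          a <- antecedent_position(env, j)
          angs <- c(angs, if (is.null(a)) 180 else
            vector_angle(a, c(env$x[j], env$y[j], env$z[j]),
                         c(lig$x[i], lig$y[i], lig$z[i])))
        }
        if (d >= crit$hbond_dist_min && d <= crit$hbond_dist_max &&
              max(angs) >= crit$hbond_angle_min) {
          cat_ij <- "hbond"
        } else if (d < crit$weak_hbond_dist_max &&
                     any(angs < crit$weak_hbond_angle_max)) {
          cat_ij <- "weak_hbond"
        } else if (d <= crit$polar_dist_max) {
          cat_ij <- "polar"
        } else if (d <= crit$weak_polar_dist_max) {
          cat_ij <- "weak_polar"
        }
      } else if (lig$element[i] != "H" && env$element[j] != "H") {
        rs <- radii[[lig$element[i]]] + radii[[env$element[j]]]
        if (d < rs - crit$clash_overlap) {
          cat_ij <- "vdw_clash"
        } else if (d <= rs + crit$vdw_slack) {
          cat_ij <- "vdw"
        }
      }
      if (!is.na(cat_ij)) {
        out <- c(out, paste(lig$name[i], env$chain[j], env$resseq[j],
                            env$name[j], cat_ij, sep = "|"))
      }
    }
  }
  sort(out)
}

fingerprint_pair_keys <- function(fp) {
  ct <- fp$contacts[fp$contacts$category != "aromatic", , drop = FALSE]
  sort(paste(ct$ligand_atom, ct$chain, ct$resseq, ct$atom, ct$category,
             sep = "|"))
}
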