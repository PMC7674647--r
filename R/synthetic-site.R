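#' @title Synthetic binding sites with planted contacts
#' @name synthetic-site
#' @description Builds toy ligand-protein complexes in which every
#'   non-covalent contact is planted at known geometry strictly inside
#'   (or outside, for decoys) the detection criteria, so detector recall
#'   and category assignment can be tested against exact ground truth.
NULL

# minimal partner fragments; the first atom is the interacting one, the
# second (when present) is its antecedent
PARTNER_FRAGMENTS <- list(
  SER = list(atoms = c("OG", "CB"), elements = c("O", "C"), bond = 1.43),
  ASN = list(atoms = c("OD1", "CG"), elements = c("O", "C"), bond = 1.23),
  LYS = list(atoms = c("NZ", "CE"), elements = c("N", "C"), bond = 1.49),
  ARG = list(atoms = c("NH1", "CZ"), elements = c("N", "C"), bond = 1.33),
  LEU = list(atoms = "CD1", elements = "C"),
  GLY = list(atoms = "CA", elements = "C"),
  HOH = list(atoms = "O", elements = "O"),
  MG = list(atoms = "MG", elements = "MG"))

#' Specify one planted contact
#'
#' @param category Target contact category.
#' @param ligand_atom Ligand anchor atom name (for `aromatic`, ignored:
#'   the guanine 6-ring is used).
#' @param partner Partner residue template name.
#' @param distance Planted distance in Angstrom.
#' @param angle Planted proxy angle in degrees (hydrogen-bond family) or
#'   inter-normal angle (aromatic).
#' @param donor_side `"partner"` or `"ligand"`: which side donates for
#'   angle-constrained plants.
#' @return A `planted_contact` list.
#' @export
planted_contact <- function(category, ligand_atom, partner = "SER",
                            distance = 3.0, angle = 150,
                            donor_side = "partner") {
  structure(list(category = category, ligand_atom = ligand_atom,
                 partner = partner, distance = distance, angle = angle,
                 donor_side = donor_side),
            class = "planted_contact")
}

#' Default nine-category plant set
#'
#' One planted contact per detectable category, on well separated ligand
#' anchors, each strictly inside its thresholds by the stated margins.
#'
#' @return List of `planted_contact`s.
#' @export
default_plants <- function() {
  list(
    planted_contact("hbond", "O6", "SER", 3.0, 150),
    planted_contact("weak_hbond", "O2'", "ASN", 2.7, 110,
                    donor_side = "ligand"),
    planted_contact("polar", "O2C", "SER", 3.3, 95),
    planted_contact("weak_polar", "O3D", "SER", 3.8, NA),
    planted_contact("ionic", "O1B", "LYS", 3.8, NA),
    planted_contact("metal", "O1A", "MG", 2.1, NA),
    planted_contact("aromatic", "guanine_ring6", "TYR", 3.6, 0),
    planted_contact("vdw", "C8", "LEU", 3.25, NA),
    planted_contact("vdw_clash", "O2D", "LEU", 2.4, NA))
}

#' Specify a synthetic binding site
#'
#' @param plants List of `planted_contact`s.
#' @param water_bridges List of ligand atom names, one bridge each
#'   (ligand-water-ASN OD1, both legs 2.9 Angstrom).
#' @param decoys Number of far (6.5-9 Angstrom) carbon decoy atoms.
#' @param seed Integer seed controlling decoy placement and any jitter.
#' @return A `site_spec` list.
#' @export
site_spec <- function(plants = default_plants(), water_bridges = list(),
                      decoys = 5L, seed = 1L) {
  structure(list(plants = plants, water_bridges = water_bridges,
                 decoys = as.integer(decoys), seed = as.integer(seed)),
            class = "site_spec")
}

fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

orthonormal_pair <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- cross3(u, a); p1 <- p1 / vnorm(p1)
  p2 <- cross3(u, p1)
  list(p1, p2)
}

# all pair contacts the partner atoms would form with the ligand
plant_contacts <- function(lig_typed, partner_atoms, crit) {
  pt <- assign_atom_types(partner_atoms, quiet = TRUE)
  got <- list()
  for (j in seq_len(nrow(pt))) {
    for (i in seq_len(nrow(lig_typed))) {
      d <- sqrt((lig_typed$x[i] - pt$x[j])^2 +
                  (lig_typed$y[i] - pt$y[j])^2 +
                  (lig_typed$z[i] - pt$z[j])^2)
      cl <- classify_pair(lig_typed, i, pt, j, d, crit)
      if (!is.null(cl)) {
        got[[length(got) + 1]] <- c(lig_typed$name[i], cl$category)
      }
    }
  }
  got
}

# verify that partner atoms form exactly the intended pair contacts with
# the ligand (ring contacts are checked by the caller)
plant_ok <- function(lig_typed, partner_atoms, intended, crit) {
  got <- plant_contacts(lig_typed, partner_atoms, crit)
  want <- lapply(intended, function(x) c(x$ligand_atom, x$category))
  if (length(got) != length(want)) return(FALSE)
  setequal(vapply(got, paste, character(1), collapse = "|"),
           vapply(want, paste, character(1), collapse = "|"))
}

partner_df <- function(res, names, elements, X, chain, resseq,
                       hetero = TRUE) {
  data.frame(serial = 0L, name = names, altloc = "", resname = res,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = X[, 1], y = X[, 2], z = X[, 3], occ = 1, bfac = 0,
             element = elements, hetero = hetero,
             water = res == "HOH",
             metal = elements %in% METAL_ELEMENTS & res != "HOH",
             stringsAsFactors = FALSE)
}

place_plant <- function(plant, ligand, lig_typed, crit, resseq) {
  frag <- PARTNER_FRAGMENTS[[plant$partner]]
  if (is.null(frag)) stop("unknown partner template: ", plant$partner)
  L <- lig_xyz(ligand, plant$ligand_atom)
  Xl <- coords(ligand$atoms)
  other <- Xl[ligand$atoms$name != plant$ligand_atom, , drop = FALSE]
  if (identical(plant$donor_side, "ligand") && !is.na(plant$angle)) {
    # direction constrained to a cone around the ligand donor's antecedent
    i <- match(plant$ligand_atom, lig_typed$name)
    ante <- antecedent_position(lig_typed, i)
    a1 <- (ante - L) / vnorm(ante - L)
    pp <- orthonormal_pair(a1)
    psis <- seq(0, 2 * pi, length.out = 37)[-37]
    dirs <- t(vapply(psis, function(psi) {
      cos(deg2rad(plant$angle)) * a1 +
        sin(deg2rad(plant$angle)) * (cos(psi) * pp[[1]] + sin(psi) * pp[[2]])
    }, numeric(3)))
  } else {
    dirs <- fib_sphere(162)
  }
  # rank candidate directions by clearance of the primary atom
  Q <- sweep(dirs * plant$distance, 2, L, `+`)
  clearance <- apply(Q, 1, function(q) {
    min(sqrt(rowSums(sweep(other, 2, q)^2)))
  })
  ord <- order(-clearance)
  chain <- if (plant$partner == "MG") "M" else "P"
  for (k in ord) {
    u <- dirs[k, ]
    q <- Q[k, ]
    configs <- if (length(frag$atoms) > 1) {
      pp <- orthonormal_pair(u)
      thetas <- if (!is.na(plant$angle) &&
                      identical(plant$donor_side, "partner")) plant$angle
                else c(115, 135, 155)
      unlist(lapply(thetas, function(theta) {
        lapply(seq(0, 2 * pi, length.out = 9)[-9], function(psi) {
          w <- cos(deg2rad(theta)) * (-u) +
            sin(deg2rad(theta)) * (cos(psi) * pp[[1]] + sin(psi) * pp[[2]])
          rbind(q, q + frag$bond * w)
        })
      }), recursive = FALSE)
    } else {
      list(matrix(q, 1, 3))
    }
    for (X in configs) {
      pa <- partner_df(plant$partner, frag$atoms, frag$elements, X,
                       chain, resseq, hetero = plant$partner %in% c("MG", "HOH"))
      intended <- list(list(ligand_atom = plant$ligand_atom,
                            category = plant$category))
      if (plant_ok(lig_typed, pa, intended, crit)) return(pa)
    }
  }
  stop(sprintf("could not place %s plant at %s without side contacts",
               plant$category, plant$ligand_atom))
}

place_aromatic_plant <- function(plant, ligand, lig_typed, crit, resseq) {
  ringdef <- LIGAND_RINGS$guanine_ring6
  RX <- do.call(rbind, lapply(ringdef, lig_xyz, ligand = ligand))
  g <- ring_centroid_normal(RX)
  ring6 <- function(center, normal, radius = 1.39) {
    pp <- orthonormal_pair(normal)
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    t(vapply(ang, function(a) {
      center + radius * (cos(a) * pp[[1]] + sin(a) * pp[[2]])
    }, numeric(3)))
  }
  # lateral offset away from the fused 5-ring keeps the 5-ring centroid
  # outside the centroid cutoff, so exactly one ring pair is in contact
  R5 <- do.call(rbind, lapply(LIGAND_RINGS$guanine_ring5, lig_xyz,
                              ligand = ligand))
  away <- g$centroid - colMeans(R5)
  away <- away - sum(away * g$normal) * g$normal
  away <- away / vnorm(away)
  for (side in c(1, -1)) {
    for (lat in c(1.2, 1.5, 0.9)) {
      center <- g$centroid + side * plant$distance * g$normal + lat * away
      if (!is.na(plant$angle) && plant$angle >= 60) {
        # T-shaped: ring normal perpendicular to the guanine normal
        pp <- orthonormal_pair(g$normal)
        X <- ring6(center, pp[[1]])
      } else {
        X <- ring6(center, g$normal)
      }
      pa <- partner_df("TYR", c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       rep("C", 6), X, "P", resseq, hetero = FALSE)
      got <- plant_contacts(lig_typed, pa, crit)
      # edge-on (T-shaped) stacks inherently graze the vdW envelope of
      # the base; only parallel plants must be free of side contacts
      tshaped <- !is.na(plant$angle) && plant$angle >= 60
      allowed <- if (tshaped) c("vdw", "vdw_clash") else character(0)
      if (!all(vapply(got, `[`, character(1), 2) %in% allowed)) next
      cen5 <- ring_centroid_normal(R5)$centroid
      d5 <- vnorm(colMeans(X) - cen5)
      d6 <- vnorm(colMeans(X) - g$centroid)
      if (d6 <= crit$aromatic_centroid_max &&
          d5 > crit$aromatic_centroid_max) return(pa)
    }
  }
  stop("could not place aromatic plant without atom-pair side contacts")
}

place_water_bridge <- function(anchor, ligand, lig_typed, crit, resseq) {
  L <- lig_xyz(ligand, anchor)
  Xl <- coords(ligand$atoms)
  other <- Xl[ligand$atoms$name != anchor, , drop = FALSE]
  dirs <- fib_sphere(162)
  W <- sweep(dirs * 2.9, 2, L, `+`)
  clearance <- apply(W, 1, function(q) {
    min(sqrt(rowSums(sweep(other, 2, q)^2)))
  })
  for (k in order(-clearance)) {
    u <- dirs[k, ]
    w <- W[k, ]
    wat <- partner_df("HOH", "O", "O", matrix(w, 1, 3), "W", resseq)
    if (!plant_ok(lig_typed, wat,
                  list(list(ligand_atom = anchor, category = "hbond")),
                  crit)) next
    # protein partner on the far side, angle ligand-water-partner 109
    pp <- orthonormal_pair(u)
    for (psi in seq(0, 2 * pi, length.out = 9)[-9]) {
      v <- cos(deg2rad(109)) * (-u) +
        sin(deg2rad(109)) * (cos(psi) * pp[[1]] + sin(psi) * pp[[2]])
      p <- w + 2.9 * v
      prot <- partner_df("ASN", c("OD1", "CG"), c("O", "C"),
                         rbind(p, p + 1.23 * v), "P", resseq + 1L,
                         hetero = FALSE)
      if (plant_ok(lig_typed, prot, list(), crit)) {
        return(rbind(wat, prot))
      }
    }
  }
  stop("could not place water bridge at ", anchor)
}

#' Build a synthetic complex with planted contacts
#'
#' Every plant in `spec` is placed at its prescribed geometry and
#' verified to produce exactly the intended contact (and nothing else)
#' against the full ligand; decoy atoms are placed beyond the
#' environment cutoff. Deterministic given the spec seed.
#'
#' @param ligand A `ligand_instance` (e.g. from [build_nucleotide()]).
#' @param spec A `site_spec`.
#' @param criteria Detection criteria the plants must respect.
#' @param pdb_id Identifier for the resulting model.
#' @return A `structure_model` with attribute `planted` (data.frame of
#'   the planted truth).
#' @export
build_site <- function(ligand, spec = site_spec(),
                       criteria = interaction_criteria(),
                       pdb_id = "SYN01") {
  lig_typed <- assign_atom_types(ligand$atoms, quiet = TRUE)
  parts <- list(ligand$atoms)
  truth <- list()
  resseq <- 100L
  for (plant in spec$plants) {
    resseq <- resseq + 2L
    pa <- if (plant$category == "aromatic") {
      place_aromatic_plant(plant, ligand, lig_typed, criteria, resseq)
    } else {
      place_plant(plant, ligand, lig_typed, criteria, resseq)
    }
    parts[[length(parts) + 1]] <- pa
    truth[[length(truth) + 1]] <- data.frame(
      category = plant$category, ligand_atom = plant$ligand_atom,
      partner = plant$partner, resseq = resseq,
      distance = plant$distance, stringsAsFactors = FALSE)
  }
  for (anchor in spec$water_bridges) {
    resseq <- resseq + 2L
    pa <- place_water_bridge(anchor, ligand, lig_typed, criteria, resseq)
    parts[[length(parts) + 1]] <- pa
    truth[[length(truth) + 1]] <- data.frame(
      category = "water_bridge", ligand_atom = anchor, partner = "HOH",
      resseq = resseq, distance = 2.9, stringsAsFactors = FALSE)
  }
  # far decoys, deterministic given seed
  if (spec$decoys > 0) {
    rs <- local_rng(spec$seed)
    on.exit(restore_rng(rs), add = TRUE)
    ctr <- colMeans(coords(ligand$atoms))
    rmax <- max(sqrt(rowSums(sweep(coords(ligand$atoms), 2, ctr)^2)))
    dirs <- fib_sphere(max(spec$decoys, 8))
    dirs <- dirs[sample.int(nrow(dirs), spec$decoys), , drop = FALSE]
    radius <- rmax + stats::runif(spec$decoys, 0.8, 3) +
      interaction_criteria()$environment_cutoff
    X <- sweep(dirs * radius, 2, ctr, `+`)
    resseq <- resseq + 2L
    parts[[length(parts) + 1]] <- partner_df(
      "GLY", rep("CA", spec$decoys), rep("C", spec$decoys), X, "D",
      seq(resseq, by = 1, length.out = spec$decoys), hetero = FALSE)
  }
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, pdb_id = pdb_id)
  attr(model, "planted") <- do.call(rbind, truth)
  model
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
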