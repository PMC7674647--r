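# small typed atom-table builders for direct detector tests
mk_atom <- function(name, element, resname, x, y = 0, z = 0, chain = "P",
                    resseq = 1L, hetero = FALSE) {
  data.frame(serial = 1L, name = name, altloc = "", resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = x, y = y, z = z, occ = 1, bfac = 0, element = element,
             hetero = hetero, water = resname == "HOH",
             metal = element %in% c("MG", "ZN", "MN"),
             stringsAsFactors = FALSE)
}

lig_O <- function(x = 0) {
  # a lone guanine O6 acceptor with its C6 antecedent
  t <- rbind(mk_atom("C6", "C", "G4P", x - 1.23, chain = "L", hetero = TRUE),
             mk_atom("O6", "O", "G4P", x, chain = "L", hetero = TRUE))
  t$serial <- 1:2
  assign_atom_types(t, quiet = TRUE)
}

ser_at <- function(d, angle = 150, with_cb = TRUE) {
  # SER OG at distance d along +x from the origin atom, CB making the
  # requested antecedent-donor-acceptor angle
  og <- mk_atom("OG", "O", "SER", d)
  at <- og
  if (with_cb) {
    th <- (180 - angle) * pi / 180
    cb <- mk_atom("CB", "C", "SER", d + 1.43 * cos(th), 1.43 * sin(th))
    at <- rbind(og, cb)
    at$serial <- 1:2
  }
  assign_atom_types(at, quiet = TRUE)
}

test_that("hydrogen bonds and weak hydrogen bonds follow the criteria", {
  lig <- lig_O()
  expect_equal(detect_hbonds(lig, ser_at(3.0, 160))$category, "hbond")
  ct <- detect_hbonds(lig, ser_at(2.5, 100))
  expect_equal(ct$category, "weak_hbond")
  expect_equal(ct$ligand_atom, "O6")
  expect_equal(nrow(detect_hbonds(lig, ser_at(3.8, 160))), 0)
  # donors without antecedent pass the angle criterion
  wat <- assign_atom_types(mk_atom("O", "O", "HOH", 3.0, chain = "W"),
                           quiet = TRUE)
  expect_equal(detect_hbonds(lig, wat)$category, "hbond")
  # short but well-aligned pairs are not weak hydrogen bonds: they fall
  # through to the polar bucket
  expect_equal(detect_polar(lig, ser_at(2.5, 170))$category, "polar")
})

test_that("vdw contacts and clashes follow Bondi radii sums", {
  lig_c <- assign_atom_types(
    mk_atom("C8", "C", "G4P", 0, chain = "L", hetero = TRUE), quiet = TRUE)
  probe_o <- function(d) assign_atom_types(mk_atom("O", "O", "GLY", d),
                                           quiet = TRUE)
  leu <- function(d) assign_atom_types(mk_atom("CD1", "C", "LEU", d),
                                       quiet = TRUE)
  # C...O sum of radii 1.70 + 1.52 = 3.22
  expect_equal(detect_vdw(lig_c, probe_o(3.2))$category, "vdw")
  expect_equal(detect_vdw(lig_c, probe_o(2.5))$category, "vdw_clash")
  expect_equal(nrow(detect_vdw(lig_c, probe_o(3.5))), 0)
  expect_equal(detect_vdw(lig_c, leu(3.45))$category, "vdw")
  expect_equal(nrow(detect_vdw(lig_c, leu(3.55))), 0)
})

test_that("ionic contacts pair charged groups within 4 A", {
  lig <- build_nucleotide(ligand_spec())
  tl <- assign_atom_types(lig$atoms, quiet = TRUE)
  o1b <- unlist(tl[tl$name == "O1B", c("x", "y", "z")])
  arg <- function(d) {
    at <- mk_atom("NH1", "N", "ARG", o1b[1] + d, o1b[2], o1b[3])
    assign_atom_types(at, quiet = TRUE)
  }
  expect_equal(detect_ionic(tl, arg(3.5))$category, "ionic")
  expect_equal(nrow(detect_ionic(tl, arg(4.5))), 0)
  lys <- mk_atom("NZ", "N", "LYS", o1b[1] + 3.9, o1b[2], o1b[3])
  expect_equal(detect_ionic(tl, assign_atom_types(lys, quiet = TRUE))$category,
               "ionic")
  # charge-assisted pairs are counted once, as ionic, not as hbond
  expect_equal(nrow(detect_hbonds(tl, arg(3.5))), 0)
})

test_that("metal coordination and bridges are reported", {
  lig <- build_nucleotide(ligand_spec())
  tl <- assign_atom_types(lig$atoms, quiet = TRUE)
  o1a <- unlist(tl[tl$name == "O1A", c("x", "y", "z")])
  pa <- unlist(tl[tl$name == "PA", c("x", "y", "z")])
  u_out <- o1a - pa                      # along the P=O bond extension
  u_out <- u_out / sqrt(sum(u_out^2))
  mg_at <- function(d, extra = NULL) {
    p <- o1a + d * u_out
    at <- mk_atom("MG", "MG", "MG", p[1], p[2], p[3],
                  chain = "M", hetero = TRUE)
    if (!is.null(extra)) {
      at <- rbind(at, extra)
      at$serial <- seq_len(nrow(at))
    }
    assign_atom_types(at, quiet = TRUE)
  }
  expect_equal(detect_metal(tl, mg_at(2.1))$category, "metal")
  expect_equal(nrow(detect_metal(tl, mg_at(3.5))), 0)
  p_asp <- o1a + (2.1 + 2.2) * u_out
  asp <- mk_atom("OD1", "O", "ASP", p_asp[1], p_asp[2], p_asp[3])
  ct <- detect_metal(tl, mg_at(2.1, extra = asp))
  expect_equal(nrow(ct), 1)
  br <- attr(ct, "bridges")
  expect_equal(nrow(br), 1)
  expect_equal(br$partner_atom, "OD1")
})

test_that("aromatic stacking is detected with parallel/T-shaped subclasses", {
  lig <- build_nucleotide(ligand_spec())
  site <- build_site(lig, site_spec(plants = list(
    planted_contact("aromatic", "guanine_ring6", "TYR", 3.6, 0)),
    decoys = 0))
  fp <- fingerprint_complex(site, extract_ligands(site)[[1]])
  ar <- fp$contacts[fp$contacts$category == "aromatic", ]
  expect_equal(nrow(ar), 1)
  expect_lt(ar$angle, 30)
  # perpendicular ring at 4.4 A centroid distance: T-shaped
  site_t <- build_site(lig, site_spec(plants = list(
    planted_contact("aromatic", "guanine_ring6", "TYR", 4.2, 90)),
    decoys = 0))
  fp_t <- fingerprint_complex(site_t, extract_ligands(site_t)[[1]])
  ar_t <- fp_t$contacts[fp_t$contacts$category == "aromatic", ]
  expect_equal(nrow(ar_t), 1)
  expect_gt(ar_t$angle, 60)
  # centroids beyond the cutoff: nothing
  tl <- assign_atom_types(lig$atoms, quiet = TRUE)
  far <- detect_aromatic(lig, lig$atoms, tl,
                         interaction_criteria(aromatic_centroid_max = 0.1))
  expect_equal(nrow(far), 0)
})

test_that("polar family respects the hierarchy and distance windows", {
  lig <- lig_O()
  expect_equal(detect_polar(lig, ser_at(3.4, 95))$category, "polar")
  expect_equal(detect_polar(lig, ser_at(3.8, 95))$category, "weak_polar")
  # a true hydrogen bond is not double counted as polar
  expect_equal(nrow(detect_polar(lig, ser_at(3.0, 160))), 0)
  expect_equal(nrow(detect_polar(lig, ser_at(4.2, 95))), 0)
})

test_that("water-mediated bridges require both legs", {
  lig <- lig_O()
  wat <- mk_atom("O", "O", "HOH", 2.9, chain = "W", resseq = 301L,
                 hetero = TRUE)
  asn_far <- mk_atom("OD1", "O", "ASN", 2.9 + 2.9, 0, 0, resseq = 401L)
  env1 <- assign_atom_types(rbind(wat, asn_far), quiet = TRUE)
  br <- water_mediated_hbonds(lig, env1)
  expect_equal(nrow(br), 1)
  expect_equal(br$ligand_atom, "O6")
  expect_equal(br$atom, "OD1")
  # water bonded only to the ligand: no bridge
  env2 <- assign_atom_types(wat, quiet = TRUE)
  expect_equal(nrow(water_mediated_hbonds(lig, env2)), 0)
  # two independent bridges
  wat2 <- mk_atom("O", "O", "HOH", 0, 2.9, 0, chain = "W",
                  resseq = 302L, hetero = TRUE)
  asn2 <- mk_atom("OD1", "O", "ASN", 0, 5.8, 0, resseq = 402L)
  env3 <- assign_atom_types(rbind(wat, asn_far, wat2, asn2), quiet = TRUE)
  br3 <- water_mediated_hbonds(lig, env3)
  expect_equal(nrow(br3), 2)
})

test_that("fingerprints recover exactly the planted nine-category truth", {
  lig <- build_nucleotide(ligand_spec())
  model <- build_site(lig, site_spec(), pdb_id = "FIX9")
  fp <- fingerprint_complex(model, extract_ligands(model)[[1]])
  expect_equal(unname(fp$counts_by_category),
               rep(1L, 9))
  truth <- attr(model, "planted")
  for (k in seq_len(nrow(truth))) {
    hit <- fp$contacts[fp$contacts$category == truth$category[k], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$ligand_atom, truth$ligand_atom[k])
  }
  # empty environment: all zero
  m0 <- structure_model(lig$atoms, pdb_id = "EMPTY")
  fp0 <- fingerprint_complex(m0, extract_ligands(m0)[[1]])
  expect_equal(sum(fp0$counts_by_category), 0)
  # marginals are exact functions of the contact list
  expect_equal(sum(fp$counts_by_atom$count), nrow(fp$contacts))
  tab <- table(fp$contacts$ligand_atom, fp$contacts$category)
  for (r in seq_len(nrow(fp$counts_by_atom))) {
    a <- fp$counts_by_atom$ligand_atom[r]
    cc <- fp$counts_by_atom$category[r]
    want <- if (a %in% rownames(tab) && cc %in% colnames(tab))
      tab[a, cc] else 0L
    expect_equal(fp$counts_by_atom$count[r], as.integer(want))
  }
})

test_that("atom-level hydrogen-bond marginals follow the contact list", {
  lig <- build_nucleotide(ligand_spec(chi_target = -120))
  tl <- assign_atom_types(lig$atoms, quiet = TRUE)
  pos <- function(nm) unlist(tl[tl$name == nm, c("x", "y", "z")])
  # bare acceptors placed along each donor/acceptor direction; without
  # antecedents the partner angle criterion is vacuous
  exterior <- function(nm, ref1, ref2) {
    u <- pos(nm) - (pos(ref1) + pos(ref2)) / 2
    u / sqrt(sum(u^2))
  }
  p_n1 <- pos("N1") + 3.1 * exterior("N1", "C6", "C6")
  p_n2 <- pos("N2") + 3.1 * exterior("N2", "C2", "C2")
  p_o6 <- pos("O6") + 3.0 * (pos("O6") - pos("C6")) /
    sqrt(sum((pos("O6") - pos("C6"))^2))
  partners <- rbind(
    mk_atom("OD1", "O", "ASN", p_n1[1], p_n1[2], p_n1[3], resseq = 201L),
    mk_atom("OD1", "O", "ASN", p_n2[1], p_n2[2], p_n2[3], resseq = 202L),
    mk_atom("O", "O", "HOH", p_o6[1], p_o6[2], p_o6[3], resseq = 203L,
            hetero = TRUE))
  partners$serial <- 100 + seq_len(nrow(partners))
  model <- structure_model(rbind(lig$atoms, partners), pdb_id = "HB3")
  fp <- fingerprint_complex(model, extract_ligands(model)[[1]])
  hb <- fp$contacts[fp$contacts$category == "hbond", ]
  expect_setequal(hb$ligand_atom, c("N1", "N2", "O6"))
  marg <- aggregate_by_atom(list(fp), category = "hbond")
  expect_equal(unname(marg[c("N1", "N2", "O6")]), c(1L, 1L, 1L))
  # groupby oracle on the same contact list
  expect_equal(unname(marg[marg > 0]),
               unname(as.integer(table(hb$ligand_atom)[names(marg[marg > 0])])))
})

test_that("detectors agree with the brute-force all-pairs oracle", {
  lig <- build_nucleotide(ligand_spec())
  model <- build_site(lig, site_spec(water_bridges = list("O1C"), seed = 4),
                      pdb_id = "ORC")
  expect_lt(nrow(model$atoms), 200)
  fp <- fingerprint_complex(model, extract_ligands(model)[[1]])
  expect_identical(fingerprint_pair_keys(fp),
                   oracle_contacts(model, extract_ligands(model)[[1]]))
  # and on a corpus member with a different recipe
  corp <- build_corpus(n_per_class = 1, seed = 7,
                       classes = "rna_polymerase")
  cx <- corp$complexes[[1]]
  expect_identical(fingerprint_pair_keys(fingerprint_complex(cx$model,
                                                             cx$ligand)),
                   oracle_contacts(cx$model, cx$ligand))
})

test_that("widening the hydrogen-bond window never loses hydrogen bonds", {
  lig <- build_nucleotide(ligand_spec())
  model <- build_site(lig, site_spec(), pdb_id = "MONO")
  ligx <- extract_ligands(model)[[1]]
  base <- fingerprint_complex(model, ligx)$counts_by_category[["hbond"]]
  wide <- fingerprint_complex(
    model, ligx,
    interaction_criteria(hbond_dist_min = 2.4, hbond_dist_max = 3.9))
  expect_gte(wide$counts_by_category[["hbond"]], base)
})

test_that("criteria configs round-trip through YAML and reject bad keys", {
  crit <- interaction_criteria(hbond_dist_max = 3.6, ionic_dist_max = 4.2)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(crit, tf)
  back <- read_criteria(tf)
  expect_equal(unclass(back), unclass(crit))
  writeLines("hbond_dist_max: 3.4\nbogus_key: 1\n", tf)
  expect_error(read_criteria(tf), "bogus_key")
  expect_error(interaction_criteria(hbond_dist_max = -1))
})
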