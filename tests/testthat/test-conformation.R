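test_that("pseudorotation reproduces the curated reference table", {
  tab <- pucker_table(reference_torsions())
  expect_equal(tab$P,
               c(188.23, 186.23, 31.47, 170.36, 158.59, 151.01),
               tolerance = 0.02 / 188)
  expect_equal(tab$nu_max[c(1, 2, 3, 6)],
               c(36.24, 34.85, 36.96, 44.27), tolerance = 0.02 / 36)
  expect_equal(tab$pucker_class,
               c("C3'-exo", "C3'-exo", "C3'-endo", "C2'-endo",
                 "C2'-endo", "C2'-endo"))
  expect_equal(tab$glycosidic_class,
               c("anti", "syn", "anti", "anti", "anti", "syn"))
})

test_that("pseudorotation handles symmetric, boundary and degenerate rings", {
  # symmetric ideal torsions: the numerator cancels exactly at P = 0
  ps <- pseudorotation(ideal_ring_torsions(0, 40))
  expect_equal(ps$P, 0, tolerance = 1e-9)
  expect_equal(ps$nu_max, 40, tolerance = 1e-9)
  expect_equal(ps$pucker_class, "C3'-endo")
  expect_equal(ps$hemisphere, "north")
  # nu2 = 0 meridian handled via the limit
  ps90 <- pseudorotation(ideal_ring_torsions(90, 38))
  expect_equal(ps90$P, 90, tolerance = 1e-9)
  expect_equal(ps90$nu_max, 38, tolerance = 1e-9)
  ps270 <- pseudorotation(ideal_ring_torsions(270, 38))
  expect_equal(ps270$P, 270, tolerance = 1e-9)
  expect_error(pseudorotation(rep(0, 5)), "planar")
})

test_that("pseudorotation round-trips ideal torsions to 1e-6 degrees", {
  set.seed(11)
  for (k in 1:40) {
    P0 <- runif(1, 0, 360)
    A0 <- runif(1, 6, 55)
    ps <- pseudorotation(ideal_ring_torsions(P0, A0))
    dP <- ((ps$P - P0 + 180) %% 360) - 180
    expect_lt(abs(dP), 1e-6)
    expect_lt(abs(ps$nu_max - A0), 1e-6)
  }
})

test_that("hemisphere and pucker class follow the 36-degree bins of P", {
  classes <- vapply(seq(18, 360, by = 36), function(P) {
    pseudorotation(ideal_ring_torsions(P, 40))$pucker_class
  }, character(1))
  expect_equal(classes,
               c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                 "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo"))
  expect_equal(pseudorotation(ideal_ring_torsions(89, 40))$hemisphere,
               "north")
  expect_equal(pseudorotation(ideal_ring_torsions(91, 40))$hemisphere,
               "south")
  expect_equal(pseudorotation(ideal_ring_torsions(275, 40))$hemisphere,
               "north")
})

test_that("glycosidic classification follows the stated chi windows", {
  expect_equal(classify_glycosidic(c(-99.58, -116.08, -112.79, 171.65)),
               rep("anti", 4))
  expect_equal(classify_glycosidic(c(84.22, 65.89)), rep("syn", 2))
  # documented boundary tie-breaks
  expect_equal(classify_glycosidic(90), "anti")
  expect_equal(classify_glycosidic(270), "syn")
  expect_equal(classify_glycosidic(-90), "syn")
  expect_error(classify_glycosidic(NaN))
})

test_that("compute_torsions recovers generator targets", {
  lig <- build_nucleotide(ligand_spec(P_target = 151.01,
                                      nu_max_target = 44.27,
                                      chi_target = 65.89,
                                      gamma_target = -143.14))
  tor <- compute_torsions(lig)
  expect_equal(tor[["chi"]], 65.89, tolerance = 0.5 / 65)
  expect_equal(tor[["gamma"]], -143.14, tolerance = 0.5 / 143)
  ps <- pseudorotation(tor)
  expect_lt(abs(ps$P - 151.01), 2)
  expect_lt(abs(ps$nu_max - 44.27), 2)
  expect_equal(ps$pucker_class, "C2'-endo")
  # torsions match an independent implementation on the same coordinates
  skip_if_not_installed("bio3d")
  idx <- match(c("O4'", "C1'", "N9", "C4"), lig$atoms$name)
  chi_ref <- bio3d::torsion.xyz(as.vector(t(coords(lig$atoms)[idx, ])))
  expect_equal(unname(tor[["chi"]]), unname(chi_ref), tolerance = 1e-6)
  # missing atoms are reported with the affected torsion
  broken <- lig
  broken$atoms <- broken$atoms[broken$atoms$name != "C4", ]
  expect_error(compute_torsions(broken), "chi")
})

test_that("generator and analysis agree across the pucker wheel", {
  # coordinate-level round trip within the declared 2-degree tolerance
  cases <- expand.grid(P = c(18, 90, 162, 234, 306),
                       A = c(25, 42))
  for (k in seq_len(nrow(cases))) {
    lig <- build_nucleotide(ligand_spec(P_target = cases$P[k],
                                        nu_max_target = cases$A[k],
                                        chi_target = -120))
    ps <- pseudorotation(compute_torsions(lig))
    dP <- ((ps$P - cases$P[k] + 180) %% 360) - 180
    expect_lt(abs(dP), 2)
    expect_lt(abs(ps$nu_max - cases$A[k]), 2)
  }
})

test_that("torsion histograms are percentage distributions over (-180,180]", {
  h <- torsion_distribution(rep(45, 100), 10)
  expect_equal(sum(h$percent), 100)
  expect_equal(h$percent[h$lower == 40], 100)
  grid <- seq(-179.5, 179.5, by = 1)
  h2 <- torsion_distribution(grid, 10)
  expect_equal(unique(h2$percent), 100 / 36, tolerance = 1e-9)
  expect_error(torsion_distribution(numeric(0)), "empty")
  expect_error(torsion_distribution(1:5, 7), "divide")
  # sampling oracle: a 70/30 von Mises mixture puts ~70% mass in syn range
  chi <- sample_chi_ensemble(ensemble_spec(n_frames = 10000,
                                           syn_fraction = 0.7, seed = 5))
  syn_mass <- sum(classify_glycosidic(chi) == "syn") / length(chi)
  expect_lt(abs(syn_mass - 0.7), 0.02)
})

test_that("rotatable-bond counter is exposed with a stable convention", {
  lig2 <- build_nucleotide(ligand_spec())
  lig3 <- build_nucleotide(ligand_spec(include_gamma_phosphate = TRUE))
  n2 <- count_rotatable_bonds(lig2)
  n3 <- count_rotatable_bonds(lig3)
  expect_gt(n2, 5)
  expect_equal(n3 - n2, 2L)  # gamma phosphate adds P-O3B and O3B-PG
})
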