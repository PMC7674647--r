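test_that("parse_pdb reads records, models and altlocs", {
  lines <- tiny_pdb_lines(matrix(rnorm(9), 3, 3))
  m <- parse_pdb(paste(lines, collapse = "\n"))
  expect_length(m, 1)
  expect_equal(nrow(m[[1]]$atoms), 3)

  # two MODEL blocks of the same 5 atoms
  lines5 <- tiny_pdb_lines(matrix(rnorm(15), 5, 3))
  multi <- c("MODEL        1", lines5, "ENDMDL",
             "MODEL        2", lines5, "ENDMDL", "END")
  mm <- parse_pdb(paste(multi, collapse = "\n"))
  expect_length(mm, 2)
  expect_equal(vapply(mm, function(x) nrow(x$atoms), integer(1)), c(5L, 5L))
  expect_equal(mm[[1]]$model_index, 1L)

  # altloc: higher occupancy wins; tie goes to 'A'
  al <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.40  0.00           C")
  a <- parse_pdb(paste(al, collapse = "\n"))[[1]]$atoms
  expect_equal(nrow(a), 1)
  expect_equal(a$altloc, "A")
  tie <- sub("0.60", "0.40", al)
  a2 <- parse_pdb(paste(tie, collapse = "\n"))[[1]]$atoms
  expect_equal(a2$altloc, "A")
  rev_occ <- c(sub("0.60", "0.40", al[1]), sub("0.40", "0.90", al[2]))
  a3 <- parse_pdb(paste(rev_occ, collapse = "\n"))[[1]]$atoms
  expect_equal(a3$altloc, "B")
})

test_that("parse_pdb reports malformed and empty input", {
  bad <- "ATOM      1  CA  GLY A   1       x.xxx   0.000   0.000  1.00  0.00           C"
  expect_error(parse_pdb(bad), "line 1")
  expect_error(parse_pdb(""), "empty")
})

test_that("write_pdb round-trips coordinates and atom count", {
  lig <- build_nucleotide(ligand_spec())
  model <- structure_model(lig$atoms, pdb_id = "RT")
  lines <- write_pdb(model)
  back <- parse_pdb(paste(lines, collapse = "\n"))[[1]]
  expect_equal(nrow(back$atoms), nrow(model$atoms))
  expect_equal(coords(back), coords(model), tolerance = 5.1e-4)
  expect_equal(back$atoms$name, model$atoms$name)
  # independent reader cross-check (bio3d)
  skip_if_not_installed("bio3d")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE),
               unname(round(coords(model), 3)), tolerance = 1e-8)
  expect_equal(trimws(ref$atom$elety), model$atoms$name)
})

test_that("multi-model ensembles survive a PDB round trip", {
  lig <- build_nucleotide(ligand_spec())
  ens <- perturb_ensemble(lig, n_frames = 4, sd = 0.2, seed = 3)
  models <- lapply(seq_along(ens$frames), function(k) {
    at <- lig$atoms
    at$x <- ens$frames[[k]][, 1]
    at$y <- ens$frames[[k]][, 2]
    at$z <- ens$frames[[k]][, 3]
    structure_model(at, pdb_id = "ENS", model_index = k)
  })
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(models, tf)
  back <- read_ensemble_pdb(tf)
  expect_length(back$frames, 4)
  expect_equal(back$frames[[3]], unname(ens$frames[[3]]),
               tolerance = 5.1e-4, ignore_attr = TRUE)
})

test_that("select_environment matches a brute-force distance filter", {
  lig <- build_nucleotide(ligand_spec())
  # probes on a radial ladder from atom O6
  o6 <- lig$atoms[lig$atoms$name == "O6", ]
  u <- c(0.26726, 0.53452, 0.80178)
  probes <- do.call(rbind, lapply(1:10, function(r) {
    data.frame(serial = 1000 + r, name = "O", altloc = "",
               resname = "HOH", chain = "W", resseq = 500 + r, icode = "",
               x = o6$x + r * u[1], y = o6$y + r * u[2],
               z = o6$z + r * u[3], occ = 1, bfac = 0, element = "O",
               hetero = TRUE, water = TRUE, metal = FALSE)
  }))
  model <- structure_model(rbind(lig$atoms, probes), pdb_id = "ENVT")
  env <- select_environment(model, lig, 5.0)
  # brute force over all model atoms
  A <- coords(model); L <- coords(lig$atoms)
  dmin <- apply(A, 1, function(p) min(sqrt(colSums((t(L) - p)^2))))
  is_lig <- paste(model$atoms$chain, model$atoms$resseq) %in%
    paste(lig$atoms$chain, lig$atoms$resseq)
  expect_equal(sort(env$serial),
               sort(model$atoms$serial[!is_lig & dmin <= 5]))
  # against the single probe-anchor atom, the radial ladder cuts at 5 A
  env_o6 <- select_environment(model, o6, 5.0)
  expect_equal(sum(env_o6$water), 5)

  # boundary behaviour just inside / outside the cutoff
  inside <- probes[1, ]; inside$x <- o6$x + 4.9; inside$y <- o6$y; inside$z <- o6$z
  outside <- inside; outside$x <- o6$x + 5.1; outside$resseq <- 600L
  m2 <- structure_model(rbind(lig$atoms, inside), pdb_id = "B1")
  m3 <- structure_model(rbind(lig$atoms, outside), pdb_id = "B2")
  d_in <- min(sqrt(rowSums(sweep(coords(lig$atoms), 2,
                                 unlist(inside[c("x", "y", "z")]))^2)))
  expect_lte(d_in, 5)
  expect_equal(nrow(select_environment(m2, lig, 5.0)), 1)
  expect_equal(nrow(select_environment(m3, lig, 5.0)), 0)
})

test_that("atom typing is a deterministic template lookup", {
  arg <- data.frame(serial = 1:2, name = c("NH1", "NE"), altloc = "",
                    resname = "ARG", chain = "A", resseq = 1, icode = "",
                    x = 0, y = 0, z = c(0, 1), occ = 1, bfac = 0,
                    element = "N", hetero = FALSE, water = FALSE,
                    metal = FALSE)
  t1 <- assign_atom_types(arg)
  expect_true(all(t1$cationic))
  expect_true(all(t1$donor))
  lig <- build_nucleotide(ligand_spec())
  tl <- assign_atom_types(lig$atoms)
  o1b <- tl[tl$name == "O1B", ]
  expect_true(o1b$anionic && o1b$acceptor)
  mg <- data.frame(serial = 1, name = "MG", altloc = "", resname = "MG",
                   chain = "M", resseq = 9, icode = "", x = 0, y = 0,
                   z = 0, occ = 1, bfac = 0, element = "MG",
                   hetero = TRUE, water = FALSE, metal = TRUE)
  expect_true(assign_atom_types(mg, quiet = TRUE)$metal)
  # unknown residues fall back to the element heuristic with a warning
  unk <- mg; unk$resname <- "XXX"; unk$name <- "N1"; unk$element <- "N"
  unk$metal <- FALSE
  expect_warning(tu <- assign_atom_types(unk), "heuristic")
  expect_true(tu$donor && tu$acceptor)
  # purity: identical output on repeated calls
  expect_identical(assign_atom_types(lig$atoms), tl)
})

test_that("ligand extraction returns canonical flagged instances", {
  lig <- build_nucleotide(ligand_spec())           # G4P
  lig3 <- build_nucleotide(ligand_spec(include_gamma_phosphate = TRUE),
                           chain = "B", resseq = 2)
  model <- structure_model(rbind(lig$atoms, lig3$atoms), pdb_id = "2COPY")
  got <- extract_ligands(model)
  expect_length(got, 2)
  expect_false(has_gamma_phosphate(got[[1]]))
  expect_true(has_gamma_phosphate(got[[2]]))
  expect_length(extract_ligands(model, codes = "XYZ"), 0)
  # the two pppGpp codes are case-insensitive synonyms
  alt <- lig3$atoms; alt$resname <- "0o2"
  m2 <- structure_model(alt, pdb_id = "LC")
  expect_length(extract_ligands(m2), 1)
  expect_equal(extract_ligands(m2)[[1]]$ligand_code, "0O2")
  # incomplete ligands are flagged, not dropped
  trunc <- lig$atoms[lig$atoms$name != "C3'", ]
  m3 <- structure_model(trunc, pdb_id = "INC")
  inc <- extract_ligands(m3)
  expect_length(inc, 1)
  expect_false(inc[[1]]$completeness[["ribose"]])
})

test_that("hydrogen-bond capable census matches the known atom counts", {
  ppgpp <- build_nucleotide(ligand_spec())
  expect_equal(unname(count_hbond_capable_atoms(ppgpp)), c(5L, 17L))
  pppgpp <- build_nucleotide(ligand_spec(include_gamma_phosphate = TRUE))
  expect_equal(unname(count_hbond_capable_atoms(pppgpp)), c(5L, 20L))
  # guanine base alone: all five nitrogens plus O6
  base <- ligand_instance(
    ppgpp$atoms[ppgpp$atoms$name %in% ligand_atom_groups()$guanine, ])
  expect_equal(unname(count_hbond_capable_atoms(base,
                                                require_complete = FALSE)),
               c(5L, 1L))
  expect_error(count_hbond_capable_atoms(base), "missing group")
})

test_that("ligand geometric invariants hold for built nucleotides", {
  for (spec in list(ligand_spec(), ligand_spec(P_target = 31.47,
                                               nu_max_target = 36.96,
                                               chi_target = 171.65,
                                               include_gamma_phosphate = TRUE))) {
    lig <- build_nucleotide(spec)
    expect_true(validate_ligand(lig))
  }
  expect_error(moiety_of("ZZ9"), "outside all moieties")
  expect_equal(moiety_of(c("O6", "O1A", "O1D", "C1'")),
               c("guanine", "phosphate_5prime", "phosphate_3prime",
                 "ribose"))
})
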