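#!/usr/bin/env Rscript
# Stage 2: conformational analysis.
#
# (a) Computes pseudorotation parameters (P, nu_max), pucker classes and
#     syn/anti labels for the curated reference torsion table (unbound
#     energy-minimised ppGpp/pppGpp and representative bound crystal
#     conformers).
# (b) Re-derives the same quantities from coordinates for every ligand
#     in the synthetic corpus, exercising the full
#     coordinates -> torsions -> pseudorotation route.
# (c) Bins the simulated glycosidic ensembles into percentage frequency
#     distributions.

suppressPackageStartupMessages(library(ppgpp))

dir.create("results", showWarnings = FALSE)
ref <- pucker_table(system.file("extdata", "reference_torsions.tsv",
                                package = "ppgpp", mustWork = TRUE))
utils::write.table(ref, "results/reference_pucker_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("reference conformers:")
print(ref[, c("id", "P", "nu_max", "pucker_class", "glycosidic_class")])

manifest <- utils::read.delim("results/corpus/manifest.tsv")
rows <- lapply(manifest$pdb_id, function(id) {
  model <- parse_pdb(file.path("results/corpus", paste0(id, ".pdb")))[[1]]
  lig <- extract_ligands(model)[[1]]
  conformation_summary(lig, id = id)
})
corpus_tab <- do.call(rbind, rows)
utils::write.table(corpus_tab, "results/corpus_pucker_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("corpus conformers: %d ligands, pucker classes: %s",
                nrow(corpus_tab),
                paste(unique(corpus_tab$pucker_class), collapse = ", ")))

for (code in c("ppGpp", "pppGpp")) {
  chi <- utils::read.delim(sprintf("results/chi_ensemble_%s.tsv", code))$chi
  h <- torsion_distribution(chi, bin_width = 10)
  utils::write.table(h, sprintf("results/chi_distribution_%s.tsv", code),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  peak <- h$mid[which.max(h$percent)]
  message(sprintf("%s chi distribution peaks at %g degrees", code, peak))
}
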