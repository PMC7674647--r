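#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds (a) an annotated corpus of ligand-protein complexes, two per
# functional class, with class-recipe planted contacts, and (b) syn/anti
# glycosidic-torsion ensembles for ppGpp and pppGpp emulating the
# bimodal occupancy seen in solution. Everything is deterministic given
# the seed.

suppressPackageStartupMessages(library(ppgpp))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dir.create("results", showWarnings = FALSE)
corp <- build_corpus(n_per_class = 2, seed = seed)
write_corpus(corp, "results/corpus")
message(sprintf("wrote %d complexes to results/corpus (seed %d)",
                length(corp$complexes), seed))

for (code in c("ppGpp", "pppGpp")) {
  chi <- sample_chi_ensemble(ensemble_spec(
    n_frames = 10000, syn_fraction = 0.7,
    seed = seed + match(code, c("ppGpp", "pppGpp"))))
  utils::write.table(
    data.frame(frame = seq_along(chi), chi = chi),
    sprintf("results/chi_ensemble_%s.tsv", code),
    sep = "\t", quote = FALSE, row.names = FALSE)
  syn_mass <- mean(classify_glycosidic(chi) == "syn")
  message(sprintf("%s chi ensemble: %.1f%% syn occupancy", code,
                  100 * syn_mass))
}
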