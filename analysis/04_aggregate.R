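#!/usr/bin/env Rscript
# Stage 4: corpus-level aggregation.
#
# Collapses the fingerprints into the summary surfaces of the analysis:
# occurrence counts per interaction category, per-ligand-atom hydrogen
# bond and van der Waals marginals, moiety totals, and per-functional-
# class profiles (raw and per-complex-normalised). Conservation of the
# totals across levels is asserted before anything is written.

suppressPackageStartupMessages(library(ppgpp))

manifest <- utils::read.delim("results/corpus/manifest.tsv")
fps <- lapply(manifest$pdb_id, function(id) {
  model <- parse_pdb(file.path("results/corpus", paste0(id, ".pdb")))[[1]]
  fingerprint_complex(model)
})

total <- aggregate_by_category(fps)
hb_atoms <- aggregate_by_atom(fps, category = "hbond")
vdw_atoms <- aggregate_by_atom(fps, category = "vdw")
moieties <- moiety_rollup(fps)
prof <- aggregate_by_class(fps, manifest[, c("pdb_id", "functional_class")])
prof_norm <- aggregate_by_class(fps,
                                manifest[, c("pdb_id", "functional_class")],
                                normalize = "per_complex")

stopifnot(sum(prof$category_counts) == sum(total),
          sum(moieties) == sum(total),
          sum(vapply(fps, function(f) nrow(f$contacts), integer(1)))
          == sum(total))

utils::write.table(data.frame(category = names(total), count = total),
                   "results/category_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(atom = names(hb_atoms), hbond = hb_atoms,
                              vdw = vdw_atoms),
                   "results/atom_marginals.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(moieties, "results/moiety_counts.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)
write_class_profile(prof, "results/class_profile")
write_class_profile(prof_norm, "results/class_profile_per_complex")

message("total contacts: ", sum(total))
message("category counts:")
print(total)
message("per-class category counts:")
print(prof$category_counts)
message("moiety totals (contacts per moiety):")
print(rowSums(moieties))
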