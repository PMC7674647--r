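#!/usr/bin/env Rscript
# Stage 3: interaction fingerprinting.
#
# Types every ligand-protein contact of every corpus complex in the nine
# geometric categories (5 A environment), writes one contact TSV per
# complex plus a combined table, and reports water bridges and metal
# bridging.

suppressPackageStartupMessages(library(ppgpp))

crit <- interaction_criteria()
manifest <- utils::read.delim("results/corpus/manifest.tsv")
dir.create("results/fingerprints", showWarnings = FALSE, recursive = TRUE)

all_contacts <- list()
for (id in manifest$pdb_id) {
  model <- parse_pdb(file.path("results/corpus", paste0(id, ".pdb")))[[1]]
  fp <- fingerprint_complex(model, criteria = crit)
  df <- write_contacts_tsv(
    fp, file.path("results/fingerprints", paste0(id, "_contacts.tsv")),
    criteria = crit)
  all_contacts[[id]] <- df
  jsonlite::write_json(
    list(pdb_id = fp$pdb_id, ligand_code = fp$ligand_code,
         counts_by_category = as.list(fp$counts_by_category),
         n_water_bridges = nrow(fp$water_bridges)),
    file.path("results/fingerprints", paste0(id, ".json")),
    auto_unbox = TRUE, digits = NA)
  message(sprintf("%s: %d contacts, %d water bridge(s)", id,
                  nrow(fp$contacts), nrow(fp$water_bridges)))
}
utils::write.table(do.call(rbind, all_contacts),
                   "results/all_contacts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
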