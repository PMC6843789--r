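#!/usr/bin/env Rscript
# Detect EPS clusters in the simulated genomes from their on-disk form
# (GenBank + reference FASTA + habitat TSV), assign roles, predict Wzx/Wzy
# topology and classify each cluster. Writes the cluster, role, topology and
# classification tables plus a run summary under results/detect/.

library(epsclust)

sim <- "results/simdata"
stopifnot(dir.exists(sim))
gbk <- list.files(sim, pattern = "\\.gbk$", full.names = TRUE)

det <- run_detect(genbank_paths = gbk,
                  reference_fasta = file.path(sim, "reference.fasta"),
                  habitat_tsv = file.path(sim, "habitat.tsv"),
                  out_dir = "results/detect")
saveRDS(det, "results/detect/detection.rds")

message(sprintf("detected %d clusters in %d genomes", nrow(det$clusters),
                length(gbk)))
message(sprintf("generic: %d / %d; most common missing essential gene: %s",
                det$summary$n_generic, det$summary$n_clusters,
                names(which.max(unlist(det$summary$missing_counts)))))
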