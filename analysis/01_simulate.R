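#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic survey.
#
# Emulates a 40-plant anaerobic-digester metaproteome survey: four plant
# groups (mesophile, thermophile, UASB, sewage sludge) x 10 samples,
# ~4000 identified spectra each, with planted group signatures, planted
# TAN/OLR correlations (Spearman 0.7) and a planted high-TAN marker
# metaprotein. Writes all input tables plus the ground truth under
# results/run/.

suppressPackageStartupMessages(library(proteotypeR))

seed <- 1L
out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(sim_config(), seed = seed)

write_psm_table(study$psms, file.path(out, "psms.tsv"))
write_parameter_table(study$parameters, file.path(out, "parameters.tsv"))
write_taxonomy(study$taxonomy, file.path(out, "taxonomy.tsv"))
write_annotation_table(study$annotations, file.path(out, "annotations.tsv"))
write_homology_table(study$homology, file.path(out, "homology.tsv"))
write.table(study$ko_pathway, file.path(out, "ko_pathway.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
gt_json <- study$ground_truth[c("groups", "signature_orders",
                                "signature_features", "planted", "marker")]
gt_json$groups <- as.list(gt_json$groups)  # keep sample names in the JSON
jsonlite::write_json(gt_json, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d PSMs over %d samples (%d metaproteins, %d orders)\n",
            nrow(study$psms), length(unique(study$psms$sample_id)),
            sim_config()$n_metaproteins, sim_config()$n_orders))
cat(sprintf("planted: %s ~ TAN (+), %s ~ OLR (-), marker %s for TAN > 4200\n",
            study$ground_truth$planted$feature[1],
            study$ground_truth$planted$feature[2],
            study$ground_truth$marker$feature))
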