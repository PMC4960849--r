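#!/usr/bin/env Rscript
# Stage 2 — PSMs to metaproteins.
#
# Applies the identification-score filter (>= 40), transfers annotations
# to metagenome accessions by homology (e-value <= 1e-4, best hit),
# drops contaminant keratins and unknowns, groups the remainder into
# UniRef50 metaproteins with common-ancestor taxonomy, and counts
# spectra per metaprotein and sample.

suppressPackageStartupMessages(library(proteotypeR))

run <- "results/run"
psms <- read_psm_table(file.path(run, "psms.tsv"))
ann <- read_annotation_table(file.path(run, "annotations.tsv"))
hom <- read_homology_table(file.path(run, "homology.tsv"))
tax <- read_taxonomy(file.path(run, "taxonomy.tsv"))

n0 <- nrow(psms)
psms <- filter_psms(psms, min_score = 40)
cat(sprintf("score filter: %d of %d PSMs retained\n", nrow(psms), n0))

ann2 <- transfer_annotations(ann, hom, max_e = 1e-4)
cat(sprintf("annotation transfer: %d accessions gained annotations\n",
            sum(ann2$source == "transfer")))

psms <- suppressWarnings(exclude_contaminants(psms, ann2))
cat(sprintf("excluded %d contaminant and %d unknown spectra\n",
            attr(psms, "n_contaminant_spectra"),
            attr(psms, "n_unknown_spectra")))

profile <- group_metaproteins(psms, ann2, tax)
cat(sprintf("grouped into %d metaproteins over %d samples\n",
            nrow(profile$counts), length(profile$samples)))

write_matrix(profile$counts, file.path(run, "metaprotein_counts.tsv"))
write.table(profile$meta, file.path(run, "metaprotein_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
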