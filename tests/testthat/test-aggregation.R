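test_that("score filter keeps exactly the records at or above threshold", {
  psms <- tiny_psms()
  psms$score <- c(35, 40, 45, 20, 40.0001, 39.9999)
  kept <- filter_psms(psms, 40)
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$score >= 40))
  expect_equal(filter_psms(psms, 0), psms)
  expect_equal(nrow(filter_psms(psms, 1e6)), 0L)
})

test_that("annotation transfer honours the e-value cutoff and best-hit rule", {
  ann <- tiny_annotations()
  hits <- data.frame(
    query_accession = c("MGa", "MGb", "MGc", "MGc"),
    subject_accession = c("A1", "B1", "M1", "A1"),
    e_value = c(1e-5, 1e-3, 1e-5, 1e-6),
    stringsAsFactors = FALSE)
  out <- transfer_annotations(ann, hits, max_e = 1e-4)
  # 1e-5 inherited, 1e-3 rejected
  expect_true("MGa" %in% out$accession)
  expect_false("MGb" %in% out$accession)
  expect_equal(out$uniref50_id[out$accession == "MGa"], "UniRef50_U1")
  # best (lowest-e) hit wins: MGc inherits from A1 (1e-6), not M1 (1e-5)
  expect_equal(out$uniref50_id[out$accession == "MGc"], "UniRef50_U1")
  # boundary is inclusive
  out2 <- transfer_annotations(ann, data.frame(
    query_accession = "MGd", subject_accession = "A1", e_value = 1e-4),
    max_e = 1e-4)
  expect_true("MGd" %in% out2$accession)
  # already-annotated accessions untouched
  expect_equal(out[out$accession %in% ann$accession,
                   setdiff(names(ann), "source")],
               ann, ignore_attr = TRUE)
})

test_that("transfer skips hits whose subject is unannotated, with a warning", {
  ann <- tiny_annotations()
  hits <- data.frame(query_accession = "MGx", subject_accession = "NOPE",
                     e_value = 1e-9, stringsAsFactors = FALSE)
  expect_warning(out <- transfer_annotations(ann, hits), "NOPE")
  expect_false("MGx" %in% out$accession)
})

test_that("contaminant and unknown accessions are excluded", {
  psms <- tiny_psms()
  ann <- tiny_annotations()
  out <- exclude_contaminants(psms, ann)
  # K1 is keratin-flagged: its only PSM (S2/sp3) drops
  expect_false(any(grepl("K1", out$proteins)))
  expect_equal(attr(out, "n_contaminant_spectra"), 1L)
  # unannotated accession: add a PSM matching only an unknown accession
  psms2 <- rbind(psms, data.frame(sample_id = "S2", spectrum_id = "sp4",
                                  peptide = "PEPTIDEF", proteins = "ZZZ",
                                  score = 50))
  out2 <- exclude_contaminants(psms2, ann)
  expect_equal(attr(out2, "n_unknown_spectra"), 1L)
  expect_equal(nrow(out2), nrow(out))
})

test_that("lca matches identity, sibling and cross-superkingdom cases", {
  tax <- tiny_taxonomy_species()
  clost <- 6L; bac <- 7L; firmicutes <- 3L
  expect_equal(lca(c(clost, clost), tax), clost)
  expect_equal(lca(c(15L, 16L), tax), 8L)            # two Clostridiales species -> family
  expect_equal(lca(c(clost, bac), tax), firmicutes)  # Clostridiales x Bacillales -> Firmicutes
  expect_equal(lca(c(15L, 19L), tax), 1L)            # Bacteria leaf x Archaea leaf -> root
  expect_error(lca(c(15L, 999L), tax), "999")
})

test_that("lca equals the brute-force lineage-intersection oracle", {
  for (rep in 1:5) {
    tax <- random_taxonomy(80, seed = rep)
    set.seed(100 + rep)
    for (i in 1:200) {
      ids <- sample(tax$taxon_id, sample(1:4, 1))
      expect_identical(lca(ids, tax), lca_oracle(ids, tax))
    }
  }
})

test_that("grouping builds one metaprotein per cluster with LCA taxonomy", {
  psms <- filter_psms(tiny_psms(), 40)
  ann <- tiny_annotations()
  tax <- tiny_taxonomy_species()
  psms <- exclude_contaminants(psms, ann)
  prof <- group_metaproteins(psms, ann, tax)
  # U1 (A1+A2, Clostridiales species) grouped: 1 spectrum S1 + 1 S2... plus
  expect_true("UniRef50_U1" %in% prof$meta$metaprotein_id)
  u1 <- prof$meta[prof$meta$metaprotein_id == "UniRef50_U1", ]
  expect_equal(u1$lca_name, "Clostridiales_fam")  # two species, same family
  expect_equal(prof$counts["UniRef50_U1", c("S1", "S2")], c(S1 = 1, S2 = 1))
  # merged function sets are unions over members
  expect_setequal(strsplit(u1$processes, ";")[[1]], c("glycolysis", "transport"))
  # accession without UniRef50 id becomes a singleton metaprotein
  expect_true("ACC:X1" %in% prof$meta$metaprotein_id)
  expect_equal(prof$counts["ACC:X1", "S2"], 1)
})

test_that("spectrum conservation holds per sample under unique assignment", {
  st <- simulate_study(small_config(), seed = 41)
  psms <- filter_psms(st$psms, 40)
  ann <- transfer_annotations(st$annotations, st$homology, 1e-4)
  psms <- suppressWarnings(exclude_contaminants(psms, ann))
  prof <- group_metaproteins(psms, ann, st$taxonomy)
  retained <- table(psms$sample_id)
  expect_equal(colSums(prof$counts)[names(retained)],
               as.numeric(retained), ignore_attr = TRUE)
})

test_that("fractional counting conserves total spectra in aggregate", {
  st <- simulate_study(small_config(shared_peptide_fraction = 0.2), seed = 43)
  psms <- filter_psms(st$psms, 40)
  ann <- transfer_annotations(st$annotations, st$homology, 1e-4)
  psms <- suppressWarnings(exclude_contaminants(psms, ann))
  prof <- group_metaproteins(psms, ann, st$taxonomy, shared = "fractional")
  retained <- table(psms$sample_id)
  expect_equal(colSums(prof$counts)[names(retained)],
               as.numeric(retained), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("grouping is invariant to PSM row order", {
  st <- simulate_study(small_config(), seed = 45)
  psms <- filter_psms(st$psms, 40)
  ann <- transfer_annotations(st$annotations, st$homology, 1e-4)
  psms <- suppressWarnings(exclude_contaminants(psms, ann))
  prof1 <- group_metaproteins(psms, ann, st$taxonomy)
  set.seed(1)
  prof2 <- group_metaproteins(psms[sample(nrow(psms)), ], ann, st$taxonomy)
  expect_equal(prof1$counts, prof2$counts)
  expect_equal(prof1$meta, prof2$meta)
})

test_that("shared spectra go to the cluster with the larger study-wide count", {
  # A spectrum matching U1 and U2; U2 has more spectra overall
  psms <- data.frame(
    sample_id = "S1", spectrum_id = paste0("sp", 1:4),
    peptide = paste0("PEP", 1:4),
    proteins = c("A1;B1", "B1", "B1", "A1"),
    score = 50, stringsAsFactors = FALSE)
  ann <- tiny_annotations()
  prof <- group_metaproteins(psms, ann, tiny_taxonomy_species())
  expect_equal(prof$counts["UniRef50_U2", "S1"], 3)  # shared spectrum to U2
  expect_equal(prof$counts["UniRef50_U1", "S1"], 1)
})
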