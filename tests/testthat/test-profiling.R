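# small profile fixture: 3 metaproteins over the tiny taxonomy
fixture_profile <- function() {
  counts <- matrix(c(5, 0,    # U1: Clostridiales species
                     3, 6,    # U2: LCA = Firmicutes (above order rank)
                     2, 4),   # U3: Methanosarcinales species
                   nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("S1", "S2")))
  meta <- data.frame(
    metaprotein_id = c("U1", "U2", "U3"),
    members = c("A1", "B1;X9", "M1"),
    lca_taxon = c(15L, 3L, 19L),
    lca_name = c("Clost_sp1", "Firmicutes", "Methano_sp1"),
    processes = c("glycolysis;transport", "transport", "methanogenesis"),
    ec_numbers = "", ko_ids = c("K00001", "K00002", ""),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta, samples = c("S1", "S2"),
                 provenance = list(shared = "unique", n_spectra = 20)),
            class = "metaprotein_profile")
}

test_that("order rollup maps LCAs to order ancestors and bins the rest", {
  prof <- fixture_profile()
  m <- count_matrix(prof, "order", taxonomy = tiny_taxonomy_species())
  expect_equal(m["Clostridiales", "S1"], 5)
  expect_equal(m["Methanosarcinales", ], c(S1 = 2, S2 = 4))
  # LCA above order rank -> unassigned bin
  expect_equal(m["unassigned_order", ], c(S1 = 3, S2 = 6))
  # rollup conserves column totals
  expect_equal(colSums(m), colSums(prof$counts))
})

test_that("process rollup duplicates spectra across keywords", {
  prof <- fixture_profile()
  m <- count_matrix(prof, "process")
  # U1 contributes its 5 S1 spectra to both of its keywords
  expect_equal(m["glycolysis", "S1"], 5)
  expect_equal(m["transport", "S1"], 5 + 3)
  # column sums exceed spectrum totals exactly by the duplicated mass
  expect_equal(colSums(m), colSums(prof$counts) + c(S1 = 5, S2 = 0))
})

test_that("normalization yields percentages summing to 100", {
  m <- matrix(c(30, 70, 1, 1, 2, 0), ncol = 2,
              dimnames = list(letters[1:3], c("S1", "S2")))
  m[3, 1] <- 0; m[1, 2] <- 1; m[2, 2] <- 1; m[3, 2] <- 2
  ab <- normalize_abundance(m)
  expect_equal(ab[, "S2"], c(a = 25, b = 25, c = 50))
  expect_lt(max(abs(colSums(ab) - 100)), 1e-9)
  bad <- m; bad[, 2] <- 0
  expect_error(normalize_abundance(bad), "S2")
})

test_that("the 1% filter keeps rows reaching min_pct in enough samples", {
  ab <- matrix(c(1.2, 0.8, 0.5, 0.3, 50, 48), nrow = 3, byrow = TRUE,
               dimnames = list(c("f1", "f2", "f3"), c("S1", "S2")))
  class(ab) <- c("abundance_matrix", class(ab))
  kept <- filter_min_abundance(ab, 1, 1)
  expect_equal(rownames(kept), c("f1", "f3"))
  # values are not renormalized
  expect_equal(kept["f1", "S1"], 1.2)
  expect_equal(rownames(filter_min_abundance(ab, 0, 1)), rownames(ab))
  expect_equal(nrow(filter_min_abundance(ab, 99, 1)), 0L)
})

test_that("filter retention is monotone in the threshold", {
  set.seed(7)
  ab <- normalize_abundance(matrix(rpois(200, 4), 20, 10,
                                   dimnames = list(paste0("f", 1:20),
                                                   paste0("S", 1:10))))
  for (p in c(0.5, 1, 2, 5)) {
    lo <- rownames(filter_min_abundance(ab, p / 2, 1))
    hi <- rownames(filter_min_abundance(ab, p, 1))
    expect_true(all(hi %in% lo))
  }
})

test_that("core features report presence-in-all with minima", {
  m <- matrix(c(2, 3, 0, 5, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), c("S1", "S2")))
  rep <- core_features(m)
  expect_equal(rep$present_in_all, c(TRUE, FALSE, TRUE))
  expect_equal(rep$min_abundance, c(2, 0, 1))
  expect_equal(rep$argmin_sample[1], "S1")
  # invariant to column permutation
  rep2 <- core_features(m[, c("S2", "S1")])
  expect_equal(rep2$present_in_all, rep$present_in_all)
  expect_equal(rep2$min_abundance, rep$min_abundance)
  # single-sample matrix: every nonzero feature is core
  rep1 <- core_features(m[, "S1", drop = FALSE])
  expect_equal(rep1$present_in_all, m[, "S1"] > 0, ignore_attr = TRUE)
})

test_that("per-group core comparison flags group-specific features", {
  m <- matrix(c(1, 2, 0, 0,
                3, 4, 5, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("fA", "fB"), paste0("S", 1:4)))
  labels <- c(S1 = "g1", S2 = "g1", S3 = "g2", S4 = "g2")
  cmp <- group_core_comparison(m, labels)
  expect_true(all(c("g1", "g2") %in% names(cmp$per_group)))
  expect_equal(cmp$contrasts$feature, "fA")
  expect_equal(cmp$contrasts$core_in, "g1")
  expect_equal(cmp$contrasts$absent_in, "g2")
  # identical groups give identical reports
  m2 <- cbind(m[, 1:2], m[, 1:2])
  colnames(m2) <- paste0("S", 1:4)
  cmp2 <- group_core_comparison(m2, setNames(rep(c("a", "b"), each = 2),
                                             paste0("S", 1:4)))
  cols <- c("feature", "present_in_all", "min_abundance")
  expect_equal(cmp2$per_group$a[cols], cmp2$per_group$b[cols])
})

test_that("thermophile signature orders are core in the thermophile group", {
  hits <- 0L
  for (s in 1:20) {
    st <- simulate_study(sim_config(n_samples_per_group = 4,
                                    n_spectra_per_sample = 1000,
                                    n_metaproteins = 150, n_orders = 24),
                         seed = s)
    res <- suppressWarnings(analyze_study(st, n_perm = 9, seed = s))
    gt <- st$ground_truth
    thermo <- colnames(res$filtered$order)[
      gt$groups[colnames(res$filtered$order)] == "thermophile"]
    sub <- res$filtered$order[, thermo, drop = FALSE]
    sig <- intersect(gt$signature_orders$thermophile, rownames(sub))
    core <- core_features(sub)
    ok <- length(sig) > 0 &&
      all(core$present_in_all[match(sig, core$feature)])
    hits <- hits + ok
  }
  expect_gte(hits, 18L)
})
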