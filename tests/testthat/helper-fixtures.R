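# Shared fixtures, all built in code.

# Hand-built 8-rank taxonomy:
# root > Bacteria > Firmicutes > {Clostridia > Clostridiales,
#                                 Bacilli    > Bacillales} > ... species
#      > Archaea  > Euryarchaeota > Methanomicrobia > Methanosarcinales ...
tiny_taxonomy <- function() {
  validate_taxonomy(data.frame(
    taxon_id  = 1:14,
    parent_id = c(1, 1, 2, 3, 3, 4, 5, 6, 7, 1, 10, 11, 12, 13),
    rank = c("root", "superkingdom", "phylum", "class", "class", "order",
             "order", "family", "family", "superkingdom", "phylum", "class",
             "order", "family"),
    name = c("root", "Bacteria", "Firmicutes", "Clostridia", "Bacilli",
             "Clostridiales", "Bacillales", "Clostridiales_fam",
             "Bacillales_fam", "Archaea", "Euryarchaeota", "Methanomicrobia",
             "Methanosarcinales", "Methanosarcinales_fam"),
    stringsAsFactors = FALSE))
}

# add species leaves under the three families of tiny_taxonomy()
tiny_taxonomy_species <- function() {
  tax <- as.data.frame(tiny_taxonomy())
  sp <- data.frame(
    taxon_id = 15:20,
    parent_id = c(8, 8, 9, 9, 14, 14),
    rank = "species",
    name = c("Clost_sp1", "Clost_sp2", "Bac_sp1", "Bac_sp2",
             "Methano_sp1", "Methano_sp2"),
    stringsAsFactors = FALSE)
  validate_taxonomy(rbind(tax, sp))
}

# minimal annotation table over the tiny taxonomy
tiny_annotations <- function() {
  data.frame(
    accession = c("A1", "A2", "B1", "M1", "K1", "X1"),
    uniref50_id = c("UniRef50_U1", "UniRef50_U1", "UniRef50_U2",
                    "UniRef50_U3", "UniRef50_KER", NA),
    taxon_id = c(15L, 16L, 17L, 19L, NA, 18L),
    processes = c("glycolysis", "glycolysis;transport", "transport",
                  "methanogenesis", "keratin", "proteolysis"),
    ec_numbers = c("", "", "", "", "", ""),
    ko_ids = c("K00001", "K00001", "K00002", "K00003", "", ""),
    is_contaminant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

tiny_psms <- function() {
  data.frame(
    sample_id   = c("S1", "S1", "S1", "S2", "S2", "S2"),
    spectrum_id = c("sp1", "sp2", "sp3", "sp1", "sp2", "sp3"),
    peptide     = c("PEPTIDEA", "PEPTIDEB", "PEPTIDEC",
                    "PEPTIDEA", "PEPTIDED", "PEPTIDEE"),
    proteins    = c("A1;A2", "B1", "M1", "A1", "X1", "K1"),
    score       = c(55, 48, 60, 70, 45, 90),
    stringsAsFactors = FALSE)
}

# small simulation config used wherever the property is size-independent
small_config <- function(...) {
  sim_config(n_samples_per_group = 2, n_spectra_per_sample = 400,
             n_metaproteins = 60, n_orders = 12, n_singletons = 4,
             n_contaminants = 2, ...)
}

# random taxonomy for oracle checks: a random parent forest grown rank by
# rank, independent of make_taxonomy()
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  ranks <- c("root", "superkingdom", "phylum", "class",
             "order", "family", "genus", "species")
  ids <- seq_len(n_nodes)
  parent <- integer(n_nodes)
  rank <- character(n_nodes)
  depth <- integer(n_nodes)
  parent[1] <- 1L; rank[1] <- "root"; depth[1] <- 1L
  for (i in ids[-1]) {
    cand <- which(depth[seq_len(i - 1L)] < length(ranks))
    p <- cand[sample.int(length(cand), 1)]
    parent[i] <- p
    depth[i] <- depth[p] + 1L
    rank[i] <- ranks[depth[i]]
  }
  validate_taxonomy(data.frame(taxon_id = ids, parent_id = parent,
                               rank = rank, name = paste0("n", ids),
                               stringsAsFactors = FALSE))
}

# brute-force LCA oracle: intersect full lineages, take the deepest node
lca_oracle <- function(taxon_ids, taxonomy) {
  ids <- unique(taxon_ids[!is.na(taxon_ids)])
  if (!length(ids)) return(attr(taxonomy, "root"))
  paths <- lapply(ids, function(id) lineage(taxonomy, id))
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(x) length(lineage(taxonomy, x)), integer(1))
  common[which.max(depths)]
}
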