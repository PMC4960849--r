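#' Synthetic metaproteome studies with planted structure
#'
#' The generator emulates a multi-plant anaerobic-digester survey at the
#' PSM level: ~4000 identified spectra per sample drawn multinomially over
#' metaprotein probabilities, four plant groups (mesophile, thermophile,
#' UASB, sewage sludge) with group-signature taxonomic orders, planted
#' rank correlations between process parameters and selected features,
#' and a planted marker metaprotein enriched above a TAN threshold.
#' Ground truth (group labels, signature features, planted associations,
#' true per-sample feature probabilities) is returned for recovery tests.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline is tested under:
#' 4 groups x 10 samples, 4000 spectra/sample, 40 orders over two
#' superkingdoms, 300 UniRef50 metaproteins, a 2.0 log-fold group effect
#' on signature features, and planted parameter-feature Spearman
#' correlations of 0.7.
#'
#' @param n_samples_per_group samples per plant group (default 10).
#' @param n_spectra_per_sample identified spectra per sample (default 4000).
#' @param n_orders taxonomic orders across the two superkingdoms.
#' @param n_metaproteins number of UniRef50 clusters.
#' @param group_effect log-fold enrichment of group-signature features and
#'   of the planted marker feature (default 2.0; 0 disables).
#' @param corr_strength target Spearman rho of planted parameter-feature
#'   associations, in `[0, 1]` (default 0.7; 0 disables planting).
#' @param frac_archaea_orders fraction of orders placed under Archaea.
#' @param n_signature_orders signature orders per group.
#' @param metagenome_fraction fraction of cluster member accessions that
#'   are unannotated metagenome accessions (annotation via homology).
#' @param fraction_fail_evalue fraction of homology hits drawn with
#'   e-value above the 1e-4 transfer cutoff.
#' @param contaminant_fraction share of spectra drawn from contaminant
#'   (keratin-like) accessions.
#' @param n_contaminants number of contaminant accessions.
#' @param n_singletons annotated accessions without UniRef50 membership
#'   (become surrogate singleton metaproteins downstream).
#' @param fraction_low_score fraction of PSMs drawn below the score-40
#'   identification threshold.
#' @param shared_peptide_fraction fraction of peptides shared between two
#'   UniRef50 clusters (exercises the shared-spectrum assignment rule).
#' @param assoc_slope log-scale slope tying planted features to their
#'   latent parameter variate.
#' @param depth_jitter relative uniform jitter on per-sample depth
#'   (default 0: fixed depth).
#' @param dirichlet_theta optional Dirichlet concentration for per-sample
#'   overdispersion of feature probabilities (NULL = off).
#' @param groups group labels (length 4 by default).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples_per_group = 10,
                       n_spectra_per_sample = 4000,
                       n_orders = 40,
                       n_metaproteins = 300,
                       group_effect = 2.0,
                       corr_strength = 0.7,
                       frac_archaea_orders = 0.25,
                       n_signature_orders = 3,
                       metagenome_fraction = 0.30,
                       fraction_fail_evalue = 0.2,
                       contaminant_fraction = 0.01,
                       n_contaminants = 4,
                       n_singletons = 10,
                       fraction_low_score = 0.05,
                       shared_peptide_fraction = 0.02,
                       assoc_slope = 0.6,
                       depth_jitter = 0,
                       dirichlet_theta = NULL,
                       groups = c("mesophile", "thermophile", "UASB",
                                  "sewage_sludge")) {
  cfg <- as.list(environment())
  counts <- c("n_samples_per_group", "n_spectra_per_sample", "n_orders",
              "n_metaproteins", "n_signature_orders")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1)
      stopf("%s must be a positive count", nm)
  if (cfg$corr_strength < 0 || cfg$corr_strength > 1)
    stopf("corr_strength must lie in [0, 1]")
  if (cfg$n_orders < 2) stopf("n_orders must be at least 2")
  structure(cfg, class = "sim_config")
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

ORDER_NAMES_BACTERIA <- c(
  "Clostridiales", "Bacillales", "Enterobacteriales", "Rhizobiales",
  "Bacteroidales", "Thermoanaerobacteriales", "Thermotogales",
  "Spirochaetales", "Lactobacillales", "Pseudomonadales", "Burkholderiales",
  "Desulfovibrionales", "Syntrophobacterales", "Actinomycetales",
  "Flavobacteriales", "Deinococcales", "Nitrosomonadales", "Rhodocyclales",
  "Sphingobacteriales", "Erysipelotrichales", "Selenomonadales",
  "Synergistales", "Planctomycetales", "Verrucomicrobiales",
  "Fibrobacterales", "Chloroflexales", "Anaerolineales", "Natranaerobiales",
  "Halanaerobiales", "Fusobacteriales")
ORDER_NAMES_ARCHAEA <- c(
  "Methanobacteriales", "Methanosarcinales", "Methanococcales",
  "Methanomicrobiales", "Thermococcales", "Methanocellales",
  "Halobacteriales", "Sulfolobales", "Thermoplasmatales", "Archaeoglobales")

#' Build a synthetic eight-rank taxonomy
#'
#' Two superkingdoms (Bacteria, Archaea) with `n_orders` orders spread
#' over a handful of phyla/classes; every order carries at least one
#' species leaf. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a validated `taxonomy_table`.
#' @export
make_taxonomy <- function(config = sim_config(), seed = 1) {
  n_orders <- config$n_orders
  n_arch <- max(1L, round(config$frac_archaea_orders * n_orders))
  if (n_orders - n_arch < 1L) n_arch <- n_orders - 1L
  n_bac <- n_orders - n_arch

  with_seed(sub_seed(seed, 1), {
    rows <- list()
    next_id <- 0L
    add <- function(parent, rank, name) {
      next_id <<- next_id + 1L
      rows[[next_id]] <<- list(taxon_id = next_id,
                               parent_id = if (is.na(parent)) next_id else parent,
                               rank = rank, name = name)
      next_id
    }
    root <- add(NA, "root", "root")
    sk <- list(
      Bacteria = list(
        id = add(root, "superkingdom", "Bacteria"),
        phyla = list(Firmicutes = c("Clostridia", "Bacilli"),
                     Proteobacteria = c("Gammaproteobacteria",
                                        "Alphaproteobacteria",
                                        "Deltaproteobacteria"),
                     Bacteroidetes = c("Bacteroidia"),
                     Thermotogae = c("Thermotogae_class"),
                     Spirochaetes = c("Spirochaetia")),
        n = n_bac, pool = ORDER_NAMES_BACTERIA),
      Archaea = list(
        id = add(root, "superkingdom", "Archaea"),
        phyla = list(Euryarchaeota = c("Methanomicrobia", "Methanobacteria",
                                       "Thermococci"),
                     Crenarchaeota = c("Thermoprotei")),
        n = n_arch, pool = ORDER_NAMES_ARCHAEA))
    for (sk_name in names(sk)) {
      info <- sk[[sk_name]]
      class_ids <- character(0)
      for (ph in names(info$phyla)) {
        ph_id <- add(info$id, "phylum", ph)
        for (cl in info$phyla[[ph]])
          class_ids <- c(class_ids, add(ph_id, "class", cl))
      }
      class_ids <- as.integer(class_ids)
      pool <- info$pool
      extra <- info$n - length(pool)
      if (extra > 0)
        pool <- c(pool, sprintf("Order%s%02d", substr(sk_name, 1, 1),
                                seq_len(extra)))
      for (i in seq_len(info$n)) {
        cl_id <- class_ids[((i - 1L) %% length(class_ids)) + 1L]
        o_id <- add(cl_id, "order", pool[[i]])
        f_id <- add(o_id, "family", paste0(pool[[i]], "_fam"))
        n_gen <- sample(1:2, 1)
        for (g in seq_len(n_gen)) {
          g_id <- add(f_id, "genus", sprintf("%s_gen%d", pool[[i]], g))
          n_sp <- sample(1:3, 1)
          for (s in seq_len(n_sp))
            add(g_id, "species", sprintf("%s_gen%d_sp%d", pool[[i]], g, s))
        }
      }
    }
    validate_taxonomy(data.table::rbindlist(rows))
  })
}

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# unique peptide strings: random 9-mer prefix + base-20 encoding of an index
make_peptides <- function(n) {
  prefix <- vapply(seq_len(n), function(i)
    paste(AA[sample.int(20, 9, replace = TRUE)], collapse = ""), character(1))
  suffix <- vapply(seq_len(n), function(i) {
    v <- character(0); x <- i
    while (x > 0) { v <- c(AA[(x %% 20) + 1L], v); x <- x %/% 20 }
    paste(v, collapse = "")
  }, character(1))
  paste0(prefix, suffix)
}

KEYWORD_POOL <- c("methanogenesis", "transport", "one-carbon metabolism",
                  "glycolysis", "amino-acid biosynthesis", "DNA repair",
                  "DNA recombination", "lipid metabolism",
                  "short-chain fatty-acid metabolism", "nitrate assimilation",
                  "proteolysis", "cell adhesion")
KO_POOL <- sprintf("K%05d", 1:60)
PATHWAY_POOL <- c("map01200", "map00010", "map00680", "map00720", "map02010")

#' Build a synthetic protein database (annotations + homology table)
#'
#' Each of `n_metaproteins` UniRef50 clusters owns 1-10 member accessions
#' whose species fall in one (mostly) or two taxonomic orders. A fraction
#' of members are unannotated metagenome accessions that appear only in
#' the homology table, with e-values drawn so that a configurable
#' fraction fail the 1e-4 transfer cutoff. A few contaminant
#' (keratin-like) accessions and UniRef50-less singleton accessions are
#' added.
#'
#' @param taxonomy taxonomy from [make_taxonomy()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `annotations`, `homology`, `members` (accession ->
#'   cluster/taxon map incl. unannotated members), `clusters`
#'   (cluster -> order(s)), `ko_pathway` (KO -> pathway map).
#' @export
make_protein_db <- function(taxonomy, config = sim_config(), seed = 1) {
  tax <- as_taxonomy(taxonomy)
  species <- tax$taxon_id[tax$rank == "species"]
  sp_order <- vapply(species, function(id)
    ancestor_at_rank(tax, id, "order"), integer(1))
  orders <- unique(sp_order)
  sp_class <- vapply(species, function(id)
    ancestor_at_rank(tax, id, "class"), integer(1))
  ord_class <- vapply(orders, function(o)
    sp_class[match(o, sp_order)], integer(1))

  with_seed(sub_seed(seed, 2), {
    n_mp <- config$n_metaproteins
    cluster_id <- sprintf("UniRef50_S%04d", seq_len(n_mp))
    single <- runif(n_mp) < 0.8
    mem <- list(); hom <- list(); clus <- list()
    acc_counter <- 0L
    new_acc <- function(prefix) {
      acc_counter <<- acc_counter + 1L
      sprintf("%s%05d", prefix, acc_counter)
    }
    kw <- lapply(seq_len(n_mp), function(i)
      sample(KEYWORD_POOL, sample(1:3, 1)))
    ko <- lapply(seq_len(n_mp), function(i)
      if (runif(1) < 0.7) sample(KO_POOL, sample(1:2, 1)) else character(0))
    for (i in seq_len(n_mp)) {
      o1 <- sample(orders, 1)
      if (single[i]) {
        cl_orders <- o1
      } else {
        sib <- orders[ord_class == ord_class[match(o1, orders)] & orders != o1]
        o2 <- if (length(sib)) sample(sib, 1) else sample(setdiff(orders, o1), 1)
        cl_orders <- c(o1, o2)
      }
      n_members <- min(10L, 1L + stats::rpois(1, 1.5))
      sp_pool <- species[sp_order %in% cl_orders]
      taxa <- sample(sp_pool, n_members, replace = TRUE)
      is_mg <- runif(n_members) < config$metagenome_fraction
      is_mg[1] <- FALSE  # at least one directly annotated member per cluster
      accs <- character(n_members)
      for (j in seq_len(n_members))
        accs[j] <- new_acc(if (is_mg[j]) "MG" else "P")
      mem[[i]] <- data.table::data.table(
        accession = accs, cluster_id = cluster_id[i], taxon_id = taxa,
        metagenome = is_mg)
      # homology: metagenome member -> annotated member of same cluster
      ann_accs <- accs[!is_mg]
      for (j in which(is_mg)) {
        fail <- runif(1) < config$fraction_fail_evalue
        e1 <- if (fail) 10^runif(1, -3.9, -0.5) else 10^runif(1, -30, -4.1)
        hom[[length(hom) + 1L]] <- data.table::data.table(
          query_accession = accs[j],
          subject_accession = sample(ann_accs, 1), e_value = e1)
        if (runif(1) < 0.3)  # decoy second hit, strictly worse
          hom[[length(hom) + 1L]] <- data.table::data.table(
            query_accession = accs[j],
            subject_accession = sample(ann_accs, 1),
            e_value = min(e1 * 10^runif(1, 1, 5), 10))
      }
      clus[[i]] <- data.table::data.table(
        cluster_id = cluster_id[i],
        orders = paste(taxon_name(tax, cl_orders), collapse = ";"),
        single_order = single[i], order_id = cl_orders[1])
    }
    members <- data.table::rbindlist(mem)
    # singleton accessions: annotated but no UniRef50 membership
    singl <- data.table::data.table(
      accession = sprintf("P9%04d", seq_len(config$n_singletons)),
      cluster_id = NA_character_,
      taxon_id = sample(species, config$n_singletons, replace = TRUE),
      metagenome = FALSE)
    # contaminants
    cont <- data.table::data.table(
      accession = sprintf("CON_KER%02d", seq_len(config$n_contaminants)),
      cluster_id = sprintf("UniRef50_KER%02d", seq_len(config$n_contaminants)),
      taxon_id = NA_integer_, metagenome = FALSE)

    ann_m <- members[!members$metagenome, ]
    kw_of <- function(cid) paste(kw[[match(cid, cluster_id)]], collapse = ";")
    ko_of <- function(cid) paste(ko[[match(cid, cluster_id)]], collapse = ";")
    annotations <- rbind(
      data.frame(accession = ann_m$accession,
                 uniref50_id = ann_m$cluster_id,
                 taxon_id = ann_m$taxon_id,
                 processes = vapply(ann_m$cluster_id, kw_of, character(1)),
                 ec_numbers = "",
                 ko_ids = vapply(ann_m$cluster_id, ko_of, character(1)),
                 is_contaminant = FALSE, stringsAsFactors = FALSE),
      data.frame(accession = singl$accession, uniref50_id = NA_character_,
                 taxon_id = singl$taxon_id,
                 processes = sample(KEYWORD_POOL, nrow(singl), replace = TRUE),
                 ec_numbers = "", ko_ids = "",
                 is_contaminant = FALSE, stringsAsFactors = FALSE),
      data.frame(accession = cont$accession, uniref50_id = cont$cluster_id,
                 taxon_id = NA_integer_, processes = "keratin",
                 ec_numbers = "", ko_ids = "",
                 is_contaminant = TRUE, stringsAsFactors = FALSE))
    homology <- if (length(hom)) as.data.frame(data.table::rbindlist(hom))
      else data.frame(query_accession = character(0),
                      subject_accession = character(0), e_value = numeric(0))
    ko_used <- sort(unique(unlist(ko)))
    ko_pathway <- data.frame(
      ko_id = ko_used,
      pathway = PATHWAY_POOL[(match(ko_used, KO_POOL) - 1L) %%
                               length(PATHWAY_POOL) + 1L],
      stringsAsFactors = FALSE)
    list(annotations = annotations, homology = homology,
         members = rbind(members, singl, cont),
         clusters = as.data.frame(data.table::rbindlist(clus)),
         ko_pathway = ko_pathway)
  })
}

# Gaussian-copula noise sd per side so that Spearman(param, feature) hits
# the target: rho_S = (6/pi) asin(r/2) with r = corr of the two noisy
# latents; each side gets N(0, sigma^2) noise, r = 1/(1+sigma^2).
copula_noise_sd <- function(rho_s) {
  r <- 2 * sin(pi * rho_s / 6)
  sqrt(1 / r - 1)
}

#' Simulate a full proteotyping study
#'
#' Generates the PSM table, process-parameter table and all reference
#' tables (taxonomy, annotations, homology, KO->pathway map) for one
#' synthetic survey, plus the ground truth needed for recovery tests.
#' Group labels scale signature-order metaproteins by
#' `exp(group_effect)`; planted associations rank-couple TAN (+) and OLR
#' (-) to one metaprotein each at Spearman `corr_strength`; one marker
#' metaprotein is enriched `exp(group_effect)`-fold in samples with
#' TAN > 4200 mg/L. Spectra are drawn multinomially at fixed per-sample
#' depth. Byte-identical outputs for identical (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `psms`, `parameters`, `taxonomy`, `annotations`,
#'   `homology`, `ko_pathway`, `ground_truth`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n_groups <- length(config$groups)
  n_samples <- n_groups * config$n_samples_per_group
  if (config$corr_strength > 0 && n_samples < 5)
    stopf("planted correlations need at least 5 samples (have %d)", n_samples)

  taxonomy <- make_taxonomy(config, seed)
  db <- make_protein_db(taxonomy, config, seed)

  members <- data.table::as.data.table(db$members)
  clusters <- db$clusters
  # feature universe: UniRef50 clusters, singleton surrogates, contaminants
  singleton_acc <- members$accession[is.na(members$cluster_id)]
  cont_clusters <- grep("^UniRef50_KER", members$cluster_id, value = TRUE)
  feat_id <- c(clusters$cluster_id, paste0("ACC:", singleton_acc),
               unique(cont_clusters))
  nf <- length(feat_id)
  n_real <- nrow(clusters)
  is_cont_feat <- seq_len(nf) > nf - length(unique(cont_clusters))
  is_singleton_feat <- !is_cont_feat & seq_len(nf) > n_real

  sample_id <- sprintf("BGP%02d", seq_len(n_samples))
  group <- rep(config$groups, each = config$n_samples_per_group)

  gt_env <- with_seed(sub_seed(seed, 3), {
    base_w <- exp(rnorm(nf, 0, 1.2))
    base_w[is_singleton_feat] <- base_w[is_singleton_feat] * 0.1
    w_cont_target <- config$contaminant_fraction
    if (any(is_cont_feat)) {
      tot_main <- sum(base_w[!is_cont_feat])
      base_w[is_cont_feat] <- w_cont_target * tot_main /
        max(1 - w_cont_target, 1e-9) / sum(is_cont_feat)
    }

    # signature orders: single-order clusters only, orders with most
    # clusters first, dealt round-robin to the groups
    so <- clusters[clusters$single_order, ]
    ord_tab <- sort(table(so$order_id), decreasing = TRUE)
    avail <- as.integer(names(ord_tab))
    # reserve the three thinnest orders for the planted features so they
    # never collide with a group signature
    assignable <- head(avail, max(0L, length(avail) - 3L))
    n_sig <- min(config$n_signature_orders,
                 floor(length(assignable) / n_groups))
    if (n_sig < 1L)
      stopf("n_orders too small to give each of the %d groups a signature order plus planted features",
            n_groups)
    sig_orders <- stats::setNames(vector("list", n_groups), config$groups)
    k <- 1L
    for (r in seq_len(n_sig)) for (g in seq_len(n_groups)) {
      sig_orders[[g]] <- c(sig_orders[[g]], assignable[k]); k <- k + 1L
    }
    sig_features <- lapply(sig_orders, function(os)
      clusters$cluster_id[clusters$single_order & clusters$order_id %in% os])

    # planted features: high-abundance single-order clusters outside the
    # signature sets
    taken <- unlist(sig_features)
    cand <- clusters$cluster_id[clusters$single_order &
                                  !(clusters$cluster_id %in% taken)]
    cand <- cand[order(-base_w[match(cand, feat_id)])]
    feat_tan <- cand[1]; feat_olr <- cand[2]; feat_marker <- cand[3]

    # latent variates for planted associations
    plant <- config$corr_strength > 0
    sig_n <- if (plant) copula_noise_sd(config$corr_strength) else NA_real_
    z_tan <- rnorm(n_samples); z_olr <- rnorm(n_samples)
    if (plant) {
      u_tan <- pnorm((z_tan + rnorm(n_samples, 0, sig_n)) / sqrt(1 + sig_n^2))
      u_olr <- pnorm((z_olr + rnorm(n_samples, 0, sig_n)) / sqrt(1 + sig_n^2))
      m_tan <- (z_tan + rnorm(n_samples, 0, sig_n)) / sqrt(1 + sig_n^2)
      m_olr <- (z_olr + rnorm(n_samples, 0, sig_n)) / sqrt(1 + sig_n^2)
    } else {
      u_tan <- runif(n_samples); u_olr <- runif(n_samples)
      m_tan <- m_olr <- rep(0, n_samples)
    }
    TAN <- exp(log(1500) + (log(9000) - log(1500)) * u_tan)
    OLR <- exp(log(1.5) + (log(11) - log(1.5)) * u_olr)

    # per-sample feature probabilities: group-signature boosts act on the
    # community background; the planted features' probability shares are
    # set directly (exactly monotone in their latent variate), and the
    # background is scaled into the complement, so the planted rank
    # correlations are attained in expectation rather than attenuated by
    # denominator drift
    ge <- config$group_effect
    i_tan <- match(feat_tan, feat_id)
    i_olr <- match(feat_olr, feat_id)
    i_mark <- match(feat_marker, feat_id)
    W <- matrix(base_w, nf, n_samples)
    W[c(i_tan, i_olr, i_mark), ] <- 0
    if (ge != 0) {
      for (g in seq_len(n_groups)) {
        idx <- match(sig_features[[g]], feat_id)
        W[idx, group == config$groups[g]] <-
          W[idx, group == config$groups[g]] * exp(ge)
      }
    }
    q <- sweep(W, 2, colSums(W), "/")
    share_tan <- 0.015 * if (plant) exp(config$assoc_slope * m_tan) else 1
    share_olr <- 0.015 * if (plant) exp(-config$assoc_slope * m_olr) else 1
    share_mark <- 0.010 * ifelse(ge != 0 & TAN > 4200, exp(ge), 1)
    tot_planted <- share_tan + share_olr + share_mark
    probs <- sweep(q, 2, 1 - tot_planted, "*")
    probs[i_tan, ] <- share_tan
    probs[i_olr, ] <- share_olr
    probs[i_mark, ] <- share_mark
    if (!is.null(config$dirichlet_theta)) {
      for (s in seq_len(n_samples)) {
        g <- stats::rgamma(nf, shape = config$dirichlet_theta * probs[, s])
        probs[, s] <- g / sum(g)
      }
    }
    dimnames(probs) <- list(feat_id, sample_id)

    # process parameters
    temperature <- numeric(n_samples)
    temperature[group == "mesophile"] <- runif(sum(group == "mesophile"), 33, 35)
    temperature[group == "thermophile"] <- runif(sum(group == "thermophile"), 40, 54)
    temperature[group == "UASB"] <- runif(sum(group == "UASB"), 33, 38)
    temperature[group == "sewage_sludge"] <- runif(sum(group == "sewage_sludge"), 33, 38)
    parameters <- data.frame(
      sample_id = sample_id,
      temperature = round(temperature, 1),
      OLR = round(OLR, 2),
      TAN = round(TAN, 0),
      SRT = round(runif(n_samples, 15, 120), 0),
      pH = round(runif(n_samples, 7.1, 8.6), 2),
      VFA = round(exp(rnorm(n_samples, log(2000), 0.8)), 0),
      reactor_type = ifelse(group == "UASB", "UASB", "CSTR"),
      substrate = ifelse(group == "sewage_sludge", "sewage_sludge",
                         sample(c("agricultural", "industrial_waste",
                                  "municipal_waste", "mixed"),
                                n_samples, replace = TRUE)),
      stringsAsFactors = FALSE)

    list(probs = probs, parameters = parameters,
         sig_orders = lapply(sig_orders, function(os) taxon_name(taxonomy, os)),
         sig_features = sig_features,
         planted = data.frame(
           parameter = c("TAN", "OLR"),
           feature = c(feat_tan, feat_olr),
           sign = c(1L, -1L),
           target_rho = rep(if (plant) config$corr_strength else 0, 2),
           stringsAsFactors = FALSE),
         marker = list(parameter = "TAN", feature = feat_marker,
                       threshold = 4200, log_fold = ge),
         latents = list(u_tan = u_tan, m_tan = m_tan,
                        u_olr = u_olr, m_olr = m_olr))
  })

  psms <- with_seed(sub_seed(seed, 4), {
    # peptide pools: each feature owns >=3 peptides, each peptide mapped
    # to 1-3 member accessions; a small fraction of cluster peptides are
    # shared with a second cluster (ambiguous spectra)
    memb_by_feat <- vector("list", nf)
    memb_by_feat[seq_len(n_real)] <- split(
      members$accession[!is.na(members$cluster_id) &
                          !(members$cluster_id %in% cont_clusters)],
      factor(members$cluster_id[!is.na(members$cluster_id) &
                                  !(members$cluster_id %in% cont_clusters)],
             levels = clusters$cluster_id))
    memb_by_feat[which(is_singleton_feat)] <- as.list(singleton_acc)
    memb_by_feat[which(is_cont_feat)] <- split(
      members$accession[members$cluster_id %in% cont_clusters],
      factor(members$cluster_id[members$cluster_id %in% cont_clusters],
             levels = unique(cont_clusters)))

    npep <- pmax(3L, 2L * lengths(memb_by_feat))
    total_pep <- sum(npep)
    pep_seq <- make_peptides(total_pep)
    pool_feat <- rep(seq_len(nf), npep)
    pool_prot <- character(total_pep)
    pos <- 1L
    for (f in seq_len(nf)) {
      mm <- memb_by_feat[[f]]
      for (j in seq_len(npep[f])) {
        k <- sample.int(min(3L, length(mm)), 1)
        accs <- sample(mm, k)
        if (f <= n_real && runif(1) < config$shared_peptide_fraction) {
          other <- sample.int(n_real, 1)
          if (other != f)
            accs <- c(accs, sample(memb_by_feat[[other]], 1))
        }
        pool_prot[pos] <- paste(accs, collapse = ";")
        pos <- pos + 1L
      }
    }
    pool_start <- c(0L, cumsum(npep))[seq_len(nf)]

    out <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      depth <- config$n_spectra_per_sample
      if (config$depth_jitter > 0)
        depth <- max(1L, round(depth * (1 + runif(1, -config$depth_jitter,
                                                  config$depth_jitter))))
      cnt <- as.integer(rmultinom(1, depth, gt_env$probs[, s]))
      fidx <- rep.int(seq_len(nf), cnt)
      n <- length(fidx)
      pidx <- pool_start[fidx] + floor(runif(n) * npep[fidx]) + 1L
      low <- runif(n) < config$fraction_low_score
      score <- ifelse(low, runif(n, 10, 39.99), 40 + rexp(n, 1 / 30))
      ord <- sample.int(n)
      out[[s]] <- data.table::data.table(
        sample_id = sample_id[s],
        spectrum_id = sprintf("sp%05d", seq_len(n)),
        peptide = pep_seq[pidx][ord],
        proteins = pool_prot[pidx][ord],
        score = round(score, 2)[ord])
    }
    as.data.frame(data.table::rbindlist(out))
  })

  ground_truth <- list(
    groups = stats::setNames(group, sample_id),
    signature_orders = gt_env$sig_orders,
    signature_features = gt_env$sig_features,
    planted = gt_env$planted,
    marker = gt_env$marker,
    latents = gt_env$latents,
    probs = gt_env$probs,
    config = unclass(config), seed = seed)

  list(psms = psms, parameters = gt_env$parameters, taxonomy = taxonomy,
       annotations = db$annotations, homology = db$homology,
       ko_pathway = db$ko_pathway, ground_truth = ground_truth)
}
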