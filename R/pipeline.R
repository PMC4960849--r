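#' End-to-end proteotyping pipeline
#'
#' [analyze_study()] runs the full in-memory chain on one study's tables:
#' score filter -> annotation transfer -> contaminant/unknown exclusion
#' -> UniRef50 grouping with LCA taxonomy -> abundance matrices
#' (metaprotein / order / process / pathway) -> 1% filter -> core
#' reports -> community indices -> z-score clustering with permutation
#' test -> PCA -> correlation screen and network -> marker trees.
#' [run_pipeline()] wraps it with file input/output and a provenance
#' record; outputs are byte-identical for identical config + seed.
#'
#' @name pipeline
NULL

#' Analyze one study in memory
#'
#' @param study list with `psms`, `parameters`, `taxonomy`,
#'   `annotations`, `homology`, `ko_pathway` (e.g. from
#'   [simulate_study()]).
#' @param min_score PSM score threshold (default 40).
#' @param max_e homology-transfer e-value cutoff (default 1e-4).
#' @param min_pct abundance filter threshold in percent (default 1).
#' @param k number of flat clusters to cut (default 4).
#' @param n_perm permutation-test replications (default 1000).
#' @param n_components PCA components to retain (default 2).
#' @param alpha network significance level (default 0.05).
#' @param marker_params named list parameter -> threshold spec for marker
#'   discovery (default: the literature thresholds plus OLR at median).
#' @param shared shared-spectrum counting mode.
#' @param seed integer seed; every stochastic stage receives a derived
#'   sub-seed.
#' @param group_labels optional named group labels for the permutation
#'   test (defaults to ground truth when `study` carries it, else the
#'   k-cut cluster labels).
#' @return list of all intermediate and final results (see names).
#' @export
analyze_study <- function(study, min_score = 40, max_e = 1e-4, min_pct = 1,
                          k = 4, n_perm = 1000, n_components = 2,
                          alpha = 0.05,
                          marker_params = c(default_thresholds(),
                                            list(OLR = "median")),
                          shared = "unique", seed = 1,
                          group_labels = NULL) {
  psms <- filter_psms(study$psms, min_score)
  ann <- transfer_annotations(study$annotations, study$homology, max_e)
  psms <- exclude_contaminants(psms, ann)
  profile <- group_metaproteins(psms, ann, study$taxonomy, shared = shared)

  counts <- list(
    metaprotein = count_matrix(profile, "metaprotein"),
    order = count_matrix(profile, "order", taxonomy = study$taxonomy),
    process = count_matrix(profile, "process"),
    pathway = count_matrix(profile, "pathway",
                           ko_pathway = study$ko_pathway))
  abundance <- lapply(names(counts), function(lv)
    normalize_abundance(counts[[lv]], level = lv))
  names(abundance) <- names(counts)
  filtered <- lapply(abundance, filter_min_abundance,
                     min_pct = min_pct, min_samples = 1)

  core <- lapply(filtered, core_features)
  indices <- community_indices(filtered$order,
                               n_spectra = colSums(counts$metaprotein))

  z <- zscore_rows(filtered$metaprotein)
  clust <- hierarchical_cluster(z, k = k)
  if (is.null(group_labels))
    group_labels <- study$ground_truth$groups %||%
      stats::setNames(paste0("cluster", clust$labels), colnames(z))
  perm <- cluster_permutation_test(z, group_labels[colnames(z)],
                                   n_perm = n_perm,
                                   seed = sub_seed(seed, 101))
  pcas <- lapply(filtered[c("order", "process", "metaprotein")],
                 pca, n_components = n_components)

  screen <- correlation_screen(filtered$order, study$parameters)
  network <- build_network(screen, alpha = alpha)

  markers <- list()
  mp <- t(filtered$metaprotein)  # samples x features for CART
  params <- study$parameters
  for (pname in names(marker_params)) {
    if (!pname %in% names(params)) next
    labs <- binarize_parameter(params[[pname]][match(rownames(mp),
                                                     params$sample_id)],
                               marker_params[[pname]])
    if (nlevels(droplevels(labs)) < 2) next
    markers[[pname]] <- train_test_marker(
      mp, labs, seed = sub_seed(seed, 300 + match(pname, names(marker_params))))
    markers[[pname]]$threshold <- attr(labs, "threshold")
    markers[[pname]]$threshold_source <- attr(labs, "threshold_source")
  }

  list(psms_retained = psms, annotations = ann, profile = profile,
       counts = counts, abundance = abundance, filtered = filtered,
       core = core, indices = indices, zscores = z, clustering = clust,
       permutation = perm, pca = pcas, correlations = screen,
       network = network, markers = markers,
       settings = list(min_score = min_score, max_e = max_e,
                       min_pct = min_pct, k = k, n_perm = n_perm,
                       alpha = alpha, shared = shared, seed = seed))
}

#' Run the pipeline and write every output table
#'
#' Simulates a study (or reads the input tables named in `config$inputs`)
#' and writes all intermediate and final tables, the GEXF network, a
#' marker summary and a provenance JSON under `out_dir`.
#'
#' @param config list; recognised fields: `sim` (a [sim_config()], used
#'   when `inputs` is NULL), `inputs` (named paths: psms, parameters,
#'   taxonomy, annotations, homology, ko_pathway), `seed`, plus any
#'   argument of [analyze_study()] (min_score, max_e, min_pct, k,
#'   n_perm, n_components, alpha).
#' @param out_dir output directory (created if needed).
#' @return the [analyze_study()] result, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  if (is.null(config$inputs)) {
    study <- simulate_study(config$sim %||% sim_config(), seed = seed)
    gt_json <- study$ground_truth[c("groups", "signature_orders",
                                    "signature_features", "planted",
                                    "marker")]
    gt_json$groups <- as.list(gt_json$groups)  # named JSON object
    jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_psm_table(study$psms, file.path(out_dir, "psms.tsv"))
    write_parameter_table(study$parameters, file.path(out_dir, "parameters.tsv"))
    write_taxonomy(study$taxonomy, file.path(out_dir, "taxonomy.tsv"))
    write_annotation_table(study$annotations, file.path(out_dir, "annotations.tsv"))
    write_homology_table(study$homology, file.path(out_dir, "homology.tsv"))
    write_tsv(study$ko_pathway, file.path(out_dir, "ko_pathway.tsv"))
  } else {
    inp <- config$inputs
    study <- list(psms = read_psm_table(inp$psms),
                  parameters = read_parameter_table(inp$parameters),
                  taxonomy = read_taxonomy(inp$taxonomy),
                  annotations = read_annotation_table(inp$annotations),
                  homology = read_homology_table(inp$homology),
                  ko_pathway = if (!is.null(inp$ko_pathway))
                    read_tsv_checked(inp$ko_pathway, c("ko_id", "pathway"),
                                     "ko_pathway") else
                    data.frame(ko_id = character(0), pathway = character(0)))
  }

  args <- config[intersect(names(config),
                           c("min_score", "max_e", "min_pct", "k", "n_perm",
                             "n_components", "alpha", "shared"))]
  res <- do.call(analyze_study, c(list(study = study, seed = seed), args))

  for (lv in names(res$abundance))
    write_matrix(res$abundance[[lv]],
                 file.path(out_dir, sprintf("abundance_%s.tsv", lv)))
  for (lv in names(res$filtered))
    write_matrix(res$filtered[[lv]],
                 file.path(out_dir, sprintf("abundance_%s_filtered.tsv", lv)))
  for (lv in names(res$core))
    write_tsv(res$core[[lv]], file.path(out_dir, sprintf("core_%s.tsv", lv)))
  write_tsv(res$indices, file.path(out_dir, "community_indices.tsv"))
  corr <- res$correlations
  corr$rho <- signif(corr$rho, 12); corr$p_value <- signif(corr$p_value, 12)
  corr$p_adjusted <- signif(corr$p_adjusted, 12)
  write_tsv(corr, file.path(out_dir, "correlations.tsv"))
  export_network_gexf(res$network, file.path(out_dir, "network.gexf"),
                      file.path(out_dir, "network.edges.tsv"))
  marker_summary <- data.frame(
    parameter = names(res$markers),
    marker = vapply(res$markers, function(m) m$marker %||% NA_character_,
                    character(1)),
    threshold = vapply(res$markers, function(m) m$threshold, numeric(1)),
    threshold_source = vapply(res$markers, function(m) m$threshold_source,
                              character(1)),
    train_error = vapply(res$markers, function(m) m$train_error, numeric(1)),
    test_error = vapply(res$markers, function(m) m$test_error, numeric(1)),
    stringsAsFactors = FALSE)
  write_tsv(marker_summary, file.path(out_dir, "markers.tsv"))

  prov <- list(settings = res$settings,
               n_psms_input = nrow(study$psms),
               n_psms_retained = nrow(res$psms_retained),
               n_metaproteins = nrow(res$profile$counts),
               n_features_filtered = vapply(res$filtered, nrow, integer(1)),
               permutation_p = res$permutation$p_value,
               variance_explained_2pc = vapply(res$pca, function(p)
                 sum(p$variance_explained_pct[1:2]), numeric(1)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
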