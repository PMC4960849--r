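#' Abundance matrices, the 1% filter and core features
#'
#' Metaprotein spectral counts are rolled up to taxonomic-order,
#' biological-process or pathway level, normalized to 100% of each
#' sample's spectra, filtered to features reaching at least 1% in at
#' least one sample, and summarized into core-community reports
#' (features present in every sample, with their minimum abundance).
#'
#' @name profiling
NULL

#' Roll a metaprotein profile up to a counting level
#'
#' * `metaprotein` — counts as-is, one row per metaprotein.
#' * `order` — counts added to the order-rank ancestor of the
#'   metaprotein's LCA taxon; metaproteins whose LCA sits above order
#'   rank (roughly half the peptides in real surveys cannot be placed at
#'   order level) are binned as `unassigned_order`.
#' * `process` — counts added once per biological-process keyword
#'   (spectra are deliberately duplicated across keywords; columns are
#'   renormalized later); keyword-less metaproteins go to
#'   `unassigned_process`.
#' * `pathway` — as `process`, via the KO -> pathway map.
#'
#' @param profile a `metaprotein_profile`.
#' @param level one of "metaprotein", "order", "process", "pathway".
#' @param taxonomy taxonomy table (required for level "order").
#' @param ko_pathway data.frame (ko_id, pathway) for level "pathway".
#' @return numeric count matrix, features x samples.
#' @export
count_matrix <- function(profile, level = c("metaprotein", "order",
                                            "process", "pathway"),
                         taxonomy = NULL, ko_pathway = NULL) {
  level <- match.arg(level)
  counts <- profile$counts
  meta <- profile$meta
  if (level == "metaprotein") {
    rownames(counts) <- meta$metaprotein_id
    return(counts)
  }
  if (level == "order") {
    if (is.null(taxonomy)) stopf("level 'order' needs a taxonomy")
    taxonomy <- as_taxonomy(taxonomy)
    ord <- vapply(meta$lca_taxon, function(id)
      ancestor_at_rank(taxonomy, id, "order"), integer(1))
    key <- ifelse(is.na(ord), "unassigned_order", taxon_name(taxonomy, ord))
    return(rowsum_matrix(counts, key))
  }
  sets <- if (level == "process") {
    split_multi(meta$processes)
  } else {
    if (is.null(ko_pathway)) stopf("level 'pathway' needs a ko_pathway map")
    lapply(split_multi(meta$ko_ids), function(ko) {
      pw <- unique(ko_pathway$pathway[match(ko, ko_pathway$ko_id)])
      pw[!is.na(pw)]
    })
  }
  unass <- paste0("unassigned_", level)
  sets <- lapply(sets, function(s) if (length(s)) s else unass)
  idx <- rep(seq_len(nrow(counts)), lengths(sets))
  rowsum_matrix(counts[idx, , drop = FALSE], unlist(sets))
}

rowsum_matrix <- function(m, key) {
  out <- rowsum(m, group = key, reorder = TRUE)
  as.matrix(out)
}

#' Normalize counts to percent of each sample's spectra
#'
#' Each column is scaled to sum to 100, so values are percentages of that
#' sample's total (retained) spectra.
#'
#' @param counts feature x sample count matrix.
#' @param level level tag stored on the result.
#' @return `abundance_matrix`: a numeric matrix with attributes `level`
#'   and `provenance`; columns sum to 100.
#' @export
normalize_abundance <- function(counts, level = "metaprotein") {
  tot <- colSums(counts)
  zero <- tot <= 0
  if (any(zero))
    stopf("all-zero sample column(s): %s",
          paste(colnames(counts)[zero], collapse = ", "))
  m <- sweep(counts, 2, tot, "/") * 100
  attr(m, "level") <- level
  attr(m, "provenance") <- list(column_totals = tot)
  class(m) <- c("abundance_matrix", class(m))
  m
}

#' Keep features reaching a minimum abundance in enough samples
#'
#' Retains rows with `value >= min_pct` in at least `min_samples`
#' columns — the study's ">= 1% of the spectra in at least one sample"
#' rule. Values are NOT renormalized: retained percentages remain
#' percentages of total sample spectra; the dropped mass per column is
#' recorded in the provenance attribute.
#'
#' @param m abundance matrix (percent).
#' @param min_pct minimum percent (default 1).
#' @param min_samples minimum number of samples (default 1).
#' @return filtered abundance matrix.
#' @export
filter_min_abundance <- function(m, min_pct = 1, min_samples = 1) {
  if (min_pct < 0) stopf("min_pct must be >= 0")
  if (min_samples < 1) stopf("min_samples must be >= 1")
  keep <- rowSums(m >= min_pct) >= min_samples
  out <- m[keep, , drop = FALSE]
  prov <- attr(m, "provenance") %||% list()
  prov$filter <- list(min_pct = min_pct, min_samples = min_samples,
                      n_dropped = sum(!keep),
                      dropped_mass = colSums(m[!keep, , drop = FALSE]))
  attr(out, "provenance") <- prov
  attr(out, "level") <- attr(m, "level")
  class(out) <- class(m)
  out
}

#' Core features across all samples
#'
#' A feature is core when its abundance is strictly above `floor` in
#' every sample; core features are reported with their minimum abundance
#' and the sample attaining it.
#'
#' @param m abundance matrix (percent).
#' @param floor detection floor (default 0: strict presence).
#' @return data.frame (feature, present_in_all, min_abundance,
#'   argmin_sample), sorted by feature.
#' @export
core_features <- function(m, floor = 0) {
  if (!nrow(m)) stopf("empty abundance matrix")
  present <- apply(m > floor, 1, all)
  amin <- apply(m, 1, which.min)
  data.frame(feature = rownames(m),
             present_in_all = unname(present),
             min_abundance = unname(apply(m, 1, min)),
             argmin_sample = colnames(m)[amin],
             stringsAsFactors = FALSE)
}

#' Per-group core comparison
#'
#' Applies [core_features()] within each sample group and reports, per
#' feature and group, whether it is core in that group and whether it is
#' entirely absent (all zero) there. Groups with a single sample are
#' allowed and flagged.
#'
#' @param m abundance matrix.
#' @param group_labels named (by sample) or positional group labels.
#' @return list with `per_group` (named list of core reports) and
#'   `contrasts` (features core in one group and absent in another).
#' @export
group_core_comparison <- function(m, group_labels) {
  if (is.null(names(group_labels))) names(group_labels) <- colnames(m)
  if (!all(colnames(m) %in% names(group_labels)))
    stopf("every sample needs a group label")
  labels <- group_labels[colnames(m)]
  groups <- unique(labels)
  per_group <- lapply(groups, function(g)
    core_features(m[, labels == g, drop = FALSE]))
  names(per_group) <- groups
  singletons <- groups[vapply(groups, function(g) sum(labels == g) == 1L,
                              logical(1))]
  contrasts <- list()
  for (g in groups) {
    core_g <- per_group[[g]]$feature[per_group[[g]]$present_in_all]
    for (h in setdiff(groups, g)) {
      absent_h <- rownames(m)[rowSums(m[, labels == h, drop = FALSE]) == 0]
      hit <- intersect(core_g, absent_h)
      if (length(hit))
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          feature = hit, core_in = g, absent_in = h, stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts)
    else data.frame(feature = character(0), core_in = character(0),
                    absent_in = character(0), stringsAsFactors = FALSE)
  list(per_group = per_group, contrasts = contrasts,
       single_sample_groups = singletons)
}
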