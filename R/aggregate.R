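#' From PSMs to metaproteins
#'
#' The aggregation chain mirrors standard metaproteome data handling:
#' score filtering (the 1% FDR threshold corresponds to a search score of
#' 40), homology transfer of annotations to metagenome accessions
#' (e-value <= 1e-4, best hit wins), exclusion of contaminant keratins
#' and of accessions left unannotated after transfer, grouping of
#' redundant identifications into UniRef50 "metaproteins", common-ancestor
#' (LCA) taxonomy per metaprotein, and per-sample spectral counting.
#'
#' @name aggregation
NULL

#' Filter PSMs by search score
#'
#' Retains records with `score >= min_score`, preserving order. The
#' default of 40 stands in for search-engine FDR control at 1%.
#'
#' @param psms PSM table.
#' @param min_score minimum score (>= 0).
#' @return filtered PSM table.
#' @export
filter_psms <- function(psms, min_score = 40) {
  if (!is.numeric(min_score) || min_score < 0)
    stopf("min_score must be a non-negative number")
  psms[psms$score >= min_score, , drop = FALSE]
}

#' Transfer annotations to homology hits
#'
#' Every accession absent from (or unannotated in) the annotation table
#' that has a homology hit with `e_value <= max_e` inherits the UniRef50
#' id, taxon and function sets of its subject accession; among multiple
#' hits the lowest e-value wins. Already-annotated accessions are never
#' touched. Hits whose subject is itself unannotated are skipped with a
#' warning.
#'
#' @param annotations annotation table.
#' @param homology_hits homology table (query, subject, e_value).
#' @param max_e e-value cutoff (default 1e-4, inclusive).
#' @return annotation table extended with inherited rows; inherited rows
#'   carry `source = "transfer"` (original rows `source = "direct"`).
#' @export
transfer_annotations <- function(annotations, homology_hits, max_e = 1e-4) {
  if (!is.numeric(max_e) || max_e <= 0) stopf("max_e must be positive")
  ann <- as.data.frame(annotations)
  if (is.null(ann$source)) ann$source <- "direct"
  annotated <- ann$accession[!is.na(ann$uniref50_id) | !is.na(ann$taxon_id)]
  hits <- as.data.frame(homology_hits)
  hits <- hits[hits$e_value <= max_e & !(hits$query_accession %in% annotated), ,
               drop = FALSE]
  if (!nrow(hits)) return(ann)
  hits <- hits[order(hits$query_accession, hits$e_value), , drop = FALSE]
  hits <- hits[!duplicated(hits$query_accession), , drop = FALSE]  # best hit
  subj <- match(hits$subject_accession, ann$accession)
  missing_subj <- is.na(subj) |
    (is.na(ann$uniref50_id[subj]) & is.na(ann$taxon_id[subj]))
  if (any(missing_subj)) {
    warnf("skipping %d homology hit(s) whose subject is not annotated: %s",
          sum(missing_subj),
          paste(head(hits$subject_accession[missing_subj], 5), collapse = ", "))
    hits <- hits[!missing_subj, , drop = FALSE]
    subj <- subj[!missing_subj]
  }
  if (!nrow(hits)) return(ann)
  inherited <- ann[subj, , drop = FALSE]
  inherited$accession <- hits$query_accession
  inherited$source <- "transfer"
  inherited <- inherited[!(inherited$accession %in% ann$accession), , drop = FALSE]
  rbind(ann, inherited)
}

#' Exclude contaminant and unknown accessions from a PSM table
#'
#' Drops, from each PSM's accession list, accessions flagged
#' `is_contaminant` and accessions with no (direct or transferred)
#' annotation; PSMs left with no accession are removed. The counts of
#' dropped spectra are recorded in attributes `n_contaminant_spectra` /
#' `n_unknown_spectra`.
#'
#' @param psms PSM table.
#' @param annotations annotation table after [transfer_annotations()].
#' @return decontaminated PSM table.
#' @export
exclude_contaminants <- function(psms, annotations) {
  ann <- as.data.frame(annotations)
  contaminant <- ann$accession[ann$is_contaminant %in% TRUE]
  known <- ann$accession[(!is.na(ann$uniref50_id) | !is.na(ann$taxon_id)) &
                           !(ann$is_contaminant %in% TRUE)]
  accs <- split_multi(as.character(psms$proteins))
  kept <- lapply(accs, function(a) a[a %in% known])
  any_cont <- vapply(accs, function(a) any(a %in% contaminant), logical(1))
  keep_row <- lengths(kept) > 0L
  out <- psms[keep_row, , drop = FALSE]
  out$proteins <- join_multi(kept[keep_row])
  attr(out, "n_contaminant_spectra") <- sum(!keep_row & any_cont)
  attr(out, "n_unknown_spectra") <- sum(!keep_row & !any_cont)
  out
}

#' Group PSMs into UniRef50 metaproteins
#'
#' One metaprotein per distinct UniRef50 cluster; accessions without a
#' UniRef50 id become singleton metaproteins keyed `ACC:<accession>`.
#' Each metaprotein's taxonomy is the lowest common ancestor of the taxa
#' of its matched member accessions (members without a taxon are ignored;
#' a metaprotein with none maps to the root). Function sets are unions
#' over members. A spectrum whose accessions span several clusters is
#' assigned whole to the cluster with the larger study-wide spectrum
#' count (ties: lexicographically smaller cluster id); with
#' `shared = "fractional"` it instead contributes 1/k to each of its k
#' clusters. With unique assignment, per-sample counts sum exactly to the
#' number of retained spectra.
#'
#' @param psms filtered, decontaminated PSM table.
#' @param annotations annotation table after transfer.
#' @param taxonomy validated taxonomy table.
#' @param shared "unique" (default) or "fractional" shared-spectrum
#'   counting.
#' @return a `metaprotein_profile`: list with integer (or fractional)
#'   `counts` matrix (metaproteins x samples), `meta` data.frame
#'   (metaprotein_id, lca_taxon, lca_name, members, processes,
#'   ec_numbers, ko_ids), `samples`, and `provenance`.
#' @export
group_metaproteins <- function(psms, annotations, taxonomy,
                               shared = c("unique", "fractional")) {
  shared <- match.arg(shared)
  taxonomy <- as_taxonomy(taxonomy)
  ann <- as.data.frame(annotations)
  cluster_of <- ifelse(is.na(ann$uniref50_id),
                       paste0("ACC:", ann$accession), ann$uniref50_id)
  names(cluster_of) <- ann$accession

  samples <- sort(unique(as.character(psms$sample_id)))
  accs <- split_multi(as.character(psms$proteins))
  spec_clusters <- lapply(accs, function(a) {
    cl <- cluster_of[a]
    sort(unique(cl[!is.na(cl)]))
  })
  n_cl <- lengths(spec_clusters)
  if (any(n_cl == 0L))
    stopf("%d PSM(s) map to no annotated cluster; run exclude_contaminants first",
          sum(n_cl == 0L))

  all_ids <- sort(unique(unlist(spec_clusters)))
  counts <- matrix(0, length(all_ids), length(samples),
                   dimnames = list(all_ids, samples))
  samp <- as.character(psms$sample_id)
  if (shared == "unique") {
    # study-wide totals: number of spectra touching each cluster
    touch <- table(factor(unlist(spec_clusters), levels = all_ids))
    pick <- vapply(spec_clusters, function(cl) {
      if (length(cl) == 1L) return(cl)
      t <- as.numeric(touch[cl])
      cl[order(-t, cl)][1]  # larger total, ties lexicographic
    }, character(1))
    tab <- table(factor(pick, levels = all_ids),
                 factor(samp, levels = samples))
    counts[] <- as.numeric(tab)
  } else {
    for (i in seq_along(spec_clusters)) {
      cl <- spec_clusters[[i]]
      counts[cl, samp[i]] <- counts[cl, samp[i]] + 1 / length(cl)
    }
  }

  # member accessions per metaprotein, restricted to accessions actually
  # matched by the grouped spectra
  acc_seen <- unique(unlist(accs))
  acc_seen <- acc_seen[!is.na(cluster_of[acc_seen])]
  by_cluster <- split(acc_seen, cluster_of[acc_seen])
  merge_set <- function(x) {
    v <- unique(unlist(split_multi(x)))
    paste(sort(v), collapse = ";")
  }
  meta <- data.frame(metaprotein_id = all_ids, stringsAsFactors = FALSE)
  meta$members <- vapply(all_ids, function(id)
    paste(sort(by_cluster[[id]]), collapse = ";"), character(1))
  idx <- lapply(all_ids, function(id) match(by_cluster[[id]], ann$accession))
  meta$lca_taxon <- vapply(idx, function(i)
    lca(ann$taxon_id[i], taxonomy), integer(1))
  meta$lca_name <- taxon_name(taxonomy, meta$lca_taxon)
  meta$processes <- vapply(idx, function(i) merge_set(ann$processes[i]), character(1))
  meta$ec_numbers <- vapply(idx, function(i) merge_set(ann$ec_numbers[i]), character(1))
  meta$ko_ids <- vapply(idx, function(i) merge_set(ann$ko_ids[i]), character(1))

  structure(list(counts = counts, meta = meta, samples = samples,
                 provenance = list(shared = shared,
                                   n_spectra = nrow(psms))),
            class = "metaprotein_profile")
}

#' @export
print.metaprotein_profile <- function(x, ...) {
  cat(sprintf("metaprotein profile: %d metaproteins x %d samples (%s shared-spectrum counting)\n",
              nrow(x$counts), ncol(x$counts), x$provenance$shared))
  invisible(x)
}
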