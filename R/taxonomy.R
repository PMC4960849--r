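#' Taxonomy tables and lowest-common-ancestor queries
#'
#' A taxonomy table is a data.frame with columns `taxon_id`, `parent_id`
#' (both integer), `rank` and `name`. Exactly one row is the root (its
#' `parent_id` equals its own `taxon_id`); every other row's parent must
#' exist and parent chains must reach the root without cycles. The eight
#' ranks used throughout are root, superkingdom, phylum, class, order,
#' family, genus and species.
#'
#' @name taxonomy
NULL

TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
               "family", "genus", "species")

#' Validate a taxonomy table
#'
#' Checks uniqueness of `taxon_id`, existence of every `parent_id`, the
#' single-root condition, and that every parent chain terminates at the
#' root (no cycles). Returns the table with class `taxonomy_table` and a
#' precomputed child->parent index used by [lineage()] and [lca()].
#'
#' @param tax data.frame with columns taxon_id, parent_id, rank, name.
#' @return the validated table (class `taxonomy_table`).
#' @export
validate_taxonomy <- function(tax) {
  need <- c("taxon_id", "parent_id", "rank", "name")
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stopf("taxonomy table is missing column(s): %s", paste(miss, collapse = ", "))
  tax <- as.data.frame(tax)[need]
  tax$taxon_id <- as.integer(tax$taxon_id)
  tax$parent_id <- as.integer(tax$parent_id)
  if (anyDuplicated(tax$taxon_id))
    stopf("duplicated taxon_id(s): %s",
          paste(unique(tax$taxon_id[duplicated(tax$taxon_id)]), collapse = ", "))
  roots <- tax$taxon_id[tax$taxon_id == tax$parent_id]
  if (length(roots) != 1L)
    stopf("taxonomy must have exactly one root (parent_id == taxon_id); found %d%s",
          length(roots),
          if (length(roots)) paste0(": ", paste(roots, collapse = ", ")) else "")
  orphan <- setdiff(tax$parent_id, tax$taxon_id)
  if (length(orphan))
    stopf("parent_id(s) absent from table: %s", paste(orphan, collapse = ", "))
  # walk every chain to the root; a chain longer than the table is a cycle
  parent_of <- setNames(tax$parent_id, as.character(tax$taxon_id))
  n <- nrow(tax)
  bad <- integer(0)
  for (id in tax$taxon_id) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      p <- parent_of[[as.character(cur)]]
      if (p == cur) break
      cur <- p
      if (step > n) { bad <- c(bad, id); break }
    }
    if (cur != roots) bad <- c(bad, id)
  }
  if (length(bad))
    stopf("parent chain does not reach the root (cycle?) for taxon_id(s): %s",
          paste(unique(bad), collapse = ", "))
  attr(tax, "root") <- roots
  attr(tax, "parent_of") <- parent_of
  class(tax) <- c("taxonomy_table", "data.frame")
  tax
}

as_taxonomy <- function(tax) {
  if (inherits(tax, "taxonomy_table")) tax else validate_taxonomy(tax)
}

#' Root-to-node lineage
#'
#' @param taxonomy a validated taxonomy table.
#' @param taxon_id a single taxon id.
#' @return integer vector of taxon ids from the root down to `taxon_id`.
#' @export
lineage <- function(taxonomy, taxon_id) {
  taxonomy <- as_taxonomy(taxonomy)
  parent_of <- attr(taxonomy, "parent_of")
  key <- as.character(taxon_id)
  if (is.na(taxon_id) || !(key %in% names(parent_of)))
    stopf("unknown taxon_id: %s", taxon_id)
  path <- integer(0)
  cur <- as.integer(taxon_id)
  repeat {
    path <- c(cur, path)
    p <- parent_of[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on the lineage of every input taxon; the root if
#' the lineages share nothing deeper. Used to redefine each metaprotein's
#' taxonomy as the common ancestor of all taxa its peptides match.
#'
#' @param taxon_ids integer vector of taxon ids (NA entries are ignored).
#' @param taxonomy a validated taxonomy table.
#' @return a single taxon id; the root when `taxon_ids` is empty after
#'   NA removal.
#' @export
lca <- function(taxon_ids, taxonomy) {
  taxonomy <- as_taxonomy(taxonomy)
  ids <- unique(taxon_ids[!is.na(taxon_ids)])
  if (!length(ids)) return(attr(taxonomy, "root"))
  common <- lineage(taxonomy, ids[[1]])
  for (id in ids[-1]) {
    ln <- lineage(taxonomy, id)
    k <- min(length(common), length(ln))
    same <- common[seq_len(k)] == ln[seq_len(k)]
    depth <- if (all(same)) k else which.min(same) - 1L
    common <- common[seq_len(depth)]
  }
  common[length(common)]
}

#' Ancestor of a taxon at a given rank
#'
#' @param taxonomy validated taxonomy table.
#' @param taxon_id taxon id.
#' @param rank target rank (e.g. "order").
#' @return the taxon id of the ancestor at `rank`, or NA if the lineage
#'   does not reach that rank (i.e. `taxon_id` sits above it).
#' @export
ancestor_at_rank <- function(taxonomy, taxon_id, rank) {
  taxonomy <- as_taxonomy(taxonomy)
  ln <- lineage(taxonomy, taxon_id)
  rk <- taxonomy$rank[match(ln, taxonomy$taxon_id)]
  hit <- ln[rk == rank]
  if (length(hit)) hit[[1]] else NA_integer_
}

taxon_name <- function(taxonomy, taxon_id) {
  taxonomy$name[match(taxon_id, taxonomy$taxon_id)]
}
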