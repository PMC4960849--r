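#' Table input/output
#'
#' All pipeline tables share one dialect: UTF-8, tab-separated, mandatory
#' header row; both "" and "NA" denote missing values. Multi-valued cells
#' (protein accessions, process keywords, EC numbers, KO ids) are
#' semicolon-joined so that each row stays one record. Every writer/reader
#' pair round-trips exactly (numeric values at 12 significant digits).
#'
#' @name io_tables
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE,
                   quote = "", comment.char = "", fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s file %s is missing column(s): %s", what, path,
          paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a PSM table
#'
#' One row per identified spectrum: `sample_id`, `spectrum_id`, `peptide`,
#' `proteins` (semicolon-joined accessions, at least one) and `score`
#' (non-negative search-engine score). (sample_id, spectrum_id) must be
#' unique.
#'
#' @param path file path.
#' @return data.frame with those five columns.
#' @export
read_psm_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "spectrum_id", "peptide",
                                 "proteins", "score"), "PSM")
  validate_psm_table(df)
}

#' @rdname read_psm_table
#' @param psms a PSM table.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  write_tsv(psms[c("sample_id", "spectrum_id", "peptide", "proteins", "score")],
            path)
}

#' @rdname read_psm_table
#' @export
validate_psm_table <- function(psms) {
  psms <- as.data.frame(psms)
  if (any(is.na(psms$peptide)) || any(!nzchar(psms$peptide)))
    stopf("PSM table: empty peptide in row(s) %s",
          paste(head(which(is.na(psms$peptide) | !nzchar(psms$peptide))),
                collapse = ", "))
  accs <- split_multi(as.character(psms$proteins))
  empty <- lengths(accs) == 0L
  if (any(empty))
    stopf("PSM table: no protein accession in row(s) %s",
          paste(head(which(empty)), collapse = ", "))
  psms$score <- as.numeric(psms$score)
  if (any(is.na(psms$score)) || any(psms$score < 0))
    stopf("PSM table: score must be a non-negative number")
  key <- paste(psms$sample_id, psms$spectrum_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- psms[duplicated(key), c("sample_id", "spectrum_id")]
    stopf("PSM table: duplicated (sample_id, spectrum_id): %s",
          paste(head(paste(d$sample_id, d$spectrum_id, sep = "/")),
                collapse = ", "))
  }
  psms
}

#' Read / write the protein annotation table
#'
#' Columns: `accession` (unique), `uniref50_id`, `taxon_id`, `processes`,
#' `ec_numbers`, `ko_ids` (all possibly missing; the last three
#' semicolon-joined sets) and logical `is_contaminant`.
#'
#' @param path file path.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("accession", "uniref50_id", "taxon_id",
                                 "processes", "ec_numbers", "ko_ids",
                                 "is_contaminant"), "annotation")
  if (anyDuplicated(df$accession))
    stopf("annotation table: duplicated accession(s): %s",
          paste(head(unique(df$accession[duplicated(df$accession)])),
                collapse = ", "))
  df$taxon_id <- as.integer(df$taxon_id)
  df$is_contaminant <- as.logical(df$is_contaminant)
  df$is_contaminant[is.na(df$is_contaminant)] <- FALSE
  for (col in c("processes", "ec_numbers", "ko_ids"))
    df[[col]][is.na(df[[col]])] <- ""
  df
}

#' @rdname read_annotation_table
#' @param ann annotation table.
#' @export
write_annotation_table <- function(ann, path) {
  write_tsv(ann[c("accession", "uniref50_id", "taxon_id", "processes",
                  "ec_numbers", "ko_ids", "is_contaminant")], path)
}

#' Read / write the homology-transfer table
#'
#' BLAST-style first hits for accessions lacking direct annotation:
#' `query_accession`, `subject_accession`, `e_value` (> 0).
#'
#' @param path file path.
#' @export
read_homology_table <- function(path) {
  df <- read_tsv_checked(path, c("query_accession", "subject_accession",
                                 "e_value"), "homology")
  df$e_value <- as.numeric(df$e_value)
  if (any(is.na(df$e_value)) || any(df$e_value <= 0))
    stopf("homology table: e_value must be a positive number")
  df
}

#' @rdname read_homology_table
#' @param hits homology table.
#' @export
write_homology_table <- function(hits, path) {
  df <- hits[c("query_accession", "subject_accession", "e_value")]
  df$e_value <- signif(df$e_value, 12)
  write_tsv(df, path)
}

#' Read / write a taxonomy table
#'
#' Tab-separated `taxon_id`, `parent_id`, `rank`, `name`; validated on
#' read (single root, no orphan parents, no cycles).
#'
#' @param path file path.
#' @return a validated `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("taxon_id", "parent_id", "rank", "name"),
                         "taxonomy")
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param taxonomy taxonomy table.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv(as.data.frame(taxonomy)[c("taxon_id", "parent_id", "rank", "name")],
            path)
}

#' Read / write the process-parameter table
#'
#' One row per sample (`sample_id` unique); remaining columns are numeric
#' process parameters (temperature, OLR, TAN, SRT, pH, ...) or categorical
#' ones (reactor_type, substrate). Missing numeric values stay NA — they
#' are never silently zeroed.
#'
#' @param path file path.
#' @param categorical character vector of columns to keep as character.
#' @export
read_parameter_table <- function(path,
                                 categorical = c("reactor_type", "substrate")) {
  df <- read_tsv_checked(path, "sample_id", "parameter")
  if (anyDuplicated(df$sample_id))
    stopf("parameter table: duplicated sample_id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in setdiff(names(df), c("sample_id", categorical))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stopf("parameter table: non-numeric value in column '%s', row %d ('%s')",
            col, bad[[1]], v[[bad[[1]]]])
    if (!any(!is.na(v) & is.na(num))) df[[col]] <- num
    stopifnot(all(is.finite(num) | is.na(num)))
  }
  df
}

#' @rdname read_parameter_table
#' @param params parameter table.
#' @export
write_parameter_table <- function(params, path) {
  df <- params
  for (col in names(df)) if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], 12)
  write_tsv(df, path)
}

#' Read / write a feature-by-sample matrix
#'
#' TSV with a leading `feature_id` column and one column per sample.
#' Values are written at 12 significant digits so that write -> read
#' round-trips exactly at that precision.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- read_tsv_checked(path, "feature_id", "matrix")
  if (anyDuplicated(df$feature_id))
    stopf("matrix file: duplicated feature_id(s): %s",
          paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  ids <- as.character(df$feature_id)
  df$feature_id <- NULL
  for (col in names(df)) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(num))
    if (length(bad))
      stopf("matrix file: non-numeric cell at row %d, column '%s'", bad[[1]], col)
    df[[col]] <- num
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m numeric matrix (feature rownames, sample colnames).
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), signif(m, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
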