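#' Write a site catalog to plain-text artifacts
#'
#' Emits `sites.bed` (BED6: 0-based half-open single-base intervals,
#' name = site_id, score = study_support), `windows.fa` (FASTA of the
#' 41-nt RNA windows, id = site_id), `occurrence.tsv` (site x condition
#' binary matrix), `conditions.tsv` (condition class labels) and, for
#' synthetic catalogs, `truth_labels.tsv` with the planted labels.
#'
#' @param catalog a `site_catalog`.
#' @param outdir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_catalog <- function(catalog, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- catalog$sites
  bed <- data.frame(chrom = s$chrom, start = s$position,
                    end = s$position + 1L, name = s$site_id,
                    score = s$study_support, strand = s$strand)
  paths <- c(bed = file.path(outdir, "sites.bed"),
             fasta = file.path(outdir, "windows.fa"),
             occurrence = file.path(outdir, "occurrence.tsv"),
             conditions = file.path(outdir, "conditions.tsv"),
             truth = file.path(outdir, "truth_labels.tsv"))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  seqs <- Biostrings::RNAStringSet(s$window_seq)
  names(seqs) <- s$site_id
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  occ <- as.data.frame(catalog$occurrence)
  occ <- cbind(site_id = rownames(catalog$occurrence), occ)
  utils::write.table(occ, paths["occurrence"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(catalog$condition_meta, paths["conditions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(s$truth_label)) {
    utils::write.table(s[, c("site_id", "truth_label")], paths["truth"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}

#' Read a site catalog written by [write_catalog()]
#'
#' Validates the BED records (every interval must be single-base,
#' `end = start + 1`) and reassembles the catalog; malformed records raise
#' a parse error naming the offending line.
#'
#' @param dir directory holding the catalog artifacts.
#' @return A `site_catalog`.
#' @export
read_catalog <- function(dir) {
  bed <- utils::read.table(file.path(dir, "sites.bed"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  bad <- which(bed$end != bed$start + 1L)
  if (length(bad))
    ecn_stop(sprintf("sites.bed line %d: base-resolution site must have end = start + 1",
                     bad[1]), "parse_error")
  seqs <- Biostrings::readRNAStringSet(file.path(dir, "windows.fa"))
  win <- as.character(seqs)[bed$name]
  occ_df <- utils::read.table(file.path(dir, "occurrence.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE,
                              check.names = FALSE)
  occ <- as.matrix(occ_df[, -1, drop = FALSE])
  rownames(occ) <- occ_df$site_id
  storage.mode(occ) <- "integer"
  cond <- utils::read.table(file.path(dir, "conditions.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = bed$name, chrom = bed$chrom,
                      position = bed$start, strand = bed$strand,
                      window_seq = unname(win), study_support = bed$score,
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth_labels.tsv")
  if (file.exists(truth_path)) {
    tl <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    sites$truth_label <- tl$truth_label[match(sites$site_id, tl$site_id)]
  }
  cat <- structure(list(sites = sites, occurrence = occ,
                        condition_meta = cond), class = "site_catalog")
  validate_catalog(cat)
  cat
}

#' Write / read a feature matrix as TSV
#'
#' The TSV header carries the schema feature names; rows are keyed by
#' site_id in the first column.
#'
#' @param features a `feature_matrix`.
#' @param path TSV file path.
#' @param schema schema used to validate on read.
#' @return `read_features` returns a `feature_matrix`.
#' @export
write_features <- function(features, path) {
  df <- cbind(site_id = features$site_ids,
              as.data.frame(features$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, schema = feature_schema()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(colnames(df)[-1], schema$name))
    ecn_stop("feature TSV header does not match the schema", "schema_error")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$site_id
  structure(list(site_ids = df$site_id, values = vals, schema = schema,
                 normalization_stats = NULL),
            class = "feature_matrix")
}

#' Write a complete synthetic fixture to disk
#'
#' Catalog artifacts (see [write_catalog()]) plus `features.tsv` and
#' `params.json`; the file set round-trips losslessly through
#' [read_fixture()].
#'
#' @param catalog a `site_catalog`.
#' @param features a `feature_matrix`.
#' @param outdir output directory.
#' @param params optional `generator_params` recorded as JSON.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(catalog, features, outdir, params = NULL) {
  paths <- write_catalog(catalog, outdir)
  fpath <- file.path(outdir, "features.tsv")
  write_features(features, fpath)
  paths <- c(paths, features = fpath)
  if (!is.null(params)) {
    ppath <- file.path(outdir, "params.json")
    p <- unclass(params)
    jsonlite::write_json(p, ppath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, params = ppath)
  }
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(outdir) {
  catalog <- read_catalog(outdir)
  features <- read_features(file.path(outdir, "features.tsv"))
  params <- NULL
  ppath <- file.path(outdir, "params.json")
  if (file.exists(ppath))
    params <- jsonlite::read_json(ppath, simplifyVector = TRUE)
  list(catalog = catalog, features = features, params = params)
}

#' Write an association/selection table as TSV
#'
#' @param results data.frame from [catalog_association()], optionally with
#'   a `label` column.
#' @param path TSV path.
#' @export
write_selection <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
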