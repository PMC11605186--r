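#' The 52-feature genomic feature schema
#'
#' Returns the ordered schema describing the 52 genome-derived features used
#' by the integrated model. Features are organised into eight groups:
#' region dummies (1-13), region lengths (14-19), site clustering (20-25),
#' evolutionary conservation (26-29), RNA secondary structure (30-31),
#' gene attributes including regulator-binding flags (32-44), transcript
#' properties (45-48) and metagene relative positions (49-52).
#'
#' Conservation, structure and regulator-binding columns are consumed as
#' external columns (they come from precomputed tracks such as phastCons,
#' fitCons, RNAfold-derived structure classes and CLIP-derived binding
#' flags); all other features are computed from the transcript annotation
#' and the 41-nt site window.
#'
#' @return A data.frame with columns `name`, `index`, `group`, `kind`
#'   (binary/count/fraction/score) and `source` (computed/external_column).
#' @export
#' @examples
#' sch <- feature_schema()
#' table(sch$group)
feature_schema <- function() {
  d <- function(name, group, kind, source) {
    data.frame(name = name, group = group, kind = kind, source = source,
               stringsAsFactors = FALSE)
  }
  sch <- rbind(
    # -- 1-13 region dummies -------------------------------------------------
    d("utr5",              "region_dummy", "binary", "computed"),
    d("cds",               "region_dummy", "binary", "computed"),
    d("utr3",              "region_dummy", "binary", "computed"),
    d("start_codon",       "region_dummy", "binary", "computed"),
    d("stop_codon",        "region_dummy", "binary", "computed"),
    d("exon",              "region_dummy", "binary", "computed"),
    d("intron",            "region_dummy", "binary", "computed"),
    d("constitutive_exon", "region_dummy", "binary", "computed"),
    d("alternative_exon",  "region_dummy", "binary", "computed"),
    d("exon_junction_50",  "region_dummy", "binary", "computed"),
    d("lncrna_exon",       "region_dummy", "binary", "computed"),
    d("sncrna",            "region_dummy", "binary", "computed"),
    d("first_exon",        "region_dummy", "binary", "computed"),
    # -- 14-19 region lengths ------------------------------------------------
    d("gene_length",       "region_length", "count", "computed"),
    d("transcript_length", "region_length", "count", "computed"),
    d("utr5_length",       "region_length", "count", "computed"),
    d("cds_length",        "region_length", "count", "computed"),
    d("utr3_length",       "region_length", "count", "computed"),
    d("exon_length",       "region_length", "count", "computed"),
    # -- 20-25 clustering ----------------------------------------------------
    d("sites_100nt",           "clustering", "count", "computed"),
    d("sites_1000nt",          "clustering", "count", "computed"),
    d("dist_nearest_site",     "clustering", "score", "computed"),
    d("a_count_50nt",          "clustering", "count", "computed"),
    d("drach_count_window",    "clustering", "count", "computed"),
    d("log_dist_nearest_site", "clustering", "score", "computed"),
    # -- 26-29 conservation --------------------------------------------------
    d("phastcons_site",   "conservation", "fraction", "external_column"),
    d("phastcons_window", "conservation", "fraction", "external_column"),
    d("fitcons_site",     "conservation", "fraction", "external_column"),
    d("fitcons_window",   "conservation", "fraction", "external_column"),
    # -- 30-31 secondary structure -------------------------------------------
    d("struct_hybridize", "structure", "binary", "external_column"),
    d("struct_loop",      "structure", "binary", "external_column"),
    # -- 32-44 gene attributes -----------------------------------------------
    d("housekeeping", "gene_attribute", "binary", "external_column"),
    d("sncrna_host",  "gene_attribute", "binary", "computed"),
    d("lncrna",       "gene_attribute", "binary", "computed"),
    d("mettl3",  "gene_attribute", "binary", "external_column"),
    d("mettl14", "gene_attribute", "binary", "external_column"),
    d("wtap",    "gene_attribute", "binary", "external_column"),
    d("fto",     "gene_attribute", "binary", "external_column"),
    d("alkbh5",  "gene_attribute", "binary", "external_column"),
    d("ythdf1",  "gene_attribute", "binary", "external_column"),
    d("ythdf2",  "gene_attribute", "binary", "external_column"),
    d("ythdf3",  "gene_attribute", "binary", "external_column"),
    d("ythdc1",  "gene_attribute", "binary", "external_column"),
    d("ythdc2",  "gene_attribute", "binary", "external_column"),
    # -- 45-48 transcript properties -----------------------------------------
    d("isoform_num",       "transcript_property", "count",    "computed"),
    d("gc_content",        "transcript_property", "fraction", "computed"),
    d("exon_count",        "transcript_property", "count",    "computed"),
    d("is_protein_coding", "transcript_property", "binary",   "computed"),
    # -- 49-52 relative positions --------------------------------------------
    d("rel_pos_transcript", "relative_position", "fraction", "computed"),
    d("rel_pos_utr5",       "relative_position", "fraction", "computed"),
    d("rel_pos_cds",        "relative_position", "fraction", "computed"),
    d("rel_pos_utr3",       "relative_position", "fraction", "computed")
  )
  sch$index <- seq_len(nrow(sch))
  validate_schema(sch)
  sch[, c("name", "index", "group", "kind", "source")]
}

# expected group sizes, fixed by the 52-feature layout
.schema_group_sizes <- c(
  region_dummy = 13L, region_length = 6L, clustering = 6L,
  conservation = 4L, structure = 2L, gene_attribute = 13L,
  transcript_property = 4L, relative_position = 4L
)

#' Validate a feature schema
#'
#' Checks the structural invariants of a 52-feature schema: unique names,
#' contiguous indices 1..52 and the fixed group sizes.
#'
#' @param schema data.frame as returned by [feature_schema()].
#' @return The schema, invisibly; errors if invalid.
#' @export
validate_schema <- function(schema) {
  if (nrow(schema) != 52L)
    ecn_stop("schema must have exactly 52 features", "schema_error")
  if (anyDuplicated(schema$name))
    ecn_stop("schema feature names must be unique", "schema_error")
  if (!identical(sort(schema$index), seq_len(52L)) &&
      !identical(schema$index, seq_len(52L)))
    ecn_stop("schema indices must be contiguous 1..52", "schema_error")
  sizes <- table(schema$group)
  for (g in names(.schema_group_sizes)) {
    if (is.na(sizes[g]) || sizes[g] != .schema_group_sizes[[g]])
      ecn_stop(sprintf("schema group '%s' must have %d features", g,
                       .schema_group_sizes[[g]]), "schema_error")
  }
  bad <- !schema$kind %in% c("binary", "count", "fraction", "score")
  if (any(bad))
    ecn_stop("schema kinds must be binary/count/fraction/score", "schema_error")
  invisible(schema)
}

#' Hash of a feature schema
#'
#' A short digest of the schema content, stored with trained models so a
#' model is never evaluated against features laid out differently from the
#' ones it was trained on.
#'
#' @param schema data.frame schema.
#' @return A character scalar (md5 of the serialized name/index/kind table).
#' @export
schema_hash <- function(schema) {
  txt <- paste(schema$name, schema$index, schema$kind, schema$source,
               sep = ":", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Write / read a schema as JSON
#'
#' @param schema data.frame schema.
#' @param path file path.
#' @return `read_schema` returns the schema data.frame.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  jsonlite::write_json(schema, path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  sch <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  sch$index <- as.integer(sch$index)
  validate_schema(sch)
  sch
}
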