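#' Build a transcript model from a GFF3 annotation
#'
#' Imports a GFF3 file (1-based closed coordinates, converted to the
#' package's 0-based half-open convention only at I/O boundaries via
#' GenomicRanges) and resolves, for every gene, its single primary
#' transcript — the isoform with the greatest summed exon length. Exons
#' present (by identical coordinates) in all isoforms of a gene are marked
#' constitutive.
#'
#' @param gff_path path to a GFF3 file with gene / mRNA-or-transcript /
#'   exon / CDS records linked by ID/Parent attributes.
#' @return A `transcript_model`: list(genes, transcripts, exons, cds,
#'   primary (gene_id -> transcript_id), tx_len, iso_count, biotype).
#' @export
read_transcript_model <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  tx <- gr[typ %in% c("mRNA", "transcript")]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  if (!length(genes) || !length(tx) || !length(exons))
    ecn_stop("GFF3 must contain gene, transcript and exon records",
             "parse_error")
  first_parent <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  tx$gene_id <- first_parent(tx)
  exons$tx_id <- first_parent(exons)
  cds$tx_id <- if (length(cds)) first_parent(cds) else character(0)
  tx_len <- vapply(tx$ID, function(id)
    sum(GenomicRanges::width(exons[exons$tx_id == id])), numeric(1))
  names(tx_len) <- tx$ID
  # primary = longest transcript per gene (ties: first listed)
  primary <- vapply(genes$ID, function(g) {
    ids <- tx$ID[tx$gene_id == g]
    if (!length(ids)) return(NA_character_)
    ids[which.max(tx_len[ids])]
  }, character(1))
  iso_count <- vapply(genes$ID, function(g) sum(tx$gene_id == g), integer(1))
  names(iso_count) <- genes$ID
  biotype <- if (!is.null(genes$gene_biotype)) genes$gene_biotype
             else if (!is.null(genes$biotype)) genes$biotype
             else ifelse(genes$ID %in% tx$gene_id[tx$ID %in% cds$tx_id],
                         "protein_coding", "other")
  names(biotype) <- genes$ID
  structure(list(genes = genes, transcripts = tx, exons = exons, cds = cds,
                 primary = primary, tx_len = tx_len, iso_count = iso_count,
                 biotype = biotype),
            class = "transcript_model")
}

# exons of one transcript ordered 5' -> 3' in the transcript's sense
.tx_exons <- function(model, tx_id) {
  ex <- model$exons[model$exons$tx_id == tx_id]
  ex <- ex[order(GenomicRanges::start(ex))]
  if (as.character(GenomicRanges::strand(ex))[1] == "-") ex <- rev(ex)
  ex
}

# 0-based transcript-coordinate offset of a 1-based genomic position;
# NA when the position is intronic. Strand-aware.
.tx_offset <- function(exons_sorted, genomic_pos, strand) {
  off <- 0L
  for (i in seq_along(exons_sorted)) {
    s <- GenomicRanges::start(exons_sorted)[i]
    e <- GenomicRanges::end(exons_sorted)[i]
    if (genomic_pos >= s && genomic_pos <= e) {
      within <- if (strand == "-") e - genomic_pos else genomic_pos - s
      return(off + within)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

# DRACH match count in an RNA window
.count_drach <- function(window) {
  chars <- strsplit(window, "")[[1]]
  n <- 0L
  for (i in seq_len(length(chars) - 4L)) {
    w <- chars[i:(i + 4L)]
    if (w[1] %in% c("A", "G", "U") && w[2] %in% c("A", "G") &&
        w[3] == "A" && w[4] == "C" && w[5] %in% c("A", "C", "U"))
      n <- n + 1L
  }
  n
}

#' Annotate sites with the 52 genomic features from a transcript model
#'
#' The annotation path used for real (non-synthetic) site catalogs:
#' computed features (region dummies, lengths, clustering counts, isoform
#' counts, GC content, metagene relative positions) come from the
#' transcript model and the site windows; external-column features
#' (conservation, secondary structure, regulator binding, housekeeping
#' status) are copied through from `aux`. Every gene is resolved to its
#' single longest transcript before region arithmetic; all distances are
#' taken in transcript (sense) coordinates. A site falling outside a
#' region gets relative position 0 for that region with the region dummy
#' at 0, so the sentinel is identifiable downstream.
#'
#' @param sites data.frame with site_id, chrom, position (0-based), strand,
#'   window_seq (as in a `site_catalog`).
#' @param model a `transcript_model` from [read_transcript_model()].
#' @param aux data.frame keyed by site_id providing every
#'   `external_column` feature of the schema.
#' @param schema feature schema (default [feature_schema()]).
#' @return A `feature_matrix` over the sites.
#' @export
annotate_sites <- function(sites, model, aux, schema = feature_schema()) {
  validate_schema(schema)
  ext <- schema$name[schema$source == "external_column"]
  missing_cols <- setdiff(ext, colnames(aux))
  if (length(missing_cols))
    ecn_stop(sprintf("aux table lacks external column(s): %s",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  aidx <- match(sites$site_id, aux$site_id)
  if (anyNA(aidx))
    ecn_stop(sprintf("aux table lacks rows for site(s): %s",
                     paste(sites$site_id[is.na(aidx)], collapse = ", ")),
             "annotation_error")
  n <- nrow(sites)
  vals <- matrix(0, n, 52L, dimnames = list(sites$site_id, schema$name))
  snc_types <- c("snRNA", "snoRNA", "miRNA", "tRNA", "sncRNA")
  site_gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$position + 1L, width = 1L),
    strand = sites$strand)
  gene_hits <- GenomicRanges::findOverlaps(site_gr, model$genes)
  for (i in seq_len(n)) {
    pos1 <- sites$position[i] + 1L # 1-based genomic
    strand <- sites$strand[i]
    g_idx <- S4Vectors::subjectHits(gene_hits)[
      S4Vectors::queryHits(gene_hits) == i]
    g_idx <- g_idx[as.character(GenomicRanges::strand(model$genes))[g_idx] %in%
                     c(strand, "*")]
    if (!length(g_idx))
      ecn_stop(sprintf("site %s maps to no annotated gene", sites$site_id[i]),
               "annotation_error")
    g_idx <- g_idx[1L]
    gene <- model$genes[g_idx]
    gid <- gene$ID
    tx_id <- model$primary[[gid]]
    ex <- .tx_exons(model, tx_id)
    tx_len <- sum(GenomicRanges::width(ex))
    off <- .tx_offset(ex, pos1, strand) # NA when intronic
    exonic <- !is.na(off)
    # which exon contains the site (index along the sorted exons)
    ex_i <- if (exonic) {
      which(pos1 >= GenomicRanges::start(ex) & pos1 <= GenomicRanges::end(ex))[1]
    } else NA_integer_

    # CDS geometry in transcript coordinates (for the primary transcript)
    cds_tx <- model$cds[model$cds$tx_id == tx_id]
    has_cds <- length(cds_tx) > 0L
    cds_len <- if (has_cds) sum(GenomicRanges::width(cds_tx)) else 0L
    cds_start_tx <- if (has_cds) {
      first_base <- if (strand == "-") max(GenomicRanges::end(cds_tx))
                    else min(GenomicRanges::start(cds_tx))
      .tx_offset(ex, first_base, strand)
    } else NA_integer_
    utr5_len <- if (has_cds) cds_start_tx else 0L
    utr3_len <- if (has_cds) tx_len - cds_start_tx - cds_len else 0L

    in_utr5 <- exonic && has_cds && off < cds_start_tx
    in_cds <- exonic && has_cds && off >= cds_start_tx &&
      off < cds_start_tx + cds_len
    in_utr3 <- exonic && has_cds && off >= cds_start_tx + cds_len
    in_start <- exonic && has_cds &&
      off >= cds_start_tx - 1L && off <= cds_start_tx + 3L
    in_stop <- exonic && has_cds &&
      off >= cds_start_tx + cds_len - 4L && off <= cds_start_tx + cds_len

    # constitutive: exon coordinates shared by every isoform of the gene
    constit <- FALSE
    if (exonic) {
      tx_ids <- model$transcripts$ID[model$transcripts$gene_id == gid]
      key <- paste(GenomicRanges::start(ex)[ex_i], GenomicRanges::end(ex)[ex_i])
      constit <- all(vapply(tx_ids, function(t2) {
        e2 <- model$exons[model$exons$tx_id == t2]
        key %in% paste(GenomicRanges::start(e2), GenomicRanges::end(e2))
      }, logical(1)))
    }
    # distance to nearest exon-exon junction, transcript coordinates
    near_junction <- FALSE
    if (exonic && length(ex) > 1L) {
      bounds <- cumsum(GenomicRanges::width(ex))
      junctions <- bounds[-length(bounds)] # junction after each exon
      near_junction <- min(abs(off - junctions)) <= 50L
    }
    bt <- model$biotype[[gid]]
    is_snc <- bt %in% snc_types
    is_lnc <- bt %in% c("lncRNA", "lincRNA")
    hosts_snc <- {
      others <- model$genes[model$biotype %in% snc_types &
                              model$genes$ID != gid]
      length(others) > 0L &&
        length(GenomicRanges::findOverlaps(gene, others)) > 0L
    }
    # clustering over the input site list (genomic distances, same chrom)
    same_chr <- which(sites$chrom == sites$chrom[i])
    dists <- abs(sites$position[setdiff(same_chr, i)] - sites$position[i])
    nearest <- if (length(dists)) min(dists) else NA_real_

    win <- toupper(chartr("T", "U", sites$window_seq[i]))
    win_chars <- strsplit(win, "")[[1]]
    gc <- mean(win_chars %in% c("G", "C"))
    a_cnt <- sum(win_chars == "A")

    vals[i, "utr5"] <- as.numeric(in_utr5)
    vals[i, "cds"] <- as.numeric(in_cds)
    vals[i, "utr3"] <- as.numeric(in_utr3)
    vals[i, "start_codon"] <- as.numeric(in_start)
    vals[i, "stop_codon"] <- as.numeric(in_stop)
    vals[i, "exon"] <- as.numeric(exonic)
    vals[i, "intron"] <- as.numeric(!exonic)
    vals[i, "constitutive_exon"] <- as.numeric(constit)
    vals[i, "alternative_exon"] <- as.numeric(exonic && !constit)
    vals[i, "exon_junction_50"] <- as.numeric(near_junction)
    vals[i, "lncrna_exon"] <- as.numeric(is_lnc && exonic)
    vals[i, "sncrna"] <- as.numeric(is_snc)
    vals[i, "first_exon"] <- as.numeric(exonic && identical(ex_i, 1L))
    vals[i, "gene_length"] <- GenomicRanges::width(gene)
    vals[i, "transcript_length"] <- tx_len
    vals[i, "utr5_length"] <- utr5_len
    vals[i, "cds_length"] <- cds_len
    vals[i, "utr3_length"] <- utr3_len
    vals[i, "exon_length"] <- if (exonic)
      GenomicRanges::width(ex)[ex_i] else 0
    vals[i, "sites_100nt"] <- sum(dists <= 100)
    vals[i, "sites_1000nt"] <- sum(dists <= 1000)
    vals[i, "dist_nearest_site"] <- nearest %||% 0
    vals[i, "a_count_50nt"] <- a_cnt
    vals[i, "drach_count_window"] <- .count_drach(win)
    vals[i, "log_dist_nearest_site"] <- log1p(nearest %||% 0)
    vals[i, "sncrna_host"] <- as.numeric(hosts_snc)
    vals[i, "lncrna"] <- as.numeric(is_lnc)
    vals[i, "isoform_num"] <- model$iso_count[[gid]]
    vals[i, "gc_content"] <- gc
    vals[i, "exon_count"] <- length(ex)
    vals[i, "is_protein_coding"] <- as.numeric(bt == "protein_coding")
    vals[i, "rel_pos_transcript"] <- if (exonic)
      relative_position(off, tx_len) else 0
    vals[i, "rel_pos_utr5"] <- if (in_utr5)
      relative_position(off, utr5_len) else 0
    vals[i, "rel_pos_cds"] <- if (in_cds)
      relative_position(off - cds_start_tx, cds_len) else 0
    vals[i, "rel_pos_utr3"] <- if (in_utr3)
      relative_position(off - cds_start_tx - cds_len, utr3_len) else 0
    for (cn in ext) vals[i, cn] <- as.numeric(aux[[cn]][aidx[i]])
  }
  structure(list(site_ids = sites$site_id, values = vals, schema = schema,
                 normalization_stats = NULL),
            class = "feature_matrix")
}
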