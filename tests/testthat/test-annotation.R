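# Annotation of sites against a GFF3 transcript model: region dummies,
# lengths, relative positions, strand-awareness, longest-transcript rule.

make_sites <- function(ids, pos0, strand, windows = NULL) {
  data.frame(site_id = ids, chrom = "chr1", position = pos0,
             strand = strand,
             window_seq = windows %||% rep(toy_window(), length(ids)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the transcript model resolves the longest isoform and biotypes", {
  model <- read_transcript_model(write_toy_gff())
  expect_equal(unname(model$primary["geneA"]), "txA1") # 600 > 450 > 400
  expect_equal(unname(model$iso_count["geneA"]), 3L)
  expect_equal(unname(model$tx_len["txA1"]), 600)
  expect_equal(unname(model$tx_len["txB1"]), 200)
  expect_equal(unname(model$biotype["geneS"]), "snoRNA")
})

test_that("plus-strand region dummies, lengths and relative positions are exact", {
  model <- read_transcript_model(write_toy_gff())
  # CDS occupies transcript positions 101-400 (1-based) of the 600-nt txA1
  sites <- make_sites(c("stop_site", "utr5_site", "utr3_site"),
                      c(1398L, 1049L, 1499L), "+") # 0-based genomic
  aux <- make_aux(sites$site_id)
  fm <- annotate_sites(sites, model, aux)
  v <- fm$values
  # stop-codon site: inside CDS and the stop codon, transcript offset 398
  expect_equal(unname(v["stop_site", c("cds", "stop_codon", "utr3")]),
               c(1, 1, 0))
  expect_equal(unname(v["stop_site", "rel_pos_cds"]), (398 - 100) / 300)
  expect_equal(unname(v["stop_site", "rel_pos_transcript"]), 398 / 600)
  # 5'UTR site at offset 49
  expect_equal(unname(v["utr5_site", c("utr5", "cds")]), c(1, 0))
  expect_equal(unname(v["utr5_site", "rel_pos_utr5"]), 49 / 100)
  expect_equal(unname(v["utr5_site", "rel_pos_cds"]), 0) # sentinel outside
  # 3'UTR site at offset 499
  expect_equal(unname(v["utr3_site", "rel_pos_utr3"]), (499 - 400) / 200)
  # shared geometry
  expect_true(all(v[, "transcript_length"] == 600))
  expect_true(all(v[, "cds_length"] == 300))
  expect_true(all(v[, "utr5_length"] == 100))
  expect_true(all(v[, "utr3_length"] == 200))
  expect_true(all(v[, "isoform_num"] == 3))
  expect_true(all(v[, "first_exon"] == 1))
  # txA1's exon is absent from the shorter isoforms: alternative, not constitutive
  expect_true(all(v[, "constitutive_exon"] == 0))
  expect_true(all(v[, "alternative_exon"] == 1))
  # geneA hosts the nested snoRNA gene
  expect_true(all(v[, "sncrna_host"] == 1))
})

test_that("minus-strand coordinates are computed in transcript sense", {
  model <- read_transcript_model(write_toy_gff())
  # txB1: exons 5301-5400 then 5001-5100 (5'->3'), CDS offsets 20..179
  sites <- make_sites(c("b_ex1", "b_ex2", "b_intron"),
                      c(5349L, 5049L, 5199L), "-")
  aux <- make_aux(sites$site_id)
  fm <- annotate_sites(sites, model, aux)
  v <- fm$values
  # offset of genomic 5350 on the minus strand: 5400 - 5350 = 50
  expect_equal(unname(v["b_ex1", "rel_pos_transcript"]), 50 / 200)
  expect_equal(unname(v["b_ex1", "rel_pos_cds"]), (50 - 20) / 160)
  expect_equal(unname(v["b_ex1", "exon_junction_50"]), 1) # junction at 100
  expect_equal(unname(v["b_ex1", "first_exon"]), 1)
  # second exon: offset 100 + (5100 - 5050) = 150
  expect_equal(unname(v["b_ex2", "rel_pos_transcript"]), 150 / 200)
  expect_equal(unname(v["b_ex2", "first_exon"]), 0)
  expect_equal(unname(v["b_ex2", "constitutive_exon"]), 1) # single isoform
  # intronic site
  expect_equal(unname(v["b_intron", c("exon", "intron", "rel_pos_transcript")]),
               c(0, 1, 0))
  expect_true(all(v[, "utr5_length"] == 20))
  expect_true(all(v[, "utr3_length"] == 20))
})

test_that("window-derived features and error contracts behave", {
  model <- read_transcript_model(write_toy_gff())
  gc_win <- paste(rep(c("G", "C"), c(21, 20)), collapse = "")
  sites <- make_sites("gc_site", 1200L, "+", windows = gc_win)
  aux <- make_aux(sites$site_id)
  fm <- annotate_sites(sites, model, aux)
  expect_equal(unname(fm$values["gc_site", "gc_content"]), 1)
  expect_equal(unname(fm$values["gc_site", "drach_count_window"]), 0)
  # a canonical window contains its central DRACH
  s2 <- make_sites("d_site", 1200L, "+")
  expect_gte(annotate_sites(s2, model, make_aux("d_site"))$values[
    "d_site", "drach_count_window"], 1)
  # unmapped site names the offender
  s3 <- make_sites("lost_site", 9000L, "+")
  expect_error(annotate_sites(s3, model, make_aux("lost_site")),
               "lost_site", class = "annotation_error")
  # missing external column is a schema error
  bad_aux <- make_aux("gc_site")
  bad_aux$struct_hybridize <- NULL
  expect_error(annotate_sites(sites, model, bad_aux), class = "schema_error")
  # external columns are copied through
  expect_equal(unname(fm$values["gc_site", "phastcons_site"]),
               aux$phastcons_site[1])
})
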