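# Shared fixtures: tiny catalogs, fixed-weight networks, a toy GFF3 gene
# model, and independent oracles used across the suite.

# small synthetic dataset ready for model training
make_small_dataset <- function(n_sites = 400, seed = 11, ...) {
  gp <- generator_params(n_sites = n_sites, seed = seed, ...)
  catalog <- generate_catalog(gp)
  features <- generate_features(catalog, gp)
  labeled <- balance_sample(select_pan_cancer(catalog_association(catalog)),
                            seed = seed)
  encode_labeled_dataset(catalog, features, labeled, seed = seed)
}

# deterministic fixed-weight DCN for forward-pass fixtures
make_toy_dcn <- function(input_dim = 2L, embedding_dim = 3L,
                         hidden_dims = c(2L, 1L), seed = 5) {
  cfg <- dcn_config(input_dim = input_dim, embedding_dim = embedding_dim,
                    hidden_dims = hidden_dims, seed = seed)
  set.seed(seed)
  dcn_init(cfg)
}

# value function over F features backed by a small random DCN
make_value_fn <- function(n_features, seed = 5) {
  model <- make_toy_dcn(input_dim = n_features, embedding_dim = 8L,
                        hidden_dims = c(6L, 1L), seed = seed)
  function(X) dcn_predict(model, X)
}

# brute-force AUROC by O(n^2) pair enumeration (ties half-credited)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# closed-form Shapley values for a two-player game
shapley_two_player <- function(v0, v1, v2, v12) {
  c(0.5 * (v1 - v0) + 0.5 * (v12 - v2),
    0.5 * (v2 - v0) + 0.5 * (v12 - v1))
}

# toy GFF3: one plus-strand gene with 3 isoforms (primary: single 600-nt
# exon, CDS at 1-based transcript positions 101-400), one minus-strand
# two-exon coding gene, and one snoRNA gene inside the first gene's span.
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    # gene A: chr1:1001-1600 (+), 3 isoforms
    "chr1\ttoy\tgene\t1001\t1600\t.\t+\t.\tID=geneA;gene_biotype=protein_coding",
    "chr1\ttoy\tmRNA\t1001\t1600\t.\t+\t.\tID=txA1;Parent=geneA",
    "chr1\ttoy\texon\t1001\t1600\t.\t+\t.\tID=exA1.1;Parent=txA1",
    "chr1\ttoy\tCDS\t1101\t1400\t.\t+\t0\tID=cdsA1;Parent=txA1",
    "chr1\ttoy\tmRNA\t1001\t1450\t.\t+\t.\tID=txA2;Parent=geneA",
    "chr1\ttoy\texon\t1001\t1450\t.\t+\t.\tID=exA2.1;Parent=txA2",
    "chr1\ttoy\tmRNA\t1201\t1600\t.\t+\t.\tID=txA3;Parent=geneA",
    "chr1\ttoy\texon\t1201\t1600\t.\t+\t.\tID=exA3.1;Parent=txA3",
    # gene B: chr1:5001-5400 (-), two exons of 100 nt, CDS spans both
    "chr1\ttoy\tgene\t5001\t5400\t.\t-\t.\tID=geneB;gene_biotype=protein_coding",
    "chr1\ttoy\tmRNA\t5001\t5400\t.\t-\t.\tID=txB1;Parent=geneB",
    "chr1\ttoy\texon\t5301\t5400\t.\t-\t.\tID=exB1.1;Parent=txB1",
    "chr1\ttoy\texon\t5001\t5100\t.\t-\t.\tID=exB1.2;Parent=txB1",
    "chr1\ttoy\tCDS\t5301\t5380\t.\t-\t0\tID=cdsB1a;Parent=txB1",
    "chr1\ttoy\tCDS\t5021\t5100\t.\t-\t1\tID=cdsB1b;Parent=txB1",
    # snoRNA nested in gene A's span
    "chr1\ttoy\tgene\t1210\t1290\t.\t+\t.\tID=geneS;gene_biotype=snoRNA",
    "chr1\ttoy\tmRNA\t1210\t1290\t.\t+\t.\tID=txS1;Parent=geneS",
    "chr1\ttoy\texon\t1210\t1290\t.\t+\t.\tID=exS1.1;Parent=txS1"
  )
  writeLines(lines, path)
  path
}

# aux table supplying every external column of the schema
make_aux <- function(site_ids, seed = 2) {
  set.seed(seed)
  sch <- feature_schema()
  ext <- sch$name[sch$source == "external_column"]
  aux <- data.frame(site_id = site_ids)
  for (nm in ext) {
    kind <- sch$kind[sch$name == nm]
    aux[[nm]] <- if (kind == "binary") rbinom(length(site_ids), 1, 0.5)
                 else runif(length(site_ids))
  }
  aux
}

# a valid 41-nt window with the DRACH core at the center
toy_window <- function(flank = "C") {
  paste0(strrep(flank, 18), "GGACU", strrep(flank, 18))
}
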