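#' Filter a catalog to high-confidence sites
#'
#' Retains sites reported by at least `min_studies` independent studies,
#' mirroring the confidence filter applied to base-resolution m6A atlases.
#'
#' @param catalog a `site_catalog`.
#' @param min_studies integer >= 1.
#' @return The filtered `site_catalog` (occurrence rows subset accordingly).
#' @export
filter_high_confidence <- function(catalog, min_studies = 2L) {
  stopifnot(min_studies >= 1L)
  keep <- catalog$sites$study_support >= min_studies
  if (!any(keep))
    warning("high-confidence filter removed every site")
  out <- catalog
  out$sites <- catalog$sites[keep, , drop = FALSE]
  out$occurrence <- catalog$occurrence[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

#' Cancer-specific positive/negative labels by set difference
#'
#' For one cancer type, positives are the sites detected under cancer but
#' not the matched normal condition (m6A c(+)n(-)); negatives the reverse
#' (m6A c(-)n(+)). Sites present in both are excluded from both labels.
#'
#' @param cancer_sites,normal_sites character vectors of site ids.
#' @return A `labeled_site_set`: list(positives, negatives, provenance,
#'   selection_params).
#' @export
cancer_specific_labels <- function(cancer_sites, normal_sites) {
  if (!length(cancer_sites) || !length(normal_sites))
    ecn_stop("both site sets must be nonempty", "labeled_set_error")
  pos <- setdiff(cancer_sites, normal_sites)
  neg <- setdiff(normal_sites, cancer_sites)
  if (!length(pos) && !length(neg))
    ecn_stop("both set differences are empty (identical site sets)",
             "labeled_set_error")
  if (!length(pos))
    ecn_stop("positive set difference (cancer \\ normal) is empty",
             "labeled_set_error")
  if (!length(neg))
    ecn_stop("negative set difference (normal \\ cancer) is empty",
             "labeled_set_error")
  structure(list(positives = pos, negatives = neg,
                 provenance = "cancer_specific",
                 selection_params = list()),
            class = "labeled_site_set")
}

#' Fisher's exact association between site occurrence and condition class
#'
#' Builds the 2x2 table (present/absent x cancer/normal) for one site and
#' computes the two-sided Fisher exact p-value by full enumeration of the
#' hypergeometric distribution at the observed margins, using the
#' probability-mass criterion (sum of all tables whose probability does not
#' exceed the observed one). The odds ratio is the sample `(a*d)/(b*c)`,
#' with the Haldane-Anscombe 0.5 correction added to every cell when any
#' cell is zero; the correction affects only the odds ratio, never the
#' p-value.
#'
#' @param occurrence_row binary vector of per-condition presence.
#' @param condition_classes character vector of "cancer"/"normal", aligned
#'   with `occurrence_row`.
#' @return An `odds_ratio_result`: list(a, b, c, d, odds_ratio, log2_or,
#'   p_value, q_value = NA until BH adjustment).
#' @export
fisher_association <- function(occurrence_row, condition_classes) {
  if (length(occurrence_row) != length(condition_classes))
    ecn_stop("occurrence row and condition classes must align",
             "contract_violation")
  if (!all(condition_classes %in% c("cancer", "normal")) ||
      length(unique(condition_classes)) < 2L)
    ecn_stop("need at least one cancer and one normal condition",
             "contract_violation")
  if (!all(occurrence_row %in% c(0L, 1L)))
    ecn_stop("occurrence must be binary", "contract_violation")
  is_cancer <- condition_classes == "cancer"
  a <- sum(occurrence_row[is_cancer] == 1L)
  b <- sum(is_cancer) - a
  c_ <- sum(occurrence_row[!is_cancer] == 1L)
  d <- sum(!is_cancer) - c_
  res <- fisher_table(a, b, c_, d)
  structure(res, class = "odds_ratio_result")
}

#' Fisher exact test statistics from 2x2 cell counts
#'
#' Vectorised over tables. See [fisher_association()] for conventions.
#'
#' @param a,b,c,d cell counts: a = cancer conditions containing the site,
#'   b = cancer lacking it, c = normal containing it, d = normal lacking it.
#' @return list(a, b, c, d, odds_ratio, log2_or, p_value, q_value = NA)
#'   (vectors when input counts are vectors).
#' @export
fisher_table <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d), all(c(a, b, c, d) >= 0))
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]            # cancer margin
    m2 <- c[i] + d[i]            # normal margin
    k <- a[i] + c[i]             # presence margin
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    xs <- lo:hi
    dens <- stats::dhyper(xs, m1, m2, k)
    obs <- stats::dhyper(a[i], m1, m2, k)
    # relative tolerance absorbs float noise between mathematically tied
    # tables (the standard convention of exact-test implementations)
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  aa <- a + 0.5 * zero; bb <- b + 0.5 * zero
  cc <- c + 0.5 * zero; dd <- d + 0.5 * zero
  or <- (aa * dd) / (bb * cc)
  list(a = a, b = b, c = c, d = d, odds_ratio = or, log2_or = log2(or),
       p_value = p, q_value = rep(NA_real_, n))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / j`, clipped to 1), returned in input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values)))
    ecn_stop("p-values must lie in [0,1]", "contract_violation")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-site Fisher association across a whole catalog
#'
#' Runs [fisher_table()] over every occurrence row and BH-adjusts the
#' p-values jointly.
#'
#' @param catalog a `site_catalog`.
#' @return data.frame with columns site_id, a, b, c, d, odds_ratio,
#'   log2_or, p_value, q_value.
#' @export
catalog_association <- function(catalog) {
  cls <- catalog$condition_meta$class
  is_cancer <- cls == "cancer"
  if (!any(is_cancer) || all(is_cancer))
    ecn_stop("need at least one cancer and one normal condition",
             "contract_violation")
  occ <- catalog$occurrence
  a <- rowSums(occ[, is_cancer, drop = FALSE])
  b <- sum(is_cancer) - a
  cc <- rowSums(occ[, !is_cancer, drop = FALSE])
  d <- sum(!is_cancer) - cc
  res <- fisher_table(a, b, cc, d)
  data.frame(site_id = catalog$sites$site_id,
             a = res$a, b = res$b, c = res$c, d = res$d,
             odds_ratio = res$odds_ratio, log2_or = res$log2_or,
             p_value = res$p_value,
             q_value = bh_adjust(res$p_value),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select pan-cancer-associated sites from association results
#'
#' Positives are sites with `log2_or > lor_cut` and adjusted p below
#' `q_cut`; the negative pool is the symmetric criterion
#' (`log2_or < -lor_cut`, adjusted p below `q_cut`). Both thresholds are
#' strict inequalities. Set `adjusted = FALSE` to threshold raw p-values
#' instead of BH-adjusted ones.
#'
#' @param results data.frame from [catalog_association()] (or a list of
#'   `odds_ratio_result`s covering each site once).
#' @param lor_cut log2 odds-ratio cutoff (default 2).
#' @param q_cut significance cutoff on the adjusted p (default 0.05).
#' @param adjusted threshold `q_value` (default) or raw `p_value`.
#' @return A `labeled_site_set` with unbalanced negatives (the pool).
#' @export
select_pan_cancer <- function(results, lor_cut = 2, q_cut = 0.05,
                              adjusted = TRUE) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(site_id = r$site_id, log2_or = r$log2_or,
                 p_value = r$p_value, q_value = r$q_value)))
  if (anyDuplicated(results$site_id))
    ecn_stop("results must cover each site exactly once",
             "contract_violation")
  sig <- if (adjusted) results$q_value else results$p_value
  pos <- results$site_id[results$log2_or > lor_cut & sig < q_cut]
  neg <- results$site_id[results$log2_or < -lor_cut & sig < q_cut]
  if (!length(pos))
    ecn_stop("no site passes the positive selection criterion",
             "selection_error")
  structure(list(positives = pos, negatives = neg,
                 provenance = "pan_cancer",
                 selection_params = list(lor_cut = lor_cut, q_cut = q_cut,
                                         adjusted = adjusted)),
            class = "labeled_site_set")
}

#' Balance a labeled set by down-sampling the negative pool
#'
#' Draws, uniformly without replacement, as many negatives as there are
#' positives (1:1 ratio). Deterministic under `seed`.
#'
#' @param labeled a `labeled_site_set`.
#' @param seed integer seed.
#' @return A balanced `labeled_site_set`.
#' @export
balance_sample <- function(labeled, seed = 1L) {
  n_pos <- length(labeled$positives)
  if (length(labeled$negatives) < n_pos)
    ecn_stop("negative pool smaller than positive set", "sampling_error")
  set.seed(stage_seed(seed, "balance"))
  out <- labeled
  out$negatives <- sort(sample(labeled$negatives, n_pos))
  out$selection_params$balance_seed <- seed
  out
}
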