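#' Parameters for the synthetic site-catalog generator
#'
#' Bundles and validates every knob of the synthetic m6A data regime: the
#' size of the site universe, the number of cancer and normal conditions,
#' the fractions of sites planted as cancer-enriched (`pan_positive`) or
#' normal-enriched (`pan_negative`), the Bernoulli occurrence probabilities,
#' class-conditional genomic feature effects, the strength of any planted
#' sequence signal, and the study-support distribution feeding the
#' high-confidence filter.
#'
#' Occurrence structure: a `pan_positive` site is present in each cancer
#' condition with probability `p_high` and in each normal condition with
#' `p_low`; a `pan_negative` site is the reverse; `background` sites occur
#' with `p_background` everywhere.
#'
#' @param n_sites number of sites in the universe.
#' @param n_cancer_conditions,n_normal_conditions condition counts.
#' @param frac_pan_positive,frac_pan_negative fractions of planted
#'   cancer-enriched / normal-enriched sites; their sum must be <= 1.
#' @param p_high,p_low,p_background occurrence probabilities; when any
#'   signal is planted they must satisfy `p_high > p_background > p_low`.
#' @param feature_effects named list of class-conditional feature draws, see
#'   [default_feature_effects()]. `NULL` plants no genomic signal.
#' @param sequence_effect nonnegative mixing weight in \[0,1\] of a
#'   class-dependent position weight matrix outside the DRACH core;
#'   0 means the window sequence carries no class signal.
#' @param study_support_lambda Poisson rate of the study-support
#'   distribution `1 + Poisson(lambda)`.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_sites = 4000L,
                             n_cancer_conditions = 10L,
                             n_normal_conditions = 10L,
                             frac_pan_positive = 0.2,
                             frac_pan_negative = 0.3,
                             p_high = 0.9,
                             p_low = 0.1,
                             p_background = 0.5,
                             feature_effects = default_feature_effects(),
                             sequence_effect = 0,
                             study_support_lambda = 1,
                             seed = 1L) {
  p <- list(n_sites = as.integer(n_sites),
            n_cancer_conditions = as.integer(n_cancer_conditions),
            n_normal_conditions = as.integer(n_normal_conditions),
            frac_pan_positive = frac_pan_positive,
            frac_pan_negative = frac_pan_negative,
            p_high = p_high, p_low = p_low, p_background = p_background,
            feature_effects = feature_effects,
            sequence_effect = sequence_effect,
            study_support_lambda = study_support_lambda,
            seed = as.integer(seed))
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

#' @rdname generator_params
#' @param params a `generator_params` list.
#' @export
validate_generator_params <- function(params) {
  p <- params
  if (p$n_sites < 1L || p$n_cancer_conditions < 1L || p$n_normal_conditions < 1L)
    ecn_stop("counts must be positive", "parameter_error")
  probs <- c(p$p_high, p$p_low, p$p_background,
             p$frac_pan_positive, p$frac_pan_negative)
  if (any(probs < 0 | probs > 1))
    ecn_stop("probabilities and fractions must lie in [0,1]", "parameter_error")
  if (p$frac_pan_positive + p$frac_pan_negative > 1)
    ecn_stop("frac_pan_positive + frac_pan_negative must be <= 1",
             "parameter_error")
  planting <- p$frac_pan_positive > 0 || p$frac_pan_negative > 0
  if (planting && !(p$p_high > p$p_background && p$p_background > p$p_low))
    ecn_stop("need p_high > p_background > p_low when planting signal",
             "parameter_error")
  if (p$sequence_effect < 0 || p$sequence_effect > 1)
    ecn_stop("sequence_effect must lie in [0,1]", "parameter_error")
  invisible(params)
}

#' Default planted genomic feature effects
#'
#' The five class-conditional effects that encode, in the synthetic data,
#' the signatures the integrated model is expected to exploit: positives
#' sit late in the CDS and early in the 3'UTR (a CDS/3'UTR-boundary
#' enrichment), fall in base-paired (hybridized) structure more often, come
#' from genes with more isoforms, and are depleted from constitutive exons.
#'
#' Each element is `list(family, pos, null)` where `family` is one of
#' `"bernoulli"` (`prob`), `"beta"` (`shape1`, `shape2`),
#' `"poisson_shift"` (`shift`, `lambda`) or `"normal"` (`mean`, `sd`);
#' `pos` parameterises draws for `pan_positive` sites and `null` all others.
#'
#' @return Named list of effect descriptors.
#' @export
default_feature_effects <- function() {
  list(
    rel_pos_cds = list(family = "beta",
                       pos = list(shape1 = 6, shape2 = 2),
                       null = list(shape1 = 2, shape2 = 2)),
    rel_pos_utr3 = list(family = "beta",
                        pos = list(shape1 = 2, shape2 = 6),
                        null = list(shape1 = 2, shape2 = 2)),
    struct_hybridize = list(family = "bernoulli",
                            pos = list(prob = 0.7),
                            null = list(prob = 0.3)),
    isoform_num = list(family = "poisson_shift",
                       pos = list(shift = 1, lambda = 4),
                       null = list(shift = 1, lambda = 2)),
    constitutive_exon = list(family = "bernoulli",
                             pos = list(prob = 0.3),
                             null = list(prob = 0.7))
  )
}

# RNA alphabet used throughout
.rna_bases <- c("A", "C", "G", "U")

# DRACH consensus alternatives per core offset (-2..+2 around the A)
.drach_sets <- list(c("A", "G", "U"), c("A", "G"), "A", "C", c("A", "C", "U"))

# class-biased base frequencies for the non-core window positions (A,C,G,U)
.seq_bias <- list(pan_positive = c(0.10, 0.40, 0.40, 0.10),
                  pan_negative = c(0.40, 0.10, 0.10, 0.40),
                  background   = c(0.25, 0.25, 0.25, 0.25))

# draw one 41-nt window for a site of the given truth class
.draw_window <- function(truth, sequence_effect) {
  base_p <- rep(0.25, 4)
  p <- (1 - sequence_effect) * base_p + sequence_effect * .seq_bias[[truth]]
  w <- sample(.rna_bases, 41, replace = TRUE, prob = p)
  core <- vapply(.drach_sets, function(s) sample(s, 1L), character(1))
  w[19:23] <- core # DRACH at 0-based 18..22; methylated A at 0-based index 20
  paste(w, collapse = "")
}

#' Generate a synthetic site catalog
#'
#' Draws a universe of base-resolution m6A sites with planted occurrence
#' asymmetry between cancer and normal conditions, 41-nt DRACH-centered
#' windows, and per-site study-support counts. Fully deterministic under
#' `params$seed`.
#'
#' @param params a [generator_params()] object.
#' @return A `site_catalog`: list with `sites` (data.frame: site_id, chrom,
#'   position, strand, window_seq, study_support, truth_label), `occurrence`
#'   (site x condition binary matrix) and `condition_meta` (data.frame:
#'   condition, class).
#' @export
generate_catalog <- function(params) {
  validate_generator_params(params)
  p <- params
  set.seed(stage_seed(p$seed, "catalog"))
  n <- p$n_sites
  n_pos <- round(p$frac_pan_positive * n)
  n_neg <- round(p$frac_pan_negative * n)
  truth <- c(rep("pan_positive", n_pos), rep("pan_negative", n_neg),
             rep("background", n - n_pos - n_neg))
  truth <- sample(truth) # order carries no information
  ids <- sprintf("site_%05d", seq_len(n))

  kc <- p$n_cancer_conditions
  kn <- p$n_normal_conditions
  conds <- c(sprintf("cancer_%02d", seq_len(kc)),
             sprintf("normal_%02d", seq_len(kn)))
  cls <- c(rep("cancer", kc), rep("normal", kn))

  # occurrence probabilities per site x condition class
  p_cancer <- ifelse(truth == "pan_positive", p$p_high,
                     ifelse(truth == "pan_negative", p$p_low, p$p_background))
  p_normal <- ifelse(truth == "pan_positive", p$p_low,
                     ifelse(truth == "pan_negative", p$p_high, p$p_background))
  occ <- cbind(
    matrix(stats::rbinom(n * kc, 1L, rep(p_cancer, kc)), nrow = n),
    matrix(stats::rbinom(n * kn, 1L, rep(p_normal, kn)), nrow = n)
  )
  dimnames(occ) <- list(ids, conds)

  windows <- vapply(truth, .draw_window, character(1),
                    sequence_effect = p$sequence_effect)
  sites <- data.frame(
    site_id = ids,
    chrom = "synth_1",
    position = sort(sample.int(10^7, n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    window_seq = unname(windows),
    study_support = 1L + stats::rpois(n, p$study_support_lambda),
    truth_label = truth,
    stringsAsFactors = FALSE
  )
  cat <- list(sites = sites, occurrence = occ,
              condition_meta = data.frame(condition = conds, class = cls,
                                          stringsAsFactors = FALSE))
  class(cat) <- "site_catalog"
  validate_catalog(cat)
  cat
}

#' Validate a site catalog
#'
#' @param catalog a `site_catalog`.
#' @return The catalog, invisibly; errors on violated invariants.
#' @export
validate_catalog <- function(catalog) {
  s <- catalog$sites
  if (anyDuplicated(s$site_id))
    ecn_stop("site_ids must be unique", "catalog_error")
  if (!all(nchar(s$window_seq) == 41L))
    ecn_stop("window sequences must be exactly 41 nt", "catalog_error")
  if (!all(substr(s$window_seq, 21, 21) == "A"))
    ecn_stop("central base (0-based index 20) must be A", "catalog_error")
  occ <- catalog$occurrence
  if (!all(occ %in% c(0L, 1L)))
    ecn_stop("occurrence entries must be 0/1", "catalog_error")
  if (nrow(occ) != nrow(s) || ncol(occ) != nrow(catalog$condition_meta))
    ecn_stop("occurrence dimensions must match sites and conditions",
             "catalog_error")
  if (!all(catalog$condition_meta$class %in% c("cancer", "normal")))
    ecn_stop("condition classes must be cancer/normal", "catalog_error")
  invisible(catalog)
}

# draw n values from an effect family
.draw_family <- function(family, par, n) {
  switch(family,
    bernoulli = stats::rbinom(n, 1L, par$prob),
    beta = stats::rbeta(n, par$shape1, par$shape2),
    poisson_shift = par$shift + stats::rpois(n, par$lambda),
    normal = stats::rnorm(n, par$mean, par$sd),
    ecn_stop(sprintf("unknown effect family '%s'", family), "parameter_error")
  )
}

# class-independent null draw for a feature, by schema kind
.draw_null <- function(kind, n) {
  switch(kind,
    binary = stats::rbinom(n, 1L, 0.5),
    count = stats::rpois(n, 3),
    fraction = stats::rbeta(n, 2, 2),
    score = stats::rnorm(n),
    ecn_stop(sprintf("unknown kind '%s'", kind), "schema_error")
  )
}

#' Generate the 52-feature genomic table for a synthetic catalog
#'
#' Draws each feature from its class-conditional distribution:
#' `pan_positive` sites use the `pos` parameters of any effect registered in
#' `params$feature_effects`, every other site the `null` parameters;
#' features without a registered effect are drawn identically across classes
#' from a kind-appropriate null. Deterministic under `params$seed`.
#'
#' @param catalog a `site_catalog`.
#' @param params a [generator_params()] object.
#' @param schema feature schema, defaults to [feature_schema()].
#' @return A `feature_matrix`: list with `site_ids`, `values` (N x 52 matrix,
#'   columns named by the schema), `schema`, `normalization_stats` (NULL
#'   until [normalize_features()] is applied).
#' @export
generate_features <- function(catalog, params, schema = feature_schema()) {
  validate_schema(schema)
  effects <- params$feature_effects
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), schema$name)
    if (length(unknown))
      ecn_stop(sprintf("feature_effects name(s) not in schema: %s",
                       paste(unknown, collapse = ", ")), "schema_error")
  }
  set.seed(stage_seed(params$seed, "features"))
  n <- nrow(catalog$sites)
  is_pos <- catalog$sites$truth_label == "pan_positive"
  vals <- matrix(0, nrow = n, ncol = 52L,
                 dimnames = list(catalog$sites$site_id, schema$name))
  for (j in seq_len(52L)) {
    nm <- schema$name[j]
    eff <- effects[[nm]]
    if (is.null(eff)) {
      vals[, j] <- .draw_null(schema$kind[j], n)
    } else {
      v <- numeric(n)
      v[is_pos] <- .draw_family(eff$family, eff$pos, sum(is_pos))
      v[!is_pos] <- .draw_family(eff$family, eff$null, sum(!is_pos))
      vals[, j] <- v
    }
  }
  fm <- list(site_ids = catalog$sites$site_id, values = vals,
             schema = schema, normalization_stats = NULL)
  class(fm) <- "feature_matrix"
  fm
}
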