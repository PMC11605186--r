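# Synthetic site-catalog generator: planted structure, construction
# constraints, determinism.

test_that("generator validates its parameter invariants", {
  expect_error(generator_params(p_high = 0.2, p_low = 0.5),
               class = "parameter_error")
  expect_error(generator_params(frac_pan_positive = 0.7,
                                frac_pan_negative = 0.6),
               class = "parameter_error")
  expect_error(generator_params(p_high = 1.2), class = "parameter_error")
  # no ordering constraint when nothing is planted
  expect_s3_class(generator_params(frac_pan_positive = 0,
                                   frac_pan_negative = 0,
                                   p_high = 0.1, p_low = 0.9,
                                   p_background = 0.5),
                  "generator_params")
})

test_that("every window is 41 nt with a central A and a DRACH core", {
  gp <- generator_params(n_sites = 200, seed = 3, sequence_effect = 0.5)
  catalog <- generate_catalog(gp)
  w <- catalog$sites$window_seq
  expect_true(all(nchar(w) == 41))
  expect_true(all(substr(w, 21, 21) == "A")) # 0-based index 20
  core <- substr(w, 19, 23)
  expect_true(all(grepl("^[AGU][AG]AC[ACU]$", core)))
})

test_that("pan_positive occurrence in cancer conditions sits inside the binomial 99% CI of p_high", {
  gp <- generator_params(n_sites = 2000, p_high = 0.9, p_low = 0.1, seed = 8)
  catalog <- generate_catalog(gp)
  pos <- catalog$sites$truth_label == "pan_positive"
  cancer <- catalog$condition_meta$class == "cancer"
  x <- sum(catalog$occurrence[pos, cancer])
  n <- sum(pos) * sum(cancer)
  ci <- qbinom(c(0.005, 0.995), n, 0.9) / n
  rate <- x / n
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("zero-effect features carry no class signal (KS test at alpha=0.01)", {
  gp <- generator_params(n_sites = 2000, feature_effects = NULL,
                         sequence_effect = 0, seed = 5)
  catalog <- generate_catalog(gp)
  fm <- generate_features(catalog, gp)
  pos <- catalog$sites$truth_label == "pan_positive"
  p <- suppressWarnings(
    ks.test(fm$values[pos, "phastcons_site"],
            fm$values[!pos, "phastcons_site"])$p.value)
  expect_gt(p, 0.01)
  # class means of every feature differ by < 3 standard errors
  for (j in seq_len(ncol(fm$values))) {
    d <- abs(mean(fm$values[pos, j]) - mean(fm$values[!pos, j]))
    se <- sqrt(var(fm$values[pos, j]) / sum(pos) +
                 var(fm$values[!pos, j]) / sum(!pos))
    if (se > 0) expect_lt(d, 3 * se + 1e-12)
  }
})

test_that("planted struct_hybridize class rates fall inside their binomial 99% CIs", {
  gp <- generator_params(n_sites = 2000, seed = 9)
  catalog <- generate_catalog(gp)
  fm <- generate_features(catalog, gp)
  pos <- catalog$sites$truth_label == "pan_positive"
  for (case in list(list(idx = pos, p = 0.7), list(idx = !pos, p = 0.3))) {
    n <- sum(case$idx)
    x <- sum(fm$values[case$idx, "struct_hybridize"])
    ci <- qbinom(c(0.005, 0.995), n, case$p)
    expect_gte(x, ci[1])
    expect_lte(x, ci[2])
  }
})

test_that("binary features only ever take values 0/1", {
  gp <- generator_params(n_sites = 300, seed = 2)
  catalog <- generate_catalog(gp)
  fm <- generate_features(catalog, gp)
  binary <- fm$schema$kind == "binary"
  expect_true(all(fm$values[, binary] %in% c(0, 1)))
})

test_that("identical params and seed give byte-identical fixtures", {
  gp <- generator_params(n_sites = 120, seed = 21)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  for (d in c(d1, d2)) {
    catalog <- generate_catalog(gp)
    fm <- generate_features(catalog, gp)
    write_fixture(catalog, fm, d, gp)
  }
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted occurrence asymmetry drives log2 odds ratios above background", {
  gp <- generator_params(n_sites = 1500, seed = 13)
  catalog <- generate_catalog(gp)
  assoc <- catalog_association(catalog)
  truth <- catalog$sites$truth_label
  lor_pos <- assoc$log2_or[truth == "pan_positive"]
  lor_bg <- assoc$log2_or[truth == "background"]
  qs <- c(0.25, 0.5, 0.75)
  expect_true(all(quantile(lor_pos, qs) > quantile(lor_bg, qs)))
})
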