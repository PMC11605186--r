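# Labeling procedures: confidence filter, set-difference labels, Fisher
# association, BH adjustment, pan-cancer selection, balanced sampling.

test_that("high-confidence filter retains exactly the sites at or above the threshold", {
  gp <- generator_params(n_sites = 1000, seed = 4)
  catalog <- generate_catalog(gp)
  filtered <- filter_high_confidence(catalog, min_studies = 2)
  expect_equal(nrow(filtered$sites),
               sum(catalog$sites$study_support >= 2)) # direct recount
  expect_true(all(filtered$sites$study_support >= 2))
  expect_identical(rownames(filtered$occurrence), filtered$sites$site_id)
  # min_studies = 1 is the identity
  id <- filter_high_confidence(catalog, min_studies = 1)
  expect_identical(id$sites$site_id, catalog$sites$site_id)
  # threshold example
  toy <- catalog
  toy$sites <- toy$sites[1:2, ]; toy$occurrence <- toy$occurrence[1:2, ]
  toy$sites$study_support <- c(3L, 1L)
  expect_identical(filter_high_confidence(toy, 2)$sites$site_id,
                   toy$sites$site_id[1])
})

test_that("cancer-specific labels are the two set differences", {
  ls <- cancer_specific_labels(c("s1", "s2", "s3"), c("s2", "s4"))
  expect_setequal(ls$positives, c("s1", "s3"))
  expect_setequal(ls$negatives, "s4")
  expect_error(cancer_specific_labels(c("s1"), c("s1")),
               class = "labeled_set_error")
  # disjoint sets label everything
  ls2 <- cancer_specific_labels(c("a", "b"), c("c"))
  expect_setequal(ls2$positives, c("a", "b"))
  expect_setequal(ls2$negatives, "c")
})

test_that("Fisher worked examples match exact enumeration arithmetic", {
  r <- fisher_table(9, 1, 1, 9)
  expect_equal(r$p_value, 202 / 184756, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 81)
  expect_equal(r$log2_or, log2(81), tolerance = 1e-12)
  # symmetric table: OR 1, p 1
  r2 <- fisher_table(5, 5, 5, 5)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$log2_or, 0)
  expect_equal(r2$p_value, 1)
  # zero cells take the Haldane-Anscombe correction for the OR only
  r3 <- fisher_table(10, 0, 0, 10)
  expect_equal(r3$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_equal(r3$log2_or, log2(441), tolerance = 1e-12)
  expect_equal(r3$p_value, fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-12)
})

test_that("Fisher p-values agree with the reference implementation on random tables", {
  set.seed(42)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    cc <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    expect_equal(fisher_table(a, b, cc, d)$p_value,
                 fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("odds ratio is monotone in a with the other cells fixed", {
  ors <- vapply(0:10, function(a) fisher_table(a, 3, 4, 6)$odds_ratio,
                numeric(1))
  expect_true(all(diff(ors) >= 0))
})

test_that("fisher_association builds the table from occurrence and classes", {
  occ <- c(1, 1, 1, 0, 0, 1, 0, 0)
  cls <- c(rep("cancer", 4), rep("normal", 4))
  r <- fisher_association(occ, cls)
  expect_equal(c(r$a, r$b, r$c, r$d), c(3, 1, 1, 3))
  expect_error(fisher_association(occ, rep("cancer", 8)),
               class = "contract_violation")
})

test_that("BH adjustment matches the hand step-up oracle and keeps rank order", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_identical(order(q, p), order(p, q)) # q preserves the p ranking
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "contract_violation")
})

test_that("pan-cancer selection uses strict thresholds on log2(OR) and q", {
  res <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                    log2_or = c(6.34, 2, -3, 2.5),
                    p_value = c(1e-4, 1e-4, 1e-4, 0.2),
                    q_value = c(0.002, 0.002, 0.002, 0.2))
  sel <- select_pan_cancer(res)
  expect_setequal(sel$positives, "s1") # s2 excluded at the boundary, s4 by q
  expect_setequal(sel$negatives, "s3")
  expect_error(select_pan_cancer(res[res$log2_or < 0, ]),
               class = "selection_error")
})

test_that("selection is invariant to site ordering and matches a brute-force pass", {
  gp <- generator_params(n_sites = 500, seed = 31)
  catalog <- generate_catalog(gp)
  assoc <- catalog_association(catalog)
  sel <- select_pan_cancer(assoc)
  # independent recomputation per site with scalar calls + oracle BH
  q <- bh_oracle(vapply(seq_len(nrow(assoc)), function(i)
    fisher.test(matrix(c(assoc$a[i], assoc$c[i], assoc$b[i], assoc$d[i]),
                       2))$p.value, numeric(1)))
  or <- with(assoc, ifelse(a == 0 | b == 0 | c == 0 | d == 0,
                           ((a + .5) * (d + .5)) / ((b + .5) * (c + .5)),
                           (a * d) / (b * c)))
  brute_pos <- assoc$site_id[log2(or) > 2 & q < 0.05]
  expect_setequal(sel$positives, brute_pos)
  # permuting rows changes nothing
  perm <- sample(nrow(assoc))
  sel2 <- select_pan_cancer(assoc[perm, ])
  expect_setequal(sel2$positives, sel$positives)
  expect_setequal(sel2$negatives, sel$negatives)
})

test_that("balanced sampling is exact, seeded and drawn from the pool", {
  labeled <- structure(list(positives = paste0("p", 1:5),
                            negatives = paste0("n", 1:100),
                            provenance = "pan_cancer",
                            selection_params = list()),
                       class = "labeled_site_set")
  b1 <- balance_sample(labeled, seed = 9)
  b2 <- balance_sample(labeled, seed = 9)
  expect_length(b1$negatives, 5)
  expect_identical(b1$negatives, b2$negatives)
  expect_true(all(b1$negatives %in% labeled$negatives))
  small <- labeled; small$negatives <- c("n1", "n2")
  expect_error(balance_sample(small), class = "sampling_error")
})
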