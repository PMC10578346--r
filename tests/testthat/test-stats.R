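test_that("pooled t-test: degenerate cases and closed-form agreement", {
  x <- c(1, 2, 3)
  r <- independent_t_test(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  r <- independent_t_test(rep(2, 5), rep(2, 7))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  expect_error(independent_t_test(rep(1, 3), rep(2, 3)), "DEGENERATE_VARIANCE")
  expect_error(independent_t_test(1, c(1, 2)), "n >= 2")

  set.seed(101)
  a <- rep(c(1, 2, 3), 10)
  r <- independent_t_test(a, a + 10 + rnorm(30, 0, 1e-4))
  expect_lt(r$p, 1e-6)

  for (i in 1:1000) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = 2)
    got <- independent_t_test(a, b)
    want <- t_oracle(a, b)
    expect_lt(abs(got$t - want$t), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
})

test_that("one-way ANOVA: F = t^2 with two groups, oracle with three", {
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(6, 1)
    aov2 <- one_way_anova(list(a, b))
    tt <- independent_t_test(a, b)
    expect_lt(abs(aov2$F - tt$t^2), 1e-10)
    expect_lt(abs(aov2$p - tt$p), 1e-10)
    g3 <- list(rnorm(5), rnorm(7, 0.5), rnorm(6, -0.3))
    got <- one_way_anova(g3)
    want <- anova_oracle(g3)
    expect_lt(abs(got$F - want$F), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
  expect_equal(one_way_anova(list(rep(1, 4), rep(1, 4)))$p, 1)
  expect_error(one_way_anova(list(rnorm(3))), ">= 2 groups")
})

test_that("Pearson correlation: exact lines, oracle, sampling distribution", {
  x <- c(0.2, 0.5, 0.9, 1.3, 2.2)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "CONSTANT_INPUT")
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")

  set.seed(21)
  for (i in 1:200) {
    x <- rnorm(15); y <- 0.5 * x + rnorm(15)
    got <- pearson_correlation(x, y)
    want <- cor_oracle(x, y)
    expect_lt(abs(got$r - want$r), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
  # mean sample r at rho = 0.7, n = 24, over 500 draws
  set.seed(31)
  rs <- replicate(500, {
    z <- rnorm(24); e <- rnorm(24)
    pearson_correlation(z, 0.7 * z + sqrt(1 - 0.49) * e)$r
  })
  expect_lt(abs(mean(rs) - 0.7), 0.05)
})

test_that("2x2 tests: expected-count rule, enumeration oracle", {
  # matched gender split 0/12 vs 0/12 -> p = 1 (small expected counts: Fisher)
  r <- chi_square_or_fisher(matrix(c(0, 12, 0, 12), 2))
  expect_equal(r$p, 1); expect_equal(r$method, "fisher")
  r <- chi_square_or_fisher(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$method, "fisher")
  expect_lt(r$p, 0.001)
  expect_equal(r$p, fisher_oracle(matrix(c(10, 0, 0, 10), 2)), tolerance = 1e-10)
  expect_equal(chi_square_or_fisher(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # large counts -> Pearson chi-square, against the closed form
  tab <- matrix(c(20, 10, 10, 20), 2)
  r <- chi_square_or_fisher(tab)
  expect_equal(r$method, "chisq")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$stat, sum((tab - expected)^2 / expected), tolerance = 1e-10)
  expect_equal(r$p, pchisq(r$stat, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_error(chi_square_or_fisher(matrix(0, 2, 2)), "zero")
})

test_that("ROC: separation, null behavior, pairwise-concordance oracle", {
  # perfectly separated groups: AUC 1, DeLong CI collapses to 1
  r <- roc_analysis(list(HC = c(5, 6, 7, 8), RA = c(1, 2, 3, 4)))
  expect_equal(r$auc, 1.0)
  expect_equal(r$ci95[2], 1.0)
  expect_error(roc_analysis(list(HC = numeric(), RA = 1:3)), "nonempty")

  # exact agreement with the concordant-pair count, ties included
  set.seed(41)
  for (i in 1:50) {
    hc <- sample(1:6, 9, replace = TRUE)   # integer ties
    ra <- sample(1:6, 7, replace = TRUE)
    got <- roc_analysis(list(HC = hc, RA = ra))$auc
    expect_equal(got, auc_oracle(hc, ra), tolerance = 1e-12)
  }

  # same-distribution groups: mean AUC ~ 0.5
  set.seed(51)
  aucs <- replicate(500,
    roc_analysis(list(HC = rnorm(12), RA = rnorm(12)))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  # invariance under strictly monotone transforms
  hc <- rnorm(10, 1); ra <- rnorm(10)
  a1 <- roc_analysis(list(HC = hc, RA = ra))$auc
  a2 <- roc_analysis(list(HC = exp(hc), RA = exp(ra)))$auc
  expect_equal(a1, a2)
})

test_that("region comparison table: units of analysis and missing groups", {
  regions <- c("ALL", "S", "I")
  schemes <- c("GLOBAL", "ETDRS", "ETDRS")
  rows <- list()
  set.seed(61)
  for (s in 1:6) {
    grp <- if (s <= 3) "HC" else "RA"
    for (k in seq_along(regions)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("%s%02d", grp, s), group = grp, eye = "OD",
        layer = "SRL", mask_kind = "TMI", scheme = schemes[k],
        region = regions[k],
        density = rnorm(1, 1.7 - 0.1 * (grp == "RA" & regions[k] == "S"), 0.02),
        stringsAsFactors = FALSE)
    }
  }
  tab <- mk_density_table(do.call(rbind, rows))
  by_eye <- compare_all_regions(tab)
  by_subj <- compare_all_regions(tab, unit = "subject")
  # with one eye per subject the two units of analysis coincide exactly
  expect_equal(by_eye$t, by_subj$t)
  expect_equal(by_eye$p, by_subj$p)
  expect_equal(by_eye$n_control, rep(3L, nrow(by_eye)))

  # a region present in only one group is flagged, not fatal
  tab2 <- tab[!(tab$group == "RA" & tab$region == "I"), ]
  cmp <- compare_all_regions(tab2)
  expect_equal(cmp$status[cmp$region == "I"], "MISSING_GROUP")
  expect_true(all(cmp$status[cmp$region != "I"] == "OK"))

  # Bonferroni correction is monotone in the raw p
  cmp_b <- compare_all_regions(tab, p_adjust = "bonferroni")
  expect_true(all(cmp_b$p_adj >= cmp_b$p - 1e-15))
})
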