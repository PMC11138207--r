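# direct-formula oracle for the paired t statistic
oracle_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

test_that("paired t matches the direct formula and its invariances", {
  pre <- c(3, 5, 1, 9, 4)
  post <- c(4, 7, 4, 9, 8)
  s <- paired_t(pre, post)
  o <- oracle_paired_t(pre, post)
  expect_equal(s$statistic, o$t, tolerance = 1e-12)
  expect_equal(s$p, o$p, tolerance = 1e-12)
  expect_equal(s$df, 4)

  # d = (1, 2, 3): closed form t = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  s2 <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(s2$statistic, 2 * sqrt(3), tolerance = 1e-12)

  # identity, shift invariance, antisymmetry
  expect_equal(paired_t(pre, pre)$statistic, 0)
  expect_equal(paired_t(pre, pre)$p, 1)
  expect_equal(paired_t(pre + 10, post + 10)$statistic, s$statistic,
               tolerance = 1e-12)
  expect_equal(paired_t(post, pre)$statistic, -s$statistic,
               tolerance = 1e-12)

  # zero-variance differences with nonzero mean flag an infinite t
  s3 <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_identical(s3$note, "infinite-t")
  expect_equal(s3$p, 0)
  expect_error(paired_t(1, 1), "at least 2")
})

test_that("t_to_p is exact for the symmetric cases and monotone", {
  expect_equal(t_to_p(0, 8), 1)
  expect_equal(t_to_p(2, 8), t_to_p(-2, 8))
  expect_true(all(diff(t_to_p(seq(0, 5, 0.5), 8)) < 0))
  expect_error(t_to_p(1, 0), "parameter error")
})

test_that("t_to_p agrees with numerical integration of the t density", {
  # small grid here; the full df 1..30 sweep runs in the acceptance suite
  for (df in c(1, 3, 8)) {
    for (t in c(0.5, 2.48, 5)) {
      q <- integrate(function(u) dt(u, df), lower = abs(t), upper = Inf,
                     rel.tol = 1e-12)$value
      expect_equal(t_to_p(t, df), 2 * q, tolerance = 1e-9)
    }
  }
})

test_that("pearson matches its t-transform and affine invariance", {
  withr::with_seed(10, {
    x <- rnorm(9)
    y <- x + rnorm(9)
  })
  s <- pearson(x, y)
  r <- cor(x, y)
  t_oracle <- r * sqrt(7) / sqrt(1 - r^2)
  expect_equal(s$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(s$p, 2 * pt(-abs(t_oracle), 7), tolerance = 1e-12)
  expect_equal(s$df, 7)

  expect_equal(pearson(x, x)$estimate, 1)
  s2 <- pearson(2 * x + 3, 0.5 * y - 1)
  expect_equal(s2$estimate, s$estimate, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "undefined-correlation")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

# brute-force step-up definition of BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m / seq(i, m)) * sorted[seq(i, m)]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  grid <- c(0.001, 0.011, 0.02, 0.04, 0.2, 0.9)
  # all non-empty subsets of the grid
  for (bits in 1:(2^6 - 1)) {
    sel <- grid[bitwAnd(bits, 2^(0:5)) > 0]
    expect_equal(bh_adjust(sel), oracle_bh(sel), tolerance = 1e-12)
  }
  # monotone on sorted input
  adj <- bh_adjust(sort(runif(20)))
  expect_true(all(diff(adj) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "parameter error")
})

test_that("SIS domains apply the instrument normalization", {
  counts <- c(adl = 10, hand_function = 5, participation = 8,
              strength = 4)
  # all items 5 -> 100 everywhere; all items 1 -> 0
  expect_equal(unname(sis_domains(counts * 5)), c(100, 100, 100))
  expect_equal(unname(sis_domains(counts * 1)), c(0, 0, 0))
  # ADL normalized 40 (mean item 2.6), Hand 20 (mean item 1.8) -> Function 30
  sc <- c(adl = 26, hand_function = 9, participation = 24, strength = 12)
  d <- sis_domains(sc)
  expect_equal(unname(d["Function"]), 30)
  expect_equal(unname(d["Participation"]), 50)
  expect_equal(unname(d["Impairment"]), (12 / 4 - 1) / 4 * 100)
  expect_error(sis_domains(c(adl = 55, hand_function = 9,
                             participation = 24, strength = 12)),
               "1-5")
  # matrix input gives one row per participant
  m <- rbind(counts * 5, counts * 1)
  dd <- sis_domains(m)
  expect_equal(dd$Impairment, c(100, 0))
})

test_that("correlation matrices adjust within the declared family", {
  withr::with_seed(33, {
    x <- data.frame(a = rnorm(20))
    y <- data.frame(b = rnorm(20))
  })
  single <- correlation_matrix(x, y, family = "single")
  expect_equal(single$p_adjusted, single$p)

  withr::with_seed(34, {
    n <- 30
    x2 <- data.frame(u = rnorm(n), v = rnorm(n))
    y2 <- data.frame(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  })
  mat <- correlation_matrix(x2, y2, family = "fam")
  expect_equal(nrow(mat), 6)
  expect_equal(mat$p_adjusted, bh_adjust(mat$p))
  expect_true(all(mat$family == "fam"))
})

test_that("a strong true correlation survives BH among nulls", {
  hits <- vapply(1:200, function(s) {
    withr::with_seed(5000 + s, {
      n <- 50
      x <- rnorm(n)
      y_true <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
      ys <- data.frame(y1 = y_true, y2 = rnorm(n), y3 = rnorm(n),
                       y4 = rnorm(n), y5 = rnorm(n), y6 = rnorm(n))
    })
    mat <- correlation_matrix(data.frame(x = x), ys)
    mat$p_adjusted[mat$y == "y1"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("all-null families rarely reject after adjustment", {
  any_hit <- vapply(1:500, function(s) {
    withr::with_seed(7000 + s, {
      n <- 9
      x <- data.frame(x = rnorm(n))
      ys <- data.frame(y1 = rnorm(n), y2 = rnorm(n), y3 = rnorm(n))
    })
    any(correlation_matrix(x, ys)$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(any_hit), 0.10)
})

test_that("group report reproduces the analysis layout deterministically", {
  tab <- generate_clinical_table(synth_clinical_config(seed = 11))
  rep1 <- group_report(tab)
  rep2 <- group_report(tab)
  expect_identical(rep1$paired_tests, rep2$paired_tests)
  expect_setequal(rep1$paired_tests$measure,
                  default_clinical_measures()$measure)
  expect_equal(unique(rep1$paired_tests$n), 9)
  # correlation families: er/active x pre/post SIS domains
  expect_true("er_extension_x_sis_post" %in% names(rep1$correlations))
  expect_true(all(vapply(rep1$correlations, nrow, numeric(1)) == 3))
  expect_length(rep1$missing_measures, 0)
})

test_that("group report under null effects is rarely significant", {
  m0 <- default_clinical_measures()
  m0$diff_mean <- 0
  flags <- vapply(1:50, function(s) {
    tab <- generate_clinical_table(
      synth_clinical_config(seed = 8000 + s, measures = m0,
                            correlations = list()))
    any(group_report(tab)$paired_tests$significant)
  }, logical(1))
  # 11 independent tests at alpha 0.05: any-significant prob ~ 0.43
  expect_lte(mean(flags), 0.65)
})

test_that("a strong programmed ROM effect is detected at n = 9", {
  m1 <- default_clinical_measures()
  m1$diff_mean[m1$measure == "active_extension"] <-
    1.5 * m1$diff_sd[m1$measure == "active_extension"]  # Cohen's d 1.5
  hits <- vapply(1:50, function(s) {
    tab <- generate_clinical_table(
      synth_clinical_config(seed = 8500 + s, measures = m1,
                            correlations = list()))
    rep <- group_report(tab)
    rep$paired_tests$significant[rep$paired_tests$measure ==
                                   "active_extension"]
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("cmc change scores feed the report's laterality and peak tests", {
  tab <- generate_clinical_table(synth_clinical_config(seed = 6))
  withr::with_seed(44, {
    cmc_change <- data.frame(
      laterality_extension_pre = rnorm(9, 0.2, 0.3),
      laterality_extension_post = rnorm(9, -0.2, 0.3),
      peak_cmc_flexion_change = rnorm(9, 0, 0.1)
    )
  })
  rep <- group_report(tab, cmc_change = cmc_change)
  expect_true("laterality_extension" %in% rep$cmc_tests$test)
  expect_true("peak_cmc_flexion_vs_fma_change" %in% rep$cmc_tests$test)
  lat_row <- rep$cmc_tests[rep$cmc_tests$test == "laterality_extension", ]
  oracle <- oracle_paired_t(cmc_change$laterality_extension_pre,
                            cmc_change$laterality_extension_post)
  expect_equal(lat_row$statistic, oracle$t, tolerance = 1e-12)
})
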