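# Two-factor indicators and the feature-selection rule.

test_that("I1 matches hand arithmetic in both modes", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(indicator_I1(g, "pairwise"), 1)
  # variances 62.5 and 15.625
  a <- c(800, 810, 790, 805, 795) # var 62.5
  b <- c(800, 805, 795, 802.5, 797.5) # var 15.625
  expect_equal(indicator_I1(list(a, b), "pairwise"), 4)
  expect_equal(indicator_I1(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)), "anova"), 3)
  expect_error(indicator_I1(list(a, rep(1, 5)), "pairwise"), "zero denominator")
  expect_error(indicator_I1(list(a, b, b), "pairwise"), "exactly two")
})

test_that("pairwise I1 is exactly reciprocal under group exchange", {
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(10); b <- rnorm(8, sd = 2)
    expect_equal(indicator_I1(list(a, b), "pairwise") *
                   indicator_I1(list(b, a), "pairwise"), 1,
                 tolerance = 1e-14)
  }
})

test_that("I2 is the one-way ANOVA tail probability", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_equal(indicator_I2(g), 0.125, tolerance = 1e-10)
  # identical group means => F = 0 => probability 1
  expect_equal(indicator_I2(list(c(1, 2, 3), c(2, 1, 3))), 1)
  expect_error(indicator_I2(list(rep(1, 3), rep(1, 4))), "degenerate")
})

test_that("I2 agrees with the aov() oracle on random layouts", {
  for (s in 1:100) {
    set.seed(s)
    k <- sample(2:5, 1L)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:12, 1L), mean = i * runif(1)))
    vals <- unlist(groups)
    fac <- factor(rep(seq_len(k), vapply(groups, length, 1L)))
    oracle <- summary(stats::aov(vals ~ fac))[[1L]][["Pr(>F)"]][1L]
    got <- indicator_I2(groups)
    expect_equal(got, oracle, tolerance = 1e-8)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("significance tiers use strict thresholds", {
  expect_identical(classify_significance(c(0.5, 0.03, 0.007, 0.0005)),
                   c("none", "some", "significant", "extreme"))
  # boundary values do not pass
  expect_identical(classify_significance(c(0.05, 0.01, 0.001)),
                   c("none", "some", "significant"))
})

test_that("the selection rule reproduces the published feature set", {
  tab <- published_indicators()
  expect_identical(select_features(tab),
                   sort(c("fixation_duration", "saccade_range", "sdnn",
                          "avg_speed")))
  # disabling the one-representative-per-category constraint admits CV
  no_cat <- screening_config(category_representative = NULL)
  expect_identical(select_features(tab, no_cat),
                   sort(c("fixation_duration", "saccade_range", "sdnn", "cv",
                          "avg_speed")))
  # pupil variability sits exactly at 0.050 in the intention stage: the
  # strict gate must exclude it even with the category rule off
  expect_false("pupil_variability" %in% select_features(tab, no_cat))

  all_null <- tab
  all_null$I2 <- 1
  expect_identical(select_features(all_null), character(0))
})

test_that("selection is monotone when any I2 decreases", {
  tab <- published_indicators()
  base <- select_features(tab)
  set.seed(42)
  for (i in sample(nrow(tab), 25L)) {
    lowered <- tab
    lowered$I2[i] <- lowered$I2[i] * 0.01
    expect_true(all(base %in% select_features(lowered)))
  }
})

test_that("missing gate cells are reported by name", {
  tab <- published_indicators()
  tab <- tab[!(tab$feature == "sdnn" & tab$stage == "intention" &
                 tab$factor == "LOS"), ]
  expect_error(select_features(tab), "sdnn/LOS/intention")
})

test_that("screening synthetic features flags the configured LOS effects", {
  cfg <- sim_config(n_drivers = 5L)
  ds <- simulate_dataset(cfg, 300, seed = 21)
  f <- extract_features(ds$sessions)
  sc <- screen_features(f)
  expect_true(all(c("feature", "factor", "stage", "I1", "I2", "tier") %in%
                    names(sc)))
  ok <- is.finite(sc$I2)
  expect_true(all(sc$I2[ok] >= 0 & sc$I2[ok] <= 1))
  # speed has the largest configured LOS shifts; its LOS effect must show
  sp <- sc[sc$feature == "avg_speed" & sc$factor == "LOS", ]
  expect_true(all(sp$I2 < 0.05))
})
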