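test_that("suppression percentage anchors at tester = 0 and control = 100", {
  expect_equal(as.numeric(suppression_percent(100, 30, 100)), 100)
  expect_equal(as.numeric(suppression_percent(30, 30, 100)), 0)
  expect_equal(as.numeric(suppression_percent(65, 30, 100)), 50)
  # unclamped overshoot and worsening, but flagged
  over <- suppression_percent(110, 30, 100)
  expect_gt(as.numeric(over), 100)
  expect_true(attr(over, "out_of_range"))
  under <- suppression_percent(20, 30, 100)
  expect_lt(as.numeric(under), 0)
  expect_true(attr(under, "out_of_range"))
  expect_error(suppression_percent(50, 80, 80), "degenerate")
})

test_that("suppression percentage is invariant to rescaling all areas", {
  set.seed(4)
  for (i in 1:20) {
    m <- runif(1, 10, 200); t <- runif(1, 5, 90); c <- t + runif(1, 10, 150)
    k <- runif(1, 0.1, 10)
    expect_equal(as.numeric(suppression_percent(k * m, k * t, k * c)),
                 as.numeric(suppression_percent(m, t, c)))
  }
})

test_that("viability ratio and normalized lethality follow the formulas", {
  expect_equal(viability_ratio(80, 100), 0.8)
  expect_equal(viability_ratio(100, 100), 1)
  expect_equal(viability_ratio(0, 100), 0)
  expect_error(viability_ratio(10, 0), "positive")

  expect_equal(as.numeric(normalized_lethality(0.8, 0.8)), 0)
  expect_equal(as.numeric(normalized_lethality(0, 0.8)), 100)
  expect_equal(as.numeric(normalized_lethality(0.4, 0.8)), 50)
  expect_error(normalized_lethality(0.5, 0), "positive")
  imp <- normalized_lethality(1, 0.8)
  expect_lt(as.numeric(imp), 0)
  expect_true(attr(imp, "improved"))
  # strictly decreasing in V_enh
  vals <- vapply(seq(0, 1, by = 0.1),
                 function(v) as.numeric(normalized_lethality(v, 0.8)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("climbing curve averages trial fractions with n-1 SEM", {
  rec <- data.frame(genotype = "tester", time_point = 1, trial = 1:5,
                    n_above = 6:10, n_total = 10)
  cc <- climbing_curve(rec)
  expect_equal(cc$fraction, 0.8)
  # hand arithmetic: deviations (-.2,-.1,0,.1,.2), SS = 0.1,
  # var = 0.1/4, SEM = sqrt(0.025)/sqrt(5)
  expect_equal(cc$sem, 0.07071068, tolerance = 1e-7)

  const <- data.frame(genotype = "g", time_point = 1, trial = 1:10,
                      n_above = 8, n_total = 10)
  cc2 <- climbing_curve(const)
  expect_equal(cc2$fraction, 0.8)
  expect_equal(cc2$sem, 0)
  perfect <- data.frame(genotype = "g", time_point = 1, trial = 1:10,
                        n_above = 10, n_total = 10)
  expect_equal(climbing_curve(perfect)$fraction, 1)

  bad <- data.frame(genotype = "g", time_point = 1, trial = 1,
                    n_above = 11, n_total = 10)
  expect_error(climbing_curve(bad), "exceeds")
})

test_that("strength classification implements the time-point rules", {
  sup <- rep(1, 5)
  expect_equal(classify_modifier_strength(c(1e-4, 1e-4, 1e-4, 0.2, 0.2),
                                          sup), "strong")
  expect_equal(classify_modifier_strength(c(0.03, 0.04, 0.5, 0.6, 0.7),
                                          sup), "intermediate")
  expect_equal(classify_modifier_strength(c(1e-4, 0.2, 0.3, 0.5, 0.9),
                                          sup), "weak")
  # worsening direction meeting a rule is an enhancer
  expect_equal(classify_modifier_strength(c(1e-4, 1e-4, 1e-4, 0.2, 0.2),
                                          rep(-1, 5)), "enhancer")
  expect_equal(classify_modifier_strength(c(0.03, 0.04, 0.5, 0.6, 0.7),
                                          rep("enhancement", 5)),
               "enhancer")
  # no significant time point
  expect_equal(classify_modifier_strength(rep(0.5, 5), sup), "none")
  expect_error(classify_modifier_strength(c(0.1, 0.2), c(1, 1)),
               "5 time points")
})

test_that("classification is total and deterministic over valid inputs", {
  classes <- c("strong", "intermediate", "weak", "enhancer", "none")
  set.seed(8)
  for (i in 1:200) {
    p <- 10^runif(5, -5, 0)
    d <- sample(c(-1, 1), 5, replace = TRUE)
    cl <- classify_modifier_strength(p, d)
    expect_true(cl %in% classes)
    expect_identical(cl, classify_modifier_strength(p, d))
  }
})

test_that("group comparisons use the design-appropriate test", {
  set.seed(12)
  base <- rnorm(10)
  same <- data.frame(value = rep(base, 3),
                     group = rep(c("a", "b", "c"), each = 10))
  res <- group_compare(same, "one_way")
  expect_equal(res$method, "anova_tukey")
  expect_gt(res$omnibus_p, 0.5)

  two <- data.frame(value = c(rnorm(20, 0), rnorm(20, 5)),
                    group = rep(c("a", "b"), each = 20))
  res2 <- group_compare(two, "one_way")
  expect_equal(res2$method, "t_test")
  expect_lt(res2$omnibus_p, 0.001)

  three <- data.frame(value = c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 5)),
                      group = rep(c("a", "b", "c"), each = 15))
  res3 <- group_compare(three, "one_way")
  flagged <- res3$pairwise[res3$pairwise$significant, ]
  expect_equal(nrow(flagged), 2L)
  expect_true(all(flagged$group1 == "c" | flagged$group2 == "c"))

  tw <- data.frame(value = c(rnorm(30, 0), rnorm(30, 2)),
                   group = rep(c("a", "b"), each = 30),
                   time = rep(rep(1:5, each = 6), 2))
  res4 <- group_compare(tw, "two_way")
  expect_equal(res4$method, "two_way_anova_bonferroni")
  expect_equal(res4$pairwise$p_adj,
               pmin(1, res4$pairwise$p_raw * 5))
  expect_error(group_compare(data.frame(value = 1:3, group = "a"),
                             "one_way"), "2 groups")
})

test_that("screen tally does the modifier arithmetic exactly", {
  tal <- screen_tally(71, 14, 1183)
  expect_identical(tal$n_modifiers, 85L)
  expect_equal(tal$hit_rate_pct, 100 * 85 / 1183)
  expect_equal(round(tal$hit_rate_pct), 7)
})

test_that("quantify_modifiers joins the three screen tables per gene", {
  scr <- generate_screen_table(screen_spec(seed = 9))
  q <- quantify_modifiers(scr$eye, scr$viability, scr$climbing)
  expect_setequal(q$gene, c("mod_sup", "mod_enh"))
  sup <- q[q$gene == "mod_sup", ]
  enh <- q[q$gene == "mod_enh", ]
  expect_gt(sup$suppression_pct, 50)
  expect_lt(enh$suppression_pct, 0)
  expect_true(enh$out_of_range)
  expect_gt(enh$lethality_pct, 25)
  expect_equal(sup$strength_class, "strong")
  expect_equal(enh$strength_class, "enhancer")
  expect_error(quantify_modifiers(scr$eye[scr$eye$genotype != "control", ]),
               "control")
})
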