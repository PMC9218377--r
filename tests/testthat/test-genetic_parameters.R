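# Frozen expectations recomputed from published variance-component rows
# (zinc: mean 18, PV 18, GV 11.5, EV 6.5; iron: mean 37.5, PV 69.6, GV 37,
# EV 32.6; plant height: PV 4577.7, GV 4531.0) with k = 2.056.

test_that("CV, heritability and genetic advance reproduce published rows", {
  zn <- variance_components("Zn", GV = 11.5, EV = 6.5, mean = 18)
  expect_equal(zn$PV, 18)
  cv <- coefficients_of_variation(zn)
  expect_equal(round(unname(cv), 1), c(18.8, 23.6, 14.2))
  expect_equal(round(broad_sense_heritability(zn), 1), 63.9)
  ga <- genetic_advance(zn)
  expect_equal(round(unname(ga["GA"]), 1), 5.6)
  expect_equal(round(unname(ga["GA_pct"]), 0), 31)

  fe <- variance_components("Fe", GV = 37, EV = 32.6, mean = 37.5)
  cv <- coefficients_of_variation(fe)
  expect_equal(round(unname(cv), 1), c(16.2, 22.2, 15.2))
  expect_equal(round(unname(genetic_advance(fe)["GA"]), 1), 9.1)

  pht <- variance_components("PHT", GV = 4531.0, EV = 46.7, mean = 256.6)
  expect_equal(round(broad_sense_heritability(pht), 1), 99.0)
})

test_that("component estimation maps mean squares with truncation", {
  # (395.75 - 25.75)/2 = 185 for a days-to-maturity-like trait
  tab <- structure(
    data.frame(source = c("Genotype", "Environment",
                          "Genotype x Environment"),
               df = c(340, 1, 340), SS = NA,
               MS = c(395.75, 681.72, 25.75), F = NA, p = NA),
    class = c("anova_table", "data.frame"), trait = "DTM",
    grand_mean = 120.1)
  vc <- estimate_variance_components(tab, n_env = 2)
  expect_equal(vc$GV, 185.0)
  expect_equal(vc$EV, 25.75)
  expect_equal(vc$PV, vc$GV + vc$EV)
  expect_false(vc$truncated)

  # MS_G <= MS_GxE truncates to zero with a flag
  tab$MS <- c(25.75, 1, 25.75)
  vc0 <- estimate_variance_components(tab, n_env = 2)
  expect_equal(vc0$GV, 0)
  expect_equal(vc0$PV, vc0$EV)
  tab$MS <- c(10, 1, 25.75)
  expect_true(estimate_variance_components(tab, n_env = 2)$truncated)
})

test_that("degenerate inputs raise domain errors", {
  expect_error(variance_components("x", GV = -1, EV = 1, mean = 5),
               "non-negative")
  z <- variance_components("x", GV = 0, EV = 0, mean = 5)
  expect_error(broad_sense_heritability(z), "PV = 0")
  expect_equal(unname(genetic_advance(z)), c(0, 0))
  m0 <- variance_components("x", GV = 1, EV = 1, mean = 0)
  expect_error(coefficients_of_variation(m0), "positive mean")
  expect_error(genetic_advance(m0), "positive mean")
  # GV = 0 gives GCV = 0
  z2 <- variance_components("x", GV = 0, EV = 4, mean = 10)
  expect_equal(unname(coefficients_of_variation(z2)["GCV"]), 0)
})

test_that("classification scales use continuous boundaries", {
  expect_equal(classify_parameter("cv", 23.6), "high")
  expect_equal(classify_parameter("cv", c(10, 10.05, 20, 20.5)),
               c("low", "moderate", "moderate", "high"))
  expect_equal(classify_parameter("h2", c(30, 30.5, 60, 61)),
               c("low", "medium", "medium", "high"))
  expect_equal(classify_parameter("ga_pct", 10.05), "moderate")
  expect_error(classify_parameter("cv", -1), "non-negative")
})

test_that("scale equivariance: c*x scales GA, leaves percentages alone", {
  base <- variance_components("t", GV = 11.5, EV = 6.5, mean = 18)
  for (c_ in c(0.1, 3, 100)) {
    scaled <- variance_components("t", GV = 11.5 * c_^2, EV = 6.5 * c_^2,
                                  mean = 18 * c_)
    expect_equal(coefficients_of_variation(scaled),
                 coefficients_of_variation(base))
    expect_equal(broad_sense_heritability(scaled),
                 broad_sense_heritability(base))
    expect_equal(unname(genetic_advance(scaled)["GA"]),
                 unname(genetic_advance(base)["GA"]) * c_)
    expect_equal(genetic_advance(scaled)[["GA_pct"]],
                 genetic_advance(base)[["GA_pct"]])
  }
})

test_that("parameter table carries classes and the PV identity", {
  vcs <- list(variance_components("Zn", GV = 11.5, EV = 6.5, mean = 18),
              variance_components("Fe", GV = 37, EV = 32.6, mean = 37.5))
  tab <- genetic_parameter_table(vcs)
  expect_equal(tab$trait, c("Zn", "Fe"))
  expect_equal(tab$PV, tab$GV + tab$EV)
  expect_equal(tab$PCV_class, c("high", "high"))
  expect_equal(tab$H2_class, c("high", "medium"))
  expect_true(all(tab$GCV <= tab$PCV + 1e-12))
  expect_equal(attr(tab, "k"), 2.056)
})
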