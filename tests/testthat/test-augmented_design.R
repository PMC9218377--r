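test_that("block adjustments match hand arithmetic and sum to zero", {
  dat <- toy_dataset()
  adj <- compute_block_adjustments(dat, "L1", "Y")
  # check means 12 and 14, grand mean 13
  expect_equal(adj$adjustment, c(-1, 1))
  expect_equal(adj$n_checks_used, c(2L, 2L))
  expect_equal(sum(adj$adjustment), 0)

  # identical check values in every block -> all adjustments zero
  flat <- dat
  flat$obs$value[flat$obs$role == "check"] <- "10"
  expect_equal(compute_block_adjustments(flat, "L1", "Y")$adjustment,
               c(0, 0))

  # zero-sum invariant on random complete designs
  for (s in 1:5) {
    d <- random_augmented(s)
    a <- compute_block_adjustments(d, "L1", "Y")
    expect_equal(sum(a$adjustment), 0, tolerance = 1e-10)
  }
})

test_that("adjusted entries equal hand values and least-squares BLUEs", {
  dat <- toy_dataset()
  at <- adjust_test_entries(dat, "L1")
  val <- setNames(at$value, at$genotype)
  expect_equal(val[["T1"]], 21)  # 20 - (-1)
  expect_equal(val[["T2"]], 19)  # 20 - (+1)
  expect_equal(val[["C1"]], 11)  # raw mean of (10, 12)
  expect_equal(val[["C2"]], 15)

  # equivalence oracle: explicit normal-equations solve of
  # y = mu + block + genotype reproduces every adjusted mean
  for (s in 1:5) {
    d <- random_augmented(s)
    at <- adjust_test_entries(d, "L1")
    o <- ls_genotype_means(d$obs$genotype, d$obs$block,
                           as.numeric(d$obs$value))
    expect_equal(setNames(at$value, at$genotype)[names(o)], o,
                 tolerance = 1e-8)
  }
})

test_that("adding a constant shifts adjusted means and leaves SS alone", {
  d <- random_augmented(7)
  shift <- d
  shift$obs$value <- as.character(as.numeric(shift$obs$value) + 100)
  a0 <- adjust_test_entries(d, "L1")
  a1 <- adjust_test_entries(shift, "L1")
  expect_equal(a1$value, a0$value + 100)
  t0 <- anova_single_location(d, "L1", "Y")
  t1 <- anova_single_location(shift, "L1", "Y")
  expect_equal(t1$SS, t0$SS, tolerance = 1e-8)
})

test_that("single-location ANOVA books df correctly and SS add up", {
  d <- random_augmented(2, n_checks = 3, n_blocks = 4, n_tests = 6)
  tab <- anova_single_location(d, "L1", "Y")
  df <- setNames(tab$df, tab$source)
  expect_equal(df[["Genotypes"]], 9 - 1)
  expect_equal(df[["Checks"]], 3 - 1)
  expect_equal(df[["Tests"]], 6 - 1)
  expect_equal(df[["Tests vs Checks"]], 1)
  expect_equal(df[["Block"]], 4 - 1)
  expect_equal(df[["Error"]], (3 - 1) * (4 - 1))
  expect_equal(tab$SS[tab$source == "Genotypes"],
               sum(tab$SS[tab$source %in%
                            c("Checks", "Tests", "Tests vs Checks")]))
  # genotype SS equals the sequential least-squares fit after block
  ss_oracle <- local({
    g <- factor(d$obs$genotype); b <- factor(d$obs$block)
    y <- as.numeric(d$obs$value)
    rss <- function(X) sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
    Xb <- cbind(1, stats::model.matrix(~ b)[, -1])
    Xg <- cbind(Xb, stats::model.matrix(~ g)[, -1])
    rss(Xb) - rss(Xg)
  })
  expect_equal(tab$SS[tab$source == "Genotypes"], ss_oracle,
               tolerance = 1e-8)
  expect_error(anova_single_location(toy_dataset(), "L1", "nope"),
               "at least 2")
})

test_that("ANOVA rejects unsupported designs", {
  obs <- data.frame(genotype = c("C1", "C1", "T1"), role = c("check",
                    "check", "test"), location = "L1",
                    block = c("B1", "B2", "B1"), trait = "Y",
                    value = c(1, 2, 3))
  d <- trial_dataset(obs, trait_dictionary(trait_spec("Y", "quantitative")))
  expect_error(anova_single_location(d, "L1", "Y"), "at least 2")
})

test_that("combined ANOVA matches the brute-force two-way decomposition", {
  m <- matrix(c(10, 14, 11, 21,
                12, 15, 15, 18), 4, 2)  # 4 genotypes x 2 locations
  rownames(m) <- paste0("T", 1:4)
  # wrap the matrix as an adjusted_means object
  v <- data.frame(genotype = rep(rownames(m), 2), role = "test",
                  location = rep(c("L1", "L2"), each = 4), trait = "Y",
                  value = as.vector(m))
  am <- structure(list(values = v,
                       pooled = stats::aggregate(value ~ genotype + role +
                                                   trait, v, mean),
                       method = "federer_check_adjustment",
                       checks = character(0), locations = c("L1", "L2")),
                  class = "adjusted_means")
  tab <- combined_anova(am, "Y")
  o <- twoway_ss_oracle(m)
  expect_equal(tab$SS[tab$source == "Genotype"], o$G)
  expect_equal(tab$SS[tab$source == "Environment"], o$E)
  expect_equal(tab$SS[tab$source == "Genotype x Environment"], o$GE)
  expect_equal(sum(tab$SS), o$total)
  expect_equal(tab$df, c(3, 1, 3))

  # identical locations -> SS(E) = SS(GxE) = 0
  v2 <- v; v2$value <- rep(m[, 1], 2)
  am2 <- am; am2$values <- v2
  tab2 <- combined_anova(am2, "Y")
  expect_equal(tab2$SS[2:3], c(0, 0), tolerance = 1e-12)

  am3 <- am; am3$locations <- "L1"
  expect_error(combined_anova(am3, "Y"), "at least 2 locations")
})

test_that("genotypes missing at a location are dropped with a warning", {
  cfg <- small_config(seed = 9)
  dat <- simulate_trial(cfg)
  dat$obs <- dat$obs[!(dat$obs$genotype == "T001" &
                         dat$obs$location == "L2"), ]
  am <- adjusted_means(dat, "YLD")
  expect_warning(tab <- combined_anova(am, "YLD"), "dropped")
  expect_equal(tab$df[1], 40 - 1 - 1)  # 40 tests minus the dropped one
})
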