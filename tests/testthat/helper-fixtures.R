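# Shared fixtures and independent oracles.

# toy augmented design: 2 checks in 2 blocks, 1 test per block, 1 trait.
# check values chosen so block adjustments are B1 = -1, B2 = +1.
toy_dataset <- function() {
  obs <- data.frame(
    genotype = c("C1", "C2", "C1", "C2", "T1", "T2"),
    role = c("check", "check", "check", "check", "test", "test"),
    location = "L1",
    block = c("B1", "B1", "B2", "B2", "B1", "B2"),
    trait = "Y",
    value = c(10, 14, 12, 16, 20, 20))
  trial_dataset(obs, trait_dictionary(trait_spec("Y", "quantitative")))
}

# random complete augmented design at one location
random_augmented <- function(seed, n_checks = 3, n_blocks = 4,
                             n_tests = 6) {
  set.seed(seed)
  checks <- paste0("C", seq_len(n_checks))
  tests <- paste0("T", seq_len(n_tests))
  rows <- list()
  for (b in seq_len(n_blocks))
    rows[[b]] <- data.frame(genotype = checks, role = "check",
                            location = "L1", block = paste0("B", b),
                            trait = "Y",
                            value = round(stats::rnorm(n_checks, 50, 5), 3))
  tb <- rep(seq_len(n_blocks), length.out = n_tests)
  rows[[n_blocks + 1]] <- data.frame(
    genotype = tests, role = "test", location = "L1",
    block = paste0("B", tb), trait = "Y",
    value = round(stats::rnorm(n_tests, 50, 8), 3))
  trial_dataset(do.call(rbind, rows),
                trait_dictionary(trait_spec("Y", "quantitative")))
}

# oracle: explicit normal-equations solve of y = mu + block + genotype,
# returning least-squares genotype means (intercept + genotype effect +
# average block effect). Treatment coding built by hand.
ls_genotype_means <- function(genotype, block, value) {
  g <- factor(genotype); b <- factor(block)
  X <- cbind(1,
             stats::model.matrix(~ b)[, -1, drop = FALSE],
             stats::model.matrix(~ g)[, -1, drop = FALSE])
  beta <- solve(t(X) %*% X, t(X) %*% value)
  nb <- nlevels(b)
  beta_block <- c(0, beta[2:nb])
  gamma <- c(0, beta[(nb + 1):(nb + nlevels(g) - 1)])
  names(gamma) <- levels(g)
  beta[1] + gamma + mean(beta_block)
}

# oracle: Pearson r by the explicit covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * stats::sd(x) * stats::sd(y))
}

# oracle: two-way single-observation ANOVA sums of squares by direct loops
twoway_ss_oracle <- function(m) {
  gm <- mean(m)
  ss_g <- 0; ss_e <- 0; ss_ge <- 0; ss_tot <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ss_tot <- ss_tot + (m[i, j] - gm)^2
    ss_ge <- ss_ge +
      (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
  }
  for (i in seq_len(nrow(m))) ss_g <- ss_g + ncol(m) * (mean(m[i, ]) - gm)^2
  for (j in seq_len(ncol(m))) ss_e <- ss_e + nrow(m) * (mean(m[, j]) - gm)^2
  lapply(list(G = ss_g, E = ss_e, GE = ss_ge, total = ss_tot),
         as.numeric)
}

# small panel-like simulation world (reduced dims for fast unit tests)
small_config <- function(seed = 1, ...) {
  tr <- data.frame(name = c("YLD", "Fe", "Zn"), kind = "quantitative",
                   mean = c(2900, 37.5, 18),
                   var_g = c(708783.5, 37, 11.5),
                   var_loc = c(1000, 4, 2),
                   var_gxe = c(108592.7, 16.3, 3.25),
                   var_block = c(5000, 2, 1),
                   var_res = c(108592.7, 16.3, 3.25))
  cg <- diag(3); dimnames(cg) <- list(tr$name, tr$name)
  cg["Fe", "Zn"] <- cg["Zn", "Fe"] <- 0.32
  cg["YLD", "Fe"] <- cg["Fe", "YLD"] <- -0.26
  sim_config(tr, cor_g = cg, n_test = 40, checks = c("CK1", "CK2"),
             n_blocks = 5, n_locations = 2, seed = seed, ...)
}
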