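# Simulation of multi-location augmented-design trials with known variance
# structure, used to validate every stage of the pipeline.
#
# Quantitative plot values follow
#   y = mu_t + g_i + l_e + (gl)_ie + b_j(e) + eps,
# with genotype effects g drawn multivariate-normal across traits so that
# cross-trait genetic correlations (e.g. Fe-Zn) can be induced. Count
# traits are Poisson with genotype/location/block offsets on the log scale
# (variances rescaled by 1/mean^2 so configured magnitudes act as
# coefficients of variation); the square-root transform downstream is then
# exercised naturally. Qualitative descriptors are drawn once per genotype
# from configured class-proportion vectors. Checks are replicated in every
# block; tests are assigned one block each by round-robin after a seeded
# shuffle.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic augmented-trial world
#'
#' @param traits Data frame with columns `name`, `kind` (`"quantitative"`
#'   or `"count"`), `mean`, `var_g`, `var_loc`, `var_gxe`, `var_block`,
#'   `var_res` (all variances >= 0; for count traits the variances are on
#'   the scale of the trait and are internally converted to log-scale
#'   offsets), optional `units`.
#' @param cor_g Genetic correlation matrix across traits (symmetric
#'   positive semi-definite, dimnames = trait names). Default identity.
#' @param qualitative Named list of class-proportion vectors (each summing
#'   to 1, names = category labels), or `NULL`.
#' @param n_test Number of unreplicated test genotypes.
#' @param checks Character vector of check identifiers (replicated in every
#'   block).
#' @param n_blocks Blocks per location.
#' @param n_locations Number of locations.
#' @param missing_rate Fraction of quantitative plot values set missing.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(traits, cor_g = NULL, qualitative = NULL,
                       n_test = 341,
                       checks = paste0("CK", 1:4),
                       n_blocks = 22, n_locations = 2,
                       missing_rate = 0, seed = 1) {
  need <- c("name", "kind", "mean", "var_g", "var_loc", "var_gxe",
            "var_block", "var_res")
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop("trait config lacks column(s): ", paste(miss, collapse = ", "))
  vcols <- c("var_g", "var_loc", "var_gxe", "var_block", "var_res")
  if (any(as.matrix(traits[vcols]) < 0))
    stop("all variances must be non-negative")
  if (is.null(cor_g)) {
    cor_g <- diag(nrow(traits))
    dimnames(cor_g) <- list(traits$name, traits$name)
  }
  cor_g <- cor_g[traits$name, traits$name, drop = FALSE]
  if (max(abs(cor_g - t(cor_g))) > 1e-8)
    stop("genetic correlation matrix must be symmetric")
  if (min(eigen(cor_g, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("genetic correlation matrix is not positive semi-definite")
  if (!is.null(qualitative)) {
    for (tr in names(qualitative)) {
      p <- qualitative[[tr]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stop("class proportions for '", tr,
             "' must be non-negative and sum to 1")
      if (is.null(names(p)))
        names(qualitative[[tr]]) <- paste0("class", seq_along(p))
    }
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(traits = traits, cor_g = cor_g,
                 qualitative = qualitative, n_test = n_test,
                 checks = checks, n_blocks = n_blocks,
                 n_locations = n_locations, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Panel-like default simulation config
#'
#' The stated world of the bundled sorghum panel: 341 tests + 4 checks in
#' 22 blocks at 2 locations; 13 quantitative/count traits with the panel's
#' published means, genotypic (GV) and environmental (EV) variance
#' magnitudes; genetic correlations Fe-Zn 0.32, YLD-Fe -0.26,
#' YLD-Zn -0.17; 10 qualitative descriptors with the published class
#' proportions. EV is split evenly between genotype-by-location interaction
#' and plot residual (the published tables do not separate them), block
#' variance is set to EV/2 and location variance to EV.
#'
#' @param traits Optional subset of trait names to simulate.
#' @param qualitative Include the qualitative descriptors.
#' @param missing_rate Fraction of quantitative plot values set missing.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sorghum_sim_config <- function(traits = NULL, qualitative = TRUE,
                               missing_rate = 0, seed = 42) {
  comp <- sorghum_reference("components")
  if (!is.null(traits)) {
    bad <- setdiff(traits, comp$trait)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    comp <- comp[comp$trait %in% traits, , drop = FALSE]
  }
  tr <- data.frame(name = comp$trait, kind = comp$kind, units = comp$units,
                   mean = comp$mean, var_g = comp$GV,
                   var_loc = comp$EV, var_gxe = comp$EV / 2,
                   var_block = comp$EV / 2, var_res = comp$EV / 2)
  cg <- diag(nrow(tr)); dimnames(cg) <- list(tr$name, tr$name)
  set_r <- function(a, b, r) {
    if (all(c(a, b) %in% tr$name)) { cg[a, b] <<- r; cg[b, a] <<- r }
  }
  set_r("Fe", "Zn", 0.32)
  set_r("YLD", "Fe", -0.26)
  set_r("YLD", "Zn", -0.17)
  qual <- if (isTRUE(qualitative)) sorghum_class_proportions() else NULL
  sim_config(tr, cor_g = cg, qualitative = qual,
             n_test = 341, checks = paste0("CK", 1:4), n_blocks = 22,
             n_locations = 2, missing_rate = missing_rate, seed = seed)
}

#' Draw qualitative descriptor values for a set of genotypes
#'
#' One multinomial draw per genotype and trait from the configured class
#' proportions.
#'
#' @param proportions Named list of class-proportion vectors.
#' @param n Number of genotypes.
#' @param seed Integer seed.
#' @return Data frame, one row per genotype, one column per trait.
#' @export
simulate_qualitative_traits <- function(proportions, n, seed = 1) {
  for (tr in names(proportions)) {
    p <- proportions[[tr]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("invalid proportions for '", tr, "'")
  }
  with_seed(seed, {
    out <- lapply(proportions, function(p)
      sample(names(p), n, replace = TRUE, prob = p))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Simulate a multi-location augmented-design trial
#'
#' @param config A [sim_config()].
#' @return A [trial_dataset()], deterministic given the config (same seed
#'   twice gives identical datasets).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$traits
  ntr <- nrow(tr)
  tests <- sprintf("T%03d", seq_len(config$n_test))
  genos <- c(config$checks, tests)
  ng <- length(genos)
  nl <- config$n_locations
  nb <- config$n_blocks
  locs <- paste0("L", seq_len(nl))
  blocks <- sprintf("B%02d", seq_len(nb))
  is_count <- tr$kind == "count"
  # effect scale per trait: raw units for quantitative, CV-style log-scale
  # offsets for counts
  esc <- function(v) ifelse(is_count, sqrt(v) / tr$mean, sqrt(v))

  with_seed(config$seed, {
    # correlated genotype effects across traits
    z <- matrix(stats::rnorm(ng * ntr), ng, ntr)
    cl <- chol(config$cor_g + diag(1e-10, ntr))
    G <- z %*% cl
    G <- sweep(G, 2, esc(tr$var_g), "*")
    L <- matrix(stats::rnorm(nl * ntr), nl, ntr)
    L <- sweep(L, 2, esc(tr$var_loc), "*")
    GL <- array(stats::rnorm(ng * nl * ntr), c(ng, nl, ntr))
    GL <- sweep(GL, 3, esc(tr$var_gxe), "*")
    B <- array(stats::rnorm(nl * nb * ntr), c(nl, nb, ntr))
    B <- sweep(B, 3, esc(tr$var_block), "*")

    # field layout: checks in every block, tests round-robin after shuffle
    test_order <- sample(tests)
    test_block <- stats::setNames(rep(seq_len(nb),
                                      length.out = length(tests)),
                                  test_order)
    layout1 <- rbind(
      data.frame(genotype = rep(config$checks, each = nb),
                 role = "check", block = rep(seq_len(nb),
                                             length(config$checks))),
      data.frame(genotype = test_order, role = "test",
                 block = as.integer(test_block)))
    plots <- do.call(rbind, lapply(seq_len(nl), function(e)
      data.frame(layout1, location = e)))
    gi <- match(plots$genotype, genos)
    li <- plots$location
    bi <- plots$block
    np <- nrow(plots)

    rows <- vector("list", ntr + length(config$qualitative))
    for (t in seq_len(ntr)) {
      eff <- G[cbind(gi, t)] + L[cbind(li, t)] +
        GL[cbind(gi, li, t)] + B[cbind(li, bi, t)]
      if (is_count[t]) {
        lambda <- tr$mean[t] * exp(eff)
        y <- stats::rpois(np, lambda)
      } else {
        y <- tr$mean[t] + eff + stats::rnorm(np, 0, sqrt(tr$var_res[t]))
      }
      if (config$missing_rate > 0)
        y[stats::runif(np) < config$missing_rate] <- NA
      rows[[t]] <- data.frame(
        genotype = plots$genotype, role = plots$role,
        location = locs[li], block = blocks[bi], trait = tr$name[t],
        value = ifelse(is.na(y), NA_character_,
                       as.character(signif(y, 10))))
    }
    if (length(config$qualitative)) {
      qvals <- as.data.frame(lapply(config$qualitative, function(p)
        sample(names(p), ng, replace = TRUE, prob = p)),
        stringsAsFactors = FALSE)
      names(qvals) <- names(config$qualitative)
      for (q in seq_along(config$qualitative)) {
        qt <- names(config$qualitative)[q]
        rows[[ntr + q]] <- data.frame(
          genotype = plots$genotype, role = plots$role,
          location = locs[li], block = blocks[bi], trait = qt,
          value = qvals[[qt]][gi])
      }
    }
    obs <- do.call(rbind, rows)

    specs <- lapply(seq_len(ntr), function(t)
      trait_spec(tr$name[t], tr$kind[t],
                 units = if ("units" %in% names(tr)) tr$units[t] else ""))
    qspecs <- lapply(names(config$qualitative), function(qt)
      trait_spec(qt, "qualitative",
                 categories = names(config$qualitative[[qt]])))
    dict <- do.call(trait_dictionary, c(specs, qspecs))
    trial_dataset(obs, dict, checks = config$checks)
  })
}

#' Heritability parameter-recovery report
#'
#' For each replicate: simulate a trial from the config (per-replicate seed
#' = master seed + replicate index), adjust test entries, run the combined
#' across-location ANOVA, estimate variance components, and record the
#' broad-sense heritability. The truth for each trait is
#' var_g / (var_g + var_gxe + var_res), the heritability on the
#' adjusted-mean scale the estimator targets.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Master seed.
#' @param traits Traits to evaluate (default: the non-count traits).
#' @return Object of class `recovery_report`: data frame with columns
#'   `trait`, `true_H2`, `mean_H2`, `bias`, `rmse` (H2 as a fraction),
#'   with attributes `n_replicates` and `seed`.
#' @export
parameter_recovery_report <- function(config, n_replicates, seed = 1,
                                      traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_replicates < 2) stop("need at least 2 replicates")
  tr <- config$traits
  if (is.null(traits)) traits <- tr$name[tr$kind != "count"]
  idx <- match(traits, tr$name)
  if (anyNA(idx)) stop("trait(s) not in config")
  truth <- tr$var_g[idx] /
    (tr$var_g[idx] + tr$var_gxe[idx] + tr$var_res[idx])
  if (any(!is.finite(truth)))
    stop("degenerate config: zero total variance for some trait")
  est <- matrix(NA_real_, n_replicates, length(traits),
                dimnames = list(NULL, traits))
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + seed + r
    dat <- simulate_trial(cfg)
    am <- adjusted_means(dat, traits)
    for (j in seq_along(traits)) {
      ca <- suppressWarnings(combined_anova(am, traits[j]))
      vc <- estimate_variance_components(ca, n_env = config$n_locations)
      est[r, j] <- vc$GV / vc$PV
    }
  }
  out <- data.frame(trait = traits, true_H2 = truth,
                    mean_H2 = colMeans(est),
                    bias = colMeans(est) - truth,
                    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)))
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"),
            n_replicates = n_replicates, seed = seed)
}
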