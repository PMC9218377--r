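# Check-based adjustment of unreplicated test entries (Federer's augmented
# randomized complete block convention) and the associated analysis of
# variance. Only the replicated checks carry information about block
# effects: a block's adjustment is the deviation of its check mean from the
# grand check mean, and the intra-block error is estimated from the
# checks x blocks two-way subtable.

# long numeric slice for one trait at one location
trait_slice <- function(data, location, trait) {
  sel <- data$obs$location == location & data$obs$trait == trait
  d <- data$obs[sel, c("genotype", "role", "block", "value")]
  d$value <- suppressWarnings(as.numeric(d$value))
  d
}

#' Block adjustments from check means
#'
#' For each block at a location, the adjustment is the block's check mean
#' minus the unweighted grand mean of block check means. Blocks containing
#' no check plot get adjustment 0 (with `n_checks_used = 0`) and a warning.
#'
#' @param data A [trial_dataset()].
#' @param location Location identifier.
#' @param trait Quantitative trait name.
#' @return Data frame with columns `location`, `block`, `adjustment`,
#'   `n_checks_used`.
#' @export
compute_block_adjustments <- function(data, location, trait) {
  stopifnot(inherits(data, "trial_dataset"))
  d <- trait_slice(data, location, trait)
  blocks <- sort(unique(d$block))
  ck <- d[d$genotype %in% data$checks & !is.na(d$value), , drop = FALSE]
  if (nrow(ck) == 0L)
    stop("no check values for trait '", trait, "' at location '",
         location, "'")
  bm <- tapply(ck$value, factor(ck$block, levels = blocks), mean)
  n_ck <- tapply(ck$value, factor(ck$block, levels = blocks), length)
  n_ck[is.na(n_ck)] <- 0L
  grand <- mean(bm, na.rm = TRUE)
  adj <- bm - grand
  empty <- is.na(adj)
  if (any(empty)) {
    warning("block(s) without check values at '", location, "': ",
            paste(blocks[empty], collapse = ", "),
            " (adjustment set to 0)")
    adj[empty] <- 0
  }
  data.frame(location = location, block = blocks,
             adjustment = as.numeric(adj),
             n_checks_used = as.integer(n_ck), row.names = NULL)
}

#' Adjusted entry means for one location
#'
#' Test entries are adjusted by subtracting their block's adjustment; check
#' entries are reported as raw means over blocks. Missing observations stay
#' missing.
#'
#' @param data A [trial_dataset()].
#' @param location Location identifier.
#' @param traits Trait names (default: all quantitative and count traits).
#' @return Long data frame `genotype`, `role`, `location`, `trait`, `value`.
#' @export
adjust_test_entries <- function(data, location,
                                traits = quantitative_traits(data)) {
  stopifnot(inherits(data, "trial_dataset"))
  out <- lapply(traits, function(tr) {
    d <- trait_slice(data, location, tr)
    if (nrow(d) == 0L) return(NULL)
    adj <- compute_block_adjustments(data, location, tr)
    is_check <- d$genotype %in% data$checks
    tests <- d[!is_check, , drop = FALSE]
    tests$value <- tests$value -
      adj$adjustment[match(tests$block, adj$block)]
    checks <- d[is_check, , drop = FALSE]
    if (nrow(checks)) {
      m <- tapply(checks$value, checks$genotype, mean, na.rm = TRUE)
      checks <- data.frame(genotype = names(m), role = "check",
                           block = NA_character_, value = as.numeric(m))
    }
    res <- rbind(tests[c("genotype", "role", "value")],
                 checks[c("genotype", "role", "value")])
    data.frame(genotype = res$genotype, role = res$role,
               location = location, trait = tr, value = res$value,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Adjusted means across all locations, with pooling
#'
#' Runs [adjust_test_entries()] for every location and pools per-genotype
#' values as the arithmetic mean over the locations where the genotype was
#' observed.
#'
#' @param data A [trial_dataset()].
#' @param traits Trait names (default: all quantitative and count traits).
#' @return Object of class `adjusted_means`: list with `values` (per
#'   location, long), `pooled` (long), `method`, `checks`, `locations`.
#' @export
adjusted_means <- function(data, traits = quantitative_traits(data)) {
  stopifnot(inherits(data, "trial_dataset"))
  locs <- sort(unique(data$obs$location))
  values <- do.call(rbind, lapply(locs, function(l)
    adjust_test_entries(data, l, traits)))
  agg <- stats::aggregate(value ~ genotype + role + trait, data = values,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  agg$value[is.nan(agg$value)] <- NA_real_
  structure(list(values = values, pooled = agg,
                 method = "federer_check_adjustment",
                 checks = data$checks, locations = locs),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("adjusted_means (", x$method, "): ",
      length(unique(x$pooled$genotype)), " genotypes, ",
      length(unique(x$pooled$trait)), " traits, ",
      length(x$locations), " location(s)\n", sep = "")
  invisible(x)
}

#' Pooled adjusted means as a genotype x trait matrix
#'
#' @param adjusted An [adjusted_means()] object.
#' @param traits Traits to include (default all present).
#' @param role Restrict to `"test"`, `"check"`, or both (default both).
#' @param complete_cases Drop genotypes with any missing trait value.
#' @return Numeric matrix, genotypes in rows.
#' @export
pooled_matrix <- function(adjusted, traits = NULL,
                          role = c("test", "check"),
                          complete_cases = FALSE) {
  stopifnot(inherits(adjusted, "adjusted_means"))
  p <- adjusted$pooled[adjusted$pooled$role %in% role, , drop = FALSE]
  if (!is.null(traits)) p <- p[p$trait %in% traits, , drop = FALSE]
  tr <- if (is.null(traits)) sort(unique(p$trait)) else traits
  gen <- sort(unique(p$genotype))
  m <- matrix(NA_real_, length(gen), length(tr),
              dimnames = list(gen, tr))
  m[cbind(match(p$genotype, gen), match(p$trait, tr))] <- p$value
  if (complete_cases) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

anova_table <- function(rows, error_row, trait, scope) {
  structure(rows, class = c("anova_table", "data.frame"),
            error_row = error_row, trait = trait, scope = scope)
}

#' Single-location augmented ANOVA for one trait
#'
#' Sequential (type-I) decomposition of the augmented randomized complete
#' block design: Block (unadjusted), Genotypes (adjusted for block),
#' partitioned into Checks, Tests and Tests vs Checks, with the intra-block
#' error from the checks x blocks subtable. With c checks, t tests and b
#' blocks the error carries (c-1)(b-1) degrees of freedom.
#'
#' @param data A [trial_dataset()].
#' @param location Location identifier.
#' @param trait Quantitative trait name.
#' @return An `anova_table` (data frame `source`, `df`, `SS`, `MS`, `F`,
#'   `p`).
#' @export
anova_single_location <- function(data, location, trait) {
  stopifnot(inherits(data, "trial_dataset"))
  d <- trait_slice(data, location, trait)
  d <- d[!is.na(d$value), , drop = FALSE]
  is_check <- d$genotype %in% data$checks
  ck <- d[is_check, , drop = FALSE]
  if (length(unique(ck$genotype)) < 2L)
    stop("unsupported design: need at least 2 replicated checks")
  if (length(unique(ck$block)) < 2L)
    stop("unsupported design: checks must appear in at least 2 blocks")

  # sequential (type-I) fit: block, then the genotype factor expanded
  # hierarchically as test-vs-check contrast, check identities, and test
  # identities; the three genotype rows are additive by construction
  d$block <- factor(d$block)
  d$group <- factor(ifelse(is_check, "check", "test"))
  d$check_id <- factor(ifelse(is_check, d$genotype, ".test"))
  d$genotype <- factor(d$genotype)
  fit <- stats::lm(value ~ block + group + check_id + genotype, data = d)
  seq_ss <- stats::anova(fit)
  ss_block <- seq_ss["block", "Sum Sq"]
  df_block <- seq_ss["block", "Df"]
  ss_tvc <- seq_ss["group", "Sum Sq"]
  df_tvc <- seq_ss["group", "Df"]
  ss_checks <- seq_ss["check_id", "Sum Sq"]
  df_checks <- seq_ss["check_id", "Df"]
  ss_tests <- seq_ss["genotype", "Sum Sq"]
  df_tests <- seq_ss["genotype", "Df"]
  ss_err <- seq_ss["Residuals", "Sum Sq"]
  df_err <- seq_ss["Residuals", "Df"]
  ss_geno <- ss_tvc + ss_checks + ss_tests
  df_geno <- df_tvc + df_checks + df_tests

  ms_err <- ss_err / df_err
  rows <- data.frame(
    source = c("Genotypes", "Checks", "Tests vs Checks", "Tests", "Block",
               "Error"),
    df = c(df_geno, df_checks, df_tvc, df_tests, df_block, df_err),
    SS = c(ss_geno, ss_checks, ss_tvc, ss_tests, ss_block, ss_err))
  rows$MS <- rows$SS / rows$df
  rows$F <- c(rows$MS[1:5] / ms_err, NA)
  rows$p <- ifelse(is.na(rows$F), NA,
                   stats::pf(rows$F, rows$df, df_err, lower.tail = FALSE))
  anova_table(rows, error_row = "Error", trait = trait,
              scope = paste0("location:", location))
}

#' Combined across-location ANOVA of adjusted means
#'
#' Two-way decomposition of the genotype x location table of adjusted test
#' means (one value per cell): Genotype, Environment, and Genotype x
#' Environment. Genotype and Environment are tested against the G x E mean
#' square. Because each cell holds a single adjusted mean, G x E cannot be
#' separated from error internally; when per-location ANOVA tables are
#' supplied, G x E is tested against their pooled intra-block error mean
#' square (effective replication of an adjusted mean taken as 1) and this
#' choice is recorded in the table's metadata.
#'
#' Only test genotypes present at every location enter (others are dropped
#' with a warning); checks are excluded, following the degrees of freedom
#' of the combined analysis.
#'
#' @param adjusted An [adjusted_means()] object.
#' @param trait Trait name.
#' @param error_pool Optional list of single-location `anova_table`s for the
#'   same trait, used to pool the intra-block error.
#' @return An `anova_table` with rows Genotype, Environment,
#'   Genotype x Environment, and (when pooled) Pooled error.
#' @export
combined_anova <- function(adjusted, trait, error_pool = NULL) {
  stopifnot(inherits(adjusted, "adjusted_means"))
  if (length(adjusted$locations) < 2L)
    stop("combined analysis needs at least 2 locations")
  v <- adjusted$values
  v <- v[v$trait == trait & v$role == "test", , drop = FALSE]
  gen <- sort(unique(v$genotype))
  locs <- adjusted$locations
  m <- matrix(NA_real_, length(gen), length(locs),
              dimnames = list(gen, locs))
  m[cbind(match(v$genotype, gen), match(v$location, locs))] <- v$value
  keep <- stats::complete.cases(m)
  if (!all(keep))
    warning(sum(!keep), " genotype(s) missing at some location dropped ",
            "from combined analysis of '", trait, "'")
  m <- m[keep, , drop = FALSE]
  g <- nrow(m); e <- ncol(m)
  if (g < 2L) stop("fewer than 2 genotypes with complete location data")

  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ss_g <- e * sum((rm_ - gm)^2)
  ss_e <- g * sum((cm - gm)^2)
  ss_ge <- sum((m - outer(rm_, rep(1, e)) -
                  outer(rep(1, g), cm) + gm)^2)
  df_g <- g - 1L; df_e <- e - 1L; df_ge <- df_g * df_e
  ms_g <- ss_g / df_g; ms_e <- ss_e / df_e; ms_ge <- ss_ge / df_ge

  rows <- data.frame(
    source = c("Genotype", "Environment", "Genotype x Environment"),
    df = c(df_g, df_e, df_ge),
    SS = c(ss_g, ss_e, ss_ge),
    MS = c(ms_g, ms_e, ms_ge),
    F = c(ms_g / ms_ge, ms_e / ms_ge, NA),
    p = c(stats::pf(ms_g / ms_ge, df_g, df_ge, lower.tail = FALSE),
          stats::pf(ms_e / ms_ge, df_e, df_ge, lower.tail = FALSE),
          NA))
  if (!is.null(error_pool)) {
    pool <- do.call(rbind, lapply(error_pool, function(a) {
      er <- a[a$source == attr(a, "error_row"), , drop = FALSE]
      data.frame(df = er$df, MS = er$MS)
    }))
    ms_pool <- sum(pool$df * pool$MS) / sum(pool$df)
    rows$F[3] <- ms_ge / ms_pool
    rows$p[3] <- stats::pf(rows$F[3], df_ge, sum(pool$df),
                           lower.tail = FALSE)
    rows <- rbind(rows, data.frame(
      source = "Pooled error", df = sum(pool$df), SS = NA, MS = ms_pool,
      F = NA, p = NA))
  }
  out <- anova_table(rows, error_row = "Genotype x Environment",
                     trait = trait, scope = "combined")
  attr(out, "n_genotypes") <- g
  attr(out, "grand_mean") <- gm
  attr(out, "note") <- paste(
    "tests only; G and E tested against GxE; GxE tested against pooled",
    "intra-block error with effective replication 1")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA (", attr(x, "scope"), ") trait=", attr(x, "trait"), "\n",
      sep = "")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}
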