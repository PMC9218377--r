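# Shannon-Weaver diversity of qualitative descriptors. H' = -sum p_i ln p_i
# over descriptor classes (natural log, 0 * ln 0 = 0) and equitability
# E_H = H' / ln(S). The default richness basis for S is the number of
# accessions scored, which is the convention that reproduces published
# germplasm-panel equitability values; the textbook basis (number of
# declared classes) is available as an option.

#' Category distribution for a qualitative trait
#'
#' @param counts Named non-negative integer vector (names = categories), or
#'   unnamed with `categories` supplied.
#' @param trait Trait name (metadata).
#' @param categories Optional declared category labels (defaults to
#'   `names(counts)`); categories absent from `counts` get count 0.
#' @return Object of class `category_distribution` with counts, total and
#'   proportions.
#' @export
category_distribution <- function(counts, trait = NA_character_,
                                  categories = names(counts)) {
  if (is.null(categories))
    stop("category labels required (name the counts or pass categories)")
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be non-negative")
  full <- stats::setNames(rep(0, length(categories)), categories)
  full[names(counts)] <- counts
  n <- sum(full)
  if (n == 0) stop("empty distribution for trait '", trait, "'")
  structure(list(trait = trait, counts = full, n_total = n,
                 proportions = full / n),
            class = "category_distribution")
}

#' Consensus category proportions across genotypes
#'
#' Each genotype contributes one consensus value: the modal category across
#' its plots/locations, ties broken by the first-declared category. The
#' distribution is over genotypes with a non-missing consensus.
#'
#' @param data A [trial_dataset()].
#' @param trait Qualitative trait name.
#' @return A [category_distribution()].
#' @export
category_proportions <- function(data, trait) {
  stopifnot(inherits(data, "trial_dataset"))
  kind <- data$traits$kind[data$traits$name == trait]
  if (!length(kind) || kind != "qualitative")
    stop("'", trait, "' is not a declared qualitative trait")
  cats <- trait_categories(data$traits, trait)
  sel <- data$obs$trait == trait & !is.na(data$obs$value)
  d <- data$obs[sel, c("genotype", "value")]
  if (nrow(d) == 0L) stop("all values missing for trait '", trait, "'")
  consensus <- tapply(d$value, d$genotype, function(v) {
    tab <- table(factor(v, levels = cats))
    cats[which.max(tab)]  # which.max takes the first-declared on ties
  })
  counts <- table(factor(consensus, levels = cats))
  category_distribution(stats::setNames(as.integer(counts), cats),
                        trait = trait)
}

#' Shannon-Weaver diversity index
#'
#' H' = -sum over classes of p_i ln p_i (natural log), with 0 ln 0 = 0.
#'
#' @param x A [category_distribution()], or a numeric vector of proportions
#'   (or percentages summing to ~100, which are rescaled).
#' @return H' in nats.
#' @export
shannon_index <- function(x) {
  p <- if (inherits(x, "category_distribution")) x$proportions else x
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("proportions sum to zero")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon's equitability
#'
#' E_H = H' / ln(S). With `basis = "accessions"` (default) S is the number
#' of genotypes scored; with `basis = "categories"` S is the number of
#' declared classes.
#'
#' @param H_prime Shannon index in nats.
#' @param S Richness (>= 2).
#' @param basis Richness basis, recorded as an attribute.
#' @return Equitability value.
#' @export
equitability <- function(H_prime, S,
                         basis = c("accessions", "categories")) {
  basis <- match.arg(basis)
  if (S < 2) stop("richness S must be at least 2")
  structure(H_prime / log(S), basis = basis)
}

#' Chi-square heterogeneity test against the equiprobable null
#'
#' chi2 = sum (O_i - E_i)^2 / E_i with E_i = n/S over the S declared
#' categories; df = S - 1.
#'
#' @param dist A [category_distribution()].
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_uniformity <- function(dist) {
  stopifnot(inherits(dist, "category_distribution"))
  s <- length(dist$counts)
  if (s < 2) stop("need at least 2 declared categories")
  expected <- dist$n_total / s
  chi2 <- sum((dist$counts - expected)^2 / expected)
  df <- s - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Diversity summary over all qualitative traits
#'
#' One row per qualitative trait: observed class proportions, H',
#' equitability, and the equiprobable-null chi-square test, plus the
#' unweighted mean H' over traits.
#'
#' @param data A [trial_dataset()].
#' @param equitability_basis Passed to [equitability()]; with the default
#'   `"accessions"`, S is the number of genotypes with a consensus score
#'   for the trait.
#' @return Object of class `diversity_table`: data frame (one row per
#'   trait) with attribute `mean_H`.
#' @export
diversity_table <- function(data,
                            equitability_basis = c("accessions",
                                                   "categories")) {
  stopifnot(inherits(data, "trial_dataset"))
  equitability_basis <- match.arg(equitability_basis)
  trs <- qualitative_traits(data)
  if (!length(trs)) stop("no qualitative traits declared")
  rows <- lapply(trs, function(tr) {
    dist <- category_proportions(data, tr)
    h <- shannon_index(dist)
    s <- if (equitability_basis == "accessions") dist$n_total
         else length(dist$counts)
    eh <- if (s >= 2) as.numeric(equitability(h, s, equitability_basis))
          else NA_real_
    ct <- chi_square_uniformity(dist)
    data.frame(trait = tr, n = dist$n_total,
               categories = paste(names(dist$counts), collapse = "|"),
               proportions_pct = paste(
                 sprintf("%.1f", 100 * dist$proportions), collapse = "|"),
               H_prime = h, E_H = eh, chi2 = ct$chi2, df = ct$df,
               p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("diversity_table", "data.frame"),
            mean_H = mean(out$H_prime),
            equitability_basis = equitability_basis)
}

#' @export
print.diversity_table <- function(x, ...) {
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  cat("mean H' =", round(attr(x, "mean_H"), 2), "\n")
  invisible(x)
}
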