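# Multivariate description of the germplasm: pairwise Pearson correlation
# with t-based tests, principal component analysis on the correlation
# matrix of z-standardized traits, UPGMA (average linkage) clustering on
# Euclidean distances, and k-means partitioning. All methods operate on the
# pooled adjusted-mean genotype x trait matrix.

# coerce adjusted_means or matrix/data.frame input to a numeric matrix
as_trait_matrix <- function(x, traits = NULL, complete_cases = FALSE) {
  if (inherits(x, "adjusted_means"))
    return(pooled_matrix(x, traits = traits,
                         complete_cases = complete_cases))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (!is.null(traits)) m <- m[, traits, drop = FALSE]
  if (complete_cases) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

# z-standardize columns with the sample (n-1) standard deviation; constant
# columns are dropped with a warning
standardize_traits <- function(m) {
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant trait(s) removed: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m, center = TRUE, scale = sds)
}

p_stars <- function(p) ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                       ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))

#' Pairwise Pearson correlation matrix with significance tests
#'
#' Pairwise-complete Pearson coefficients with two-sided t-based p-values
#' (p reported only where at least 3 complete pairs exist). Constant traits
#' yield `NA` coefficients and are flagged.
#'
#' @param x An [adjusted_means()] object or a numeric genotype x trait
#'   matrix / data frame.
#' @param traits Trait names to include (default: all columns).
#' @return Object of class `correlation_matrix`: list with `r`, `p`, `n`,
#'   `stars`, `traits`, `constant`.
#' @export
correlation_matrix <- function(x, traits = NULL) {
  m <- as_trait_matrix(x, traits)
  if (ncol(m) < 2L) stop("need at least 2 traits")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(m)[!is.na(sds) & sds == 0]
  r <- suppressWarnings(
    stats::cor(m, use = "pairwise.complete.obs", method = "pearson"))
  k <- ncol(m)
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k))
    n[i, j] <- sum(stats::complete.cases(m[, c(i, j)]))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  ok <- n >= 3 & !is.na(r) & abs(r) < 1
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p[ok] <- 2 * stats::pt(abs(tstat[ok]), n[ok] - 2, lower.tail = FALSE)
  p[!is.na(r) & abs(r) == 1 & n >= 3] <- 0
  diag(p) <- NA
  structure(list(r = r, p = p, n = n, stars = p_stars(p),
                 traits = colnames(m), constant = constant),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  disp <- matrix(paste0(format(round(x$r, digits)),
                        ifelse(x$stars == "ns", "", x$stars)),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Principal component analysis of standardized trait means
#'
#' Eigen-decomposition of the correlation matrix of the complete-case,
#' z-standardized genotype x trait matrix. Components are ordered by
#' eigenvalue; each loading vector is signed so that its largest-magnitude
#' element is positive. Components with eigenvalue > 1 are marked retained.
#'
#' @param x An [adjusted_means()] object or numeric matrix.
#' @param traits Trait names to include.
#' @return Object of class `trait_pca`: eigenvalues, proportion and
#'   cumulative percentages, loadings (trait x component), scores
#'   (genotype x component), `retained`.
#' @export
trait_pca <- function(x, traits = NULL) {
  m <- as_trait_matrix(x, traits, complete_cases = TRUE)
  if (nrow(m) <= ncol(m))
    stop("need more complete-case genotypes than traits")
  z <- standardize_traits(m)
  cm <- stats::cor(z)
  eig <- eigen(cm, symmetric = TRUE)
  val <- pmax(eig$values, 0)
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(z), paste0("PC", seq_len(ncol(vec))))
  scores <- z %*% vec
  prop <- 100 * val / sum(val)
  structure(list(eigenvalues = val, proportion = prop,
                 cumulative = cumsum(prop), loadings = vec,
                 scores = scores, retained = sum(val > 1),
                 n_genotypes = nrow(z)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA of", ncol(x$loadings), "traits,", x$n_genotypes, "genotypes;",
      x$retained, "component(s) with eigenvalue > 1\n")
  tab <- rbind(Eigenvalue = round(x$eigenvalues, 3),
               `Proportion (%)` = round(x$proportion, 1),
               `Cumulative (%)` = round(x$cumulative, 1))
  colnames(tab) <- colnames(x$loadings)
  print(tab)
  invisible(x)
}

#' Flag important loadings
#'
#' A trait is flagged as an important contributor to a component when the
#' absolute loading is at least `threshold` (inclusive).
#'
#' @param result A [trait_pca()] object.
#' @param threshold Loading magnitude cut-off (default 0.30).
#' @return Logical trait x component matrix.
#' @export
important_loadings <- function(result, threshold = 0.30) {
  stopifnot(inherits(result, "trait_pca"))
  abs(result$loadings) >= threshold
}

#' UPGMA dendrogram of genotypes
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' z-standardized trait profiles. Cutting the tree at `k` clusters gives
#' assignments.
#'
#' @param x An [adjusted_means()] object or numeric matrix.
#' @param traits Trait names to include.
#' @param k Optional number of clusters to cut at.
#' @param standardize Standardize traits first (default TRUE).
#' @return Object of class `cluster_result` with the `hclust` tree, merge
#'   heights, and (when `k` given) assignments.
#' @export
upgma_tree <- function(x, traits = NULL, k = NULL, standardize = TRUE) {
  m <- as_trait_matrix(x, traits, complete_cases = TRUE)
  if (nrow(m) < 2L) stop("need at least 2 complete-case genotypes")
  z <- if (standardize) standardize_traits(m) else m
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "average")
  assignments <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(assignments = assignments, k = k, method = "upgma_cut",
                 tree = hc, heights = hc$height, labels = rownames(z)),
            class = "cluster_result")
}

#' Cophenetic (tree) distances of a UPGMA result
#'
#' @param result A `cluster_result` from [upgma_tree()].
#' @return A `dist` object of cophenetic distances.
#' @export
cophenetic_distances <- function(result) {
  stopifnot(inherits(result, "cluster_result"),
            result$method == "upgma_cut")
  stats::cophenetic(result$tree)
}

#' Export a UPGMA dendrogram as a Newick string
#'
#' @param result A `cluster_result` from [upgma_tree()].
#' @param path Optional file to write to.
#' @return Newick string, invisibly if written to file.
#' @export
as_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"),
            result$method == "upgma_cut")
  phy <- ape::as.phylo(result$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' K-means partition of genotypes
#'
#' K-means (Hartigan-Wong, 10 random restarts) on the z-standardized trait
#' matrix, deterministic for a given seed. Cluster ids are relabelled 1..k
#' by descending cluster mean of `rank_trait` (raw scale) so that reported
#' cluster numbers are stable; without `rank_trait`, by descending size.
#'
#' @param x An [adjusted_means()] object or numeric matrix.
#' @param traits Trait names to include.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed driving initialization.
#' @param rank_trait Optional trait used to order cluster labels (e.g.
#'   grain yield).
#' @param nstart Number of random restarts.
#' @return Object of class `cluster_result` with assignments, within- and
#'   between-cluster sums of squares.
#' @export
kmeans_clusters <- function(x, traits = NULL, k = 4, seed = 1,
                            rank_trait = NULL, nstart = 10) {
  if (k < 2) stop("k must be at least 2")
  m <- as_trait_matrix(x, traits, complete_cases = TRUE)
  if (k > nrow(m)) stop("k exceeds the number of genotypes")
  z <- standardize_traits(m)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  raw_assign <- stats::setNames(km$cluster, rownames(z))
  if (!is.null(rank_trait) && rank_trait %in% colnames(m)) {
    key <- tapply(m[, rank_trait], raw_assign, mean)
    ord <- order(-key)
  } else ord <- order(-tabulate(raw_assign, k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- stats::setNames(relabel[raw_assign], names(raw_assign))
  structure(list(assignments = assignments, k = k, method = "kmeans",
                 seed = seed,
                 withinss = km$withinss[ord],
                 tot_withinss = km$tot.withinss,
                 betweenss = km$betweenss, totss = km$totss,
                 centers = km$centers[ord, , drop = FALSE],
                 labels = rownames(z)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result (", x$method, ")", sep = "")
  if (!is.null(x$k)) cat(": k =", x$k)
  cat(",", length(x$labels), "genotypes\n")
  if (!is.null(x$assignments)) print(table(x$assignments))
  invisible(x)
}

#' Cluster trait means and origin composition
#'
#' @param result A `cluster_result` with assignments.
#' @param x The matrix / [adjusted_means()] the clustering was computed on
#'   (raw trait scale is used for the means).
#' @param traits Trait names to summarize.
#' @param origins Optional named character vector genotype -> origin;
#'   genotypes without an entry are counted as `"unknown"`.
#' @return List with `cluster_means` (cluster x trait) and `source_counts`
#'   (cluster x origin), plus `sizes`.
#' @export
cluster_summary <- function(result, x, traits = NULL, origins = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$assignments)) stop("cluster result has no assignments")
  m <- as_trait_matrix(x, traits, complete_cases = TRUE)
  m <- m[names(result$assignments), , drop = FALSE]
  cl <- factor(result$assignments)
  means <- do.call(rbind, lapply(split(seq_len(nrow(m)), cl),
                                 function(ix)
                                   colMeans(m[ix, , drop = FALSE])))
  sizes <- as.integer(table(cl))
  src <- NULL
  if (!is.null(origins)) {
    o <- origins[names(result$assignments)]
    o[is.na(o)] <- "unknown"
    src <- table(cluster = cl, origin = o)
  }
  list(cluster_means = means, sizes = sizes, source_counts = src)
}
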