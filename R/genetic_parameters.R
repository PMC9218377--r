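# Variance components from the combined ANOVA's expected mean squares and
# the derived selection-genetics statistics: coefficients of variation
# (GCV/PCV/ECV), broad-sense heritability H2 = 100 * GV/PV, and predicted
# genetic advance GA = H2 * sigma_p * k under truncation selection.
#
# Component mapping (default, two-component mode): with n_env environments,
#   GV = (MS_G - MS_GxE) / n_env   (truncated at 0),
#   EV = MS_GxE,
#   PV = GV + EV  (identity enforced).
# A stricter three-component mode keeps a separate GxE term:
#   GV as above, GxE = (MS_GxE - MS_err)/1, EV = MS_err, available when a
#   pooled error row is present.

#' Construct a variance-component record directly
#'
#' Downstream statistics accept components directly, so published component
#' tables can be re-analysed without the ANOVA stage.
#'
#' @param trait Trait name.
#' @param GV,EV Genotypic and environmental variance (trait units squared).
#' @param mean Population mean of the trait (must be finite).
#' @param PV Phenotypic variance; defaults to `GV + EV`.
#' @param n_env Number of environments the components refer to.
#' @param truncated Whether a negative method-of-moments GV was truncated.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(trait, GV, EV, mean, PV = GV + EV,
                                n_env = NA_integer_, truncated = FALSE) {
  if (GV < 0 || EV < 0 || PV < 0)
    stop("variance components must be non-negative")
  structure(list(trait = trait, PV = PV, GV = GV, EV = EV, mean = mean,
                 n_env = n_env, truncated = truncated),
            class = "variance_components")
}

#' Estimate variance components from a combined ANOVA table
#'
#' @param combined An `anova_table` from [combined_anova()] with Genotype
#'   and Genotype x Environment rows.
#' @param n_env Number of environments (locations).
#' @param mean Grand mean of the trait; defaults to the grand mean recorded
#'   on the table.
#' @return Object of class `variance_components`. A negative
#'   method-of-moments genotypic variance is truncated to zero and flagged
#'   (`truncated = TRUE`).
#' @export
estimate_variance_components <- function(combined, n_env,
                                         mean = attr(combined,
                                                     "grand_mean")) {
  stopifnot(inherits(combined, "anova_table"))
  ms_g <- combined$MS[combined$source == "Genotype"]
  ms_ge <- combined$MS[combined$source == "Genotype x Environment"]
  if (!length(ms_g) || !length(ms_ge))
    stop("combined ANOVA table lacks Genotype / Genotype x Environment rows")
  gv <- (ms_g - ms_ge) / n_env
  truncated <- gv < 0
  gv <- max(gv, 0)
  variance_components(attr(combined, "trait"), GV = gv, EV = ms_ge,
                      mean = mean, n_env = n_env, truncated = truncated)
}

#' Coefficients of variation (percent)
#'
#' GCV, PCV and ECV are 100 * sqrt(component) / mean.
#'
#' @param vc A [variance_components()] object.
#' @return Named numeric vector `c(GCV, PCV, ECV)`.
#' @export
coefficients_of_variation <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.finite(vc$mean) || vc$mean <= 0)
    stop("coefficients of variation need a positive mean")
  c(GCV = 100 * sqrt(vc$GV) / vc$mean,
    PCV = 100 * sqrt(vc$PV) / vc$mean,
    ECV = 100 * sqrt(vc$EV) / vc$mean)
}

#' Broad-sense heritability (percent)
#'
#' H2 = 100 * GV / PV, the share of phenotypic variance that is genotypic.
#'
#' @param vc A [variance_components()] object.
#' @return Heritability in percent.
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$PV <= 0) stop("heritability undefined for PV = 0")
  100 * vc$GV / vc$PV
}

#' Predicted genetic advance under truncation selection
#'
#' GA = H2 * sigma_p * k with H2 as a fraction and sigma_p = sqrt(PV);
#' GA% = 100 * GA / mean. The default k = 2.056 is the standardized
#' selection differential for selecting the top 5 percent.
#'
#' @param vc A [variance_components()] object.
#' @param k Standardized selection differential.
#' @return Named numeric vector `c(GA, GA_pct)`.
#' @export
genetic_advance <- function(vc, k = 2.056) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$PV < 0) stop("PV must be non-negative")
  ga <- if (vc$PV == 0) 0 else (vc$GV / vc$PV) * sqrt(vc$PV) * k
  if (!is.finite(vc$mean) || vc$mean <= 0)
    stop("GA% needs a positive mean")
  c(GA = ga, GA_pct = 100 * ga / vc$mean)
}

#' Classify a genetic parameter on its conventional scale
#'
#' Coefficients of variation and GA%: low <= 10 < moderate <= 20 < high.
#' Heritability: low <= 30 < medium <= 60 < high. Boundaries are continuous
#' (the conventional printed scales leave 10-11 style gaps).
#'
#' @param statistic One of `"cv"`, `"h2"`, `"ga_pct"`.
#' @param value Parameter value in percent (non-negative).
#' @return Class label.
#' @export
classify_parameter <- function(statistic = c("cv", "h2", "ga_pct"), value) {
  statistic <- match.arg(statistic)
  if (any(value < 0)) stop("parameter values must be non-negative")
  if (statistic == "h2")
    ifelse(value <= 30, "low", ifelse(value <= 60, "medium", "high"))
  else
    ifelse(value <= 10, "low", ifelse(value <= 20, "moderate", "high"))
}

#' Genetic-parameter table for a set of traits
#'
#' Applies [coefficients_of_variation()], [broad_sense_heritability()] and
#' [genetic_advance()] to each variance-component record and attaches the
#' conventional class labels.
#'
#' @param vcs List of [variance_components()] objects.
#' @param k Standardized selection differential (default 2.056).
#' @return Data frame with one row per trait: Mean, PV, GV, EV, GCV, PCV,
#'   ECV, H2, GA, GA_pct plus `*_class` label columns.
#' @export
genetic_parameter_table <- function(vcs, k = 2.056) {
  rows <- lapply(vcs, function(vc) {
    cv <- coefficients_of_variation(vc)
    h2 <- broad_sense_heritability(vc)
    ga <- genetic_advance(vc, k = k)
    data.frame(trait = vc$trait, Mean = vc$mean, PV = vc$PV, GV = vc$GV,
               EV = vc$EV, GCV = cv[["GCV"]], PCV = cv[["PCV"]],
               ECV = cv[["ECV"]], H2 = h2, GA = ga[["GA"]],
               GA_pct = ga[["GA_pct"]],
               GCV_class = classify_parameter("cv", cv[["GCV"]]),
               PCV_class = classify_parameter("cv", cv[["PCV"]]),
               H2_class = classify_parameter("h2", h2),
               GA_pct_class = classify_parameter("ga_pct", ga[["GA_pct"]]),
               truncated = vc$truncated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  rownames(out) <- NULL
  out
}
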