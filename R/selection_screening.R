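# Selection screening: ranking entries against the best replicated check
# (percent gain) and threshold screening of grain micronutrient density.
# Conventions: gain threshold inclusive (>=), nutrient thresholds strict
# (>); the "best" check maximizes a benefit trait and minimizes a cost
# trait.

#' Percent gain over the best check
#'
#' The best check is the one with the maximal value (benefit traits) or
#' minimal value (`direction = "min"`, cost traits such as earliness).
#' Gain is 100 * (value - best_check) / best_check.
#'
#' @param values Named numeric vector genotype -> trait value (checks
#'   included).
#' @param checks Character vector of check identifiers.
#' @param direction `"max"` (default) or `"min"`.
#' @return Object of class `selection_report`: data frame `ranked`
#'   (genotype, value, rank, gain_pct) ordered by rank, plus `best_check`
#'   and `best_check_value`.
#' @export
percent_gain_over_best_check <- function(values, checks,
                                         direction = c("max", "min")) {
  direction <- match.arg(direction)
  ckv <- values[names(values) %in% checks]
  ckv <- ckv[!is.na(ckv)]
  if (!length(ckv)) stop("no check values available")
  best <- if (direction == "max") which.max(ckv) else which.min(ckv)
  best_value <- ckv[[best]]
  v <- values[!is.na(values)]
  gain <- 100 * (v - best_value) / best_value
  if (direction == "min") gain <- -gain
  ord <- order(if (direction == "max") -v else v, names(v))
  ranked <- data.frame(genotype = names(v)[ord], value = as.numeric(v[ord]),
                       rank = seq_along(v), gain_pct = as.numeric(gain[ord]),
                       row.names = NULL)
  structure(list(ranked = ranked, best_check = names(ckv)[best],
                 best_check_value = best_value, direction = direction),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, n = 10, ...) {
  cat("selection_report: best check", x$best_check, "=",
      x$best_check_value, "\n")
  print(utils::head(x$ranked, n), row.names = FALSE)
  invisible(x)
}

#' Select genotypes by minimum gain
#'
#' Genotypes with gain >= `min_gain` (inclusive), in descending gain order;
#' ties broken by genotype identifier.
#'
#' @param report A [percent_gain_over_best_check()] result.
#' @param min_gain Gain threshold in percent.
#' @return Character vector of selected genotypes.
#' @export
rank_and_select <- function(report, min_gain) {
  stopifnot(inherits(report, "selection_report"))
  r <- report$ranked
  r <- r[r$gain_pct >= min_gain, , drop = FALSE]
  r <- r[order(-r$gain_pct, r$genotype), , drop = FALSE]
  r$genotype
}

#' Micronutrient density screen
#'
#' Strict-threshold screen for grain iron and zinc density: a genotype
#' passes when its concentration exceeds the threshold (Fe > `fe_min` ppm,
#' Zn > `zn_min` ppm). Genotypes with a missing value are excluded from
#' that screen and reported.
#'
#' @param fe,zn Named numeric vectors genotype -> ppm.
#' @param fe_min,zn_min Thresholds in ppm (defaults 60 and 32, the
#'   conventional biofortification targets).
#' @return List with `pass_Fe`, `pass_Zn`, `pass_either` (character
#'   vectors, descending concentration), `excluded_Fe`, `excluded_Zn`, and
#'   the thresholds.
#' @export
nutrient_screen <- function(fe, zn, fe_min = 60, zn_min = 32) {
  if (!length(fe) && !length(zn)) stop("no nutrient values supplied")
  screen1 <- function(v, thr) {
    excluded <- names(v)[is.na(v)]
    v <- v[!is.na(v)]
    pass <- v[v > thr]
    list(pass = names(pass)[order(-pass, names(pass))],
         excluded = excluded)
  }
  sf <- screen1(fe, fe_min)
  sz <- screen1(zn, zn_min)
  list(pass_Fe = sf$pass, pass_Zn = sz$pass,
       pass_either = union(sf$pass, sz$pass),
       excluded_Fe = sf$excluded, excluded_Zn = sz$excluded,
       fe_min = fe_min, zn_min = zn_min)
}
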