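# Data model and I/O for plot-level augmented-trial phenotype data.
#
# The canonical on-disk form is a long-format CSV (RFC 4180, UTF-8, header
# required) with columns genotype, role, location, block, trait, value, plus
# a trait dictionary CSV with columns name, kind, units, categories,
# transform (categories pipe-separated). Values are stored as character
# internally so that quantitative measurements and qualitative category
# labels share one observation table; numeric conversion happens at the
# point of use.

TRAIT_KINDS <- c("quantitative", "count", "qualitative")

#' Declare a single trait
#'
#' @param name Trait identifier, unique within a dictionary.
#' @param kind One of `"quantitative"`, `"count"`, `"qualitative"`.
#' @param units Free-text units (e.g. `"cm"`, `"ppm"`, `"codes"`).
#' @param categories Ordered character vector of class labels; required for
#'   qualitative traits (at least two), forbidden otherwise.
#' @param transform `"none"` or `"sqrt"`; count traits default to `"sqrt"`.
#' @return A one-row data frame usable as a trait-dictionary row.
#' @export
trait_spec <- function(name, kind, units = "", categories = NULL,
                       transform = if (kind == "count") "sqrt" else "none") {
  kind <- match.arg(kind, TRAIT_KINDS)
  transform <- match.arg(transform, c("none", "sqrt"))
  if (kind == "qualitative") {
    if (length(categories) < 2L)
      stop("qualitative trait '", name, "' needs at least 2 categories")
  } else if (length(categories))
    stop("trait '", name, "' is ", kind, " and cannot declare categories")
  data.frame(name = as.character(name), kind = kind, units = units,
             categories = paste(categories, collapse = "|"),
             transform = transform, stringsAsFactors = FALSE)
}

#' Assemble a trait dictionary
#'
#' @param ... One-row data frames from [trait_spec()], or a single data frame.
#' @return A validated trait-dictionary data frame.
#' @export
trait_dictionary <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.data.frame(specs[[1]]) &&
      nrow(specs[[1]]) != 1L)
    dict <- specs[[1]]
  else
    dict <- do.call(rbind, specs)
  if (anyDuplicated(dict$name))
    stop("duplicate trait names in dictionary: ",
         paste(unique(dict$name[duplicated(dict$name)]), collapse = ", "))
  rownames(dict) <- NULL
  dict
}

trait_categories <- function(traits, name) {
  row <- traits[traits$name == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown trait: ", name)
  if (row$kind != "qualitative") return(character(0))
  strsplit(row$categories, "|", fixed = TRUE)[[1]]
}

#' Construct a plot-level trial dataset
#'
#' @param obs Data frame with columns `genotype`, `role` (`"test"`/`"check"`),
#'   `location`, `block`, `trait`, `value`. Values may be numeric or category
#'   labels; missing values are `NA` or empty strings.
#' @param traits Trait dictionary (see [trait_dictionary()]).
#' @param checks Character vector of check genotype identifiers; defaults to
#'   the genotypes with role `"check"`.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(obs, traits, checks = NULL) {
  needed <- c("genotype", "role", "location", "block", "trait", "value")
  miss <- setdiff(needed, names(obs))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
  obs <- obs[needed]
  for (col in needed) obs[[col]] <- as.character(obs[[col]])
  obs$value[!is.na(obs$value) & obs$value == ""] <- NA_character_
  bad <- setdiff(unique(obs$trait), traits$name)
  if (length(bad))
    stop("trait(s) not in dictionary: ", paste(bad, collapse = ", "))
  if (!all(obs$role %in% c("test", "check")))
    stop("role must be 'test' or 'check'")
  if (is.null(checks))
    checks <- sort(unique(obs$genotype[obs$role == "check"]))
  # qualitative labels must come from the declared category list
  for (tr in traits$name[traits$kind == "qualitative"]) {
    v <- obs$value[obs$trait == tr]
    v <- v[!is.na(v)]
    bad <- setdiff(unique(v), trait_categories(traits, tr))
    if (length(bad))
      stop("trait '", tr, "': undeclared categories: ",
           paste(bad, collapse = ", "))
  }
  # quantitative/count values must parse to finite numbers
  for (tr in traits$name[traits$kind != "qualitative"]) {
    v <- obs$value[obs$trait == tr]
    v <- v[!is.na(v)]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num) || any(!is.finite(num)))
      stop("trait '", tr, "': non-numeric or non-finite values present")
  }
  structure(list(obs = obs, traits = traits, checks = checks,
                 transformed = character(0)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("trial_dataset:", length(unique(x$obs$genotype)), "genotypes (",
      length(x$checks), "checks ),",
      length(unique(x$obs$location)), "location(s),",
      nrow(x$traits), "traits,", nrow(x$obs), "plot values\n")
  invisible(x)
}

# numeric values of one trait, named by nothing; rows of obs preserved
numeric_values <- function(data, trait) {
  sel <- data$obs$trait == trait
  suppressWarnings(as.numeric(data$obs$value[sel]))
}

quantitative_traits <- function(data)
  data$traits$name[data$traits$kind %in% c("quantitative", "count")]

qualitative_traits <- function(data)
  data$traits$name[data$traits$kind == "qualitative"]

#' Read a trait dictionary CSV
#'
#' Columns: `name`, `kind`, `units`, `categories` (pipe-separated class
#' labels, empty for non-qualitative traits), `transform`.
#'
#' @param path CSV file path.
#' @return Trait-dictionary data frame.
#' @export
read_trait_dictionary <- function(path) {
  if (!file.exists(path)) stop("trait dictionary not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  miss <- setdiff(c("name", "kind"), names(raw))
  if (length(miss))
    stop("trait dictionary lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$units)) raw$units <- ""
  if (is.null(raw$categories)) raw$categories <- ""
  if (is.null(raw$transform) || all(raw$transform == ""))
    raw$transform <- ifelse(raw$kind == "count", "sqrt", "none")
  raw$transform[raw$transform == ""] <-
    ifelse(raw$kind[raw$transform == ""] == "count", "sqrt", "none")
  specs <- lapply(seq_len(nrow(raw)), function(i) {
    cats <- if (nzchar(raw$categories[i]))
      strsplit(raw$categories[i], "|", fixed = TRUE)[[1]] else NULL
    trait_spec(raw$name[i], raw$kind[i], raw$units[i], cats, raw$transform[i])
  })
  do.call(trait_dictionary, specs)
}

#' Read a long-format trial CSV with its trait dictionary
#'
#' @param path Trial CSV (columns genotype, role, location, block, trait,
#'   value; empty value fields are missing).
#' @param dictionary_path Trait dictionary CSV (see
#'   [read_trait_dictionary()]).
#' @return A validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, dictionary_path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  traits <- read_trait_dictionary(dictionary_path)
  obs <- tryCatch(
    utils::read.csv(path, colClasses = "character"),
    error = function(e) stop("malformed trial CSV '", path, "': ",
                             conditionMessage(e)))
  trial_dataset(obs, traits)
}

#' Read a wide-format trial CSV (one column per trait)
#'
#' Convenience reader: columns genotype, role, location, block, then one
#' column per trait named as in the dictionary.
#'
#' @inheritParams read_trial_csv
#' @return A validated [trial_dataset()].
#' @export
read_trial_wide_csv <- function(path, dictionary_path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  traits <- read_trait_dictionary(dictionary_path)
  wide <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE)
  id <- c("genotype", "role", "location", "block")
  miss <- setdiff(id, names(wide))
  if (length(miss))
    stop("wide trial CSV lacks column(s): ", paste(miss, collapse = ", "))
  tr_cols <- setdiff(names(wide), id)
  long <- do.call(rbind, lapply(tr_cols, function(tr)
    data.frame(wide[id], trait = tr, value = wide[[tr]],
               stringsAsFactors = FALSE)))
  trial_dataset(long, traits)
}

#' Write a trial dataset back to long CSV (and optionally its dictionary)
#'
#' @param data A [trial_dataset()].
#' @param path Output CSV path.
#' @param dictionary_path Optional path for the trait dictionary CSV.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, dictionary_path = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  out <- data$obs
  out$value[is.na(out$value)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  if (!is.null(dictionary_path))
    utils::write.csv(data$traits, dictionary_path, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Square-root transform of count traits
#'
#' Replaces x with sqrt(x) (or sqrt(x + 0.5) when `add_half = TRUE`) for all
#' traits flagged `transform = "sqrt"` in the dictionary. Transform
#' provenance is recorded on the dataset; applying the transform twice is an
#' error.
#'
#' @param data A [trial_dataset()].
#' @param add_half Use sqrt(x + 0.5) instead of plain sqrt(x).
#' @return A transformed copy of `data`.
#' @export
transform_counts <- function(data, add_half = FALSE) {
  stopifnot(inherits(data, "trial_dataset"))
  flagged <- data$traits$name[data$traits$transform == "sqrt"]
  if (length(intersect(flagged, data$transformed)))
    stop("count traits already transformed: ",
         paste(intersect(flagged, data$transformed), collapse = ", "))
  if (!length(flagged)) return(data)
  for (tr in flagged) {
    sel <- which(data$obs$trait == tr & !is.na(data$obs$value))
    x <- as.numeric(data$obs$value[sel])
    if (any(x < 0)) {
      i <- sel[which(x < 0)[1]]
      stop("negative count for trait '", tr, "' at genotype ",
           data$obs$genotype[i], ", location ", data$obs$location[i],
           ", block ", data$obs$block[i])
    }
    data$obs$value[sel] <-
      as.character(sqrt(x + if (add_half) 0.5 else 0))
  }
  data$transformed <- union(data$transformed, flagged)
  data
}

#' Structural validation report for a trial dataset
#'
#' Reports, per trait, the number of missing plot values; test genotypes
#' observed at only a subset of the locations; and blocks from which a
#' declared check is absent (a warning-level degradation for the adjustment,
#' not an error). The report is deterministic: entries are sorted.
#'
#' @param data A [trial_dataset()].
#' @return An object of class `trial_validation` with elements
#'   `missing_values`, `single_location_entries`, `blocks_missing_check`,
#'   and `n_issues`.
#' @export
validate_dataset <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  obs <- data$obs
  mv <- vapply(sort(unique(obs$trait)), function(tr)
    sum(is.na(obs$value[obs$trait == tr])), integer(1))
  mv <- data.frame(trait = names(mv), n_missing = unname(mv))

  locs <- sort(unique(obs$location))
  tests <- sort(unique(obs$genotype[obs$role == "test"]))
  gl <- unique(obs[c("genotype", "location")])
  n_loc <- table(factor(gl$genotype[gl$genotype %in% tests], levels = tests))
  single <- names(n_loc)[n_loc < length(locs)]

  bm <- list()
  blocks <- unique(obs[c("location", "block")])
  for (i in seq_len(nrow(blocks))) {
    present <- unique(obs$genotype[obs$location == blocks$location[i] &
                                     obs$block == blocks$block[i]])
    for (ck in setdiff(data$checks, present))
      bm[[length(bm) + 1L]] <- data.frame(
        location = blocks$location[i], block = blocks$block[i], check = ck)
  }
  bm <- if (length(bm)) do.call(rbind, bm) else
    data.frame(location = character(0), block = character(0),
               check = character(0))
  bm <- bm[order(bm$location, bm$block, bm$check), , drop = FALSE]
  rownames(bm) <- NULL

  structure(list(
    missing_values = mv,
    single_location_entries = single,
    blocks_missing_check = bm,
    n_issues = sum(mv$n_missing > 0) + length(single) + nrow(bm)),
    class = "trial_validation")
}

#' @export
print.trial_validation <- function(x, ...) {
  cat("trial validation:", x$n_issues, "issue(s)\n")
  if (any(x$missing_values$n_missing > 0)) {
    cat("  missing values per trait:\n")
    mv <- x$missing_values[x$missing_values$n_missing > 0, ]
    for (i in seq_len(nrow(mv)))
      cat("    ", mv$trait[i], ": ", mv$n_missing[i], "\n", sep = "")
  }
  if (length(x$single_location_entries))
    cat("  single-location entries:",
        paste(x$single_location_entries, collapse = ", "), "\n")
  if (nrow(x$blocks_missing_check))
    cat("  blocks missing a check:", nrow(x$blocks_missing_check), "\n")
  invisible(x)
}
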