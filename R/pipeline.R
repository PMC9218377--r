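# End-to-end orchestration: adjust -> ANOVA -> genetic parameters ->
# diversity -> correlation/PCA/clustering -> selection, from one run
# config, writing one CSV per stage plus a JSON manifest (parameters,
# seeds, warnings, artifact checksums). Reruns with identical config and
# inputs reproduce identical outputs.

default_run_params <- function() {
  list(k = 2.056, kmeans_k = 4, seed = 1, loading_threshold = 0.30,
       equitability_basis = "accessions", fe_min = 60, zn_min = 32,
       min_gain = 12, yield_trait = "YLD", fe_trait = "Fe",
       zn_trait = "Zn")
}

#' Read a run configuration (JSON)
#'
#' Recognized fields: `input` (list with `trial` and `dictionary` CSV
#' paths) or `simulate` (logical; uses the panel-like synthetic world),
#' `stages` (named logicals: adjust, anova, genetic_parameters, diversity,
#' correlation, pca, cluster, selection), `params` (see
#' [run_full_analysis()]), `outdir`.
#'
#' @param path JSON file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline
#'
#' @param config Config list (see [read_run_config()]); may also be a path
#'   to a JSON config.
#' @return The run manifest (list), invisibly; written as `manifest.json`
#'   in the output directory alongside the stage CSVs.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  params <- utils::modifyList(default_run_params(),
                              as.list(config$params %||% list()))
  stages <- utils::modifyList(
    list(adjust = TRUE, anova = TRUE, genetic_parameters = TRUE,
         diversity = TRUE, correlation = TRUE, pca = TRUE, cluster = TRUE,
         selection = TRUE),
    as.list(config$stages %||% list()))
  outdir <- config$outdir %||% "augtrial_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  artifacts <- character(0)
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    artifacts <<- c(artifacts, file)
    path
  }
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # ---- input ----
  data <- run_stage("input", {
    if (!is.null(config$input)) {
      read_trial_csv(config$input$trial, config$input$dictionary)
    } else if (isTRUE(config$simulate) || is.list(config$simulate)) {
      sim_seed <- if (is.list(config$simulate))
        config$simulate$seed %||% params$seed else params$seed
      simulate_trial(sorghum_sim_config(seed = sim_seed))
    } else stop("config needs either 'input' paths or 'simulate'")
  })
  data <- run_stage("transform", transform_counts(data))
  val <- validate_dataset(data)
  if (val$n_issues > 0)
    note(paste("validation:", val$n_issues, "issue(s)"))

  am <- NULL
  if (stages$adjust) {
    am <- run_stage("adjust", adjusted_means(data))
    emit(am$values, "adjusted_means_by_location.csv")
    emit(am$pooled, "adjusted_means_pooled.csv")
  }

  anovas <- list()
  if (stages$anova) {
    run_stage("anova", {
      locs <- sort(unique(data$obs$location))
      qt <- quantitative_traits(data)
      per_loc <- list(); comb <- list()
      for (trn in qt) {
        anovas[[trn]] <- lapply(locs, function(l)
          anova_single_location(data, l, trn))
        for (i in seq_along(locs))
          per_loc[[paste(trn, i)]] <- data.frame(
            trait = trn, location = locs[i],
            as.data.frame(anovas[[trn]][[i]]))
        if (length(locs) >= 2) {
          ca <- combined_anova(am %||% adjusted_means(data, trn), trn,
                               error_pool = anovas[[trn]])
          comb[[trn]] <- data.frame(trait = trn, as.data.frame(ca))
          anovas[[trn]]$combined <- ca
        }
      }
      emit(do.call(rbind, per_loc), "anova_by_location.csv")
      if (length(comb)) emit(do.call(rbind, comb), "anova_combined.csv")
    })
  }

  if (stages$genetic_parameters && length(anovas) &&
      length(sort(unique(data$obs$location))) >= 2) {
    run_stage("genetic_parameters", {
      n_env <- length(unique(data$obs$location))
      vcs <- lapply(names(anovas), function(trn)
        estimate_variance_components(anovas[[trn]]$combined,
                                     n_env = n_env))
      emit(genetic_parameter_table(vcs, k = params$k),
           "genetic_parameters.csv")
    })
  }

  if (stages$diversity && length(qualitative_traits(data))) {
    run_stage("diversity", {
      dt <- diversity_table(data, params$equitability_basis)
      out <- as.data.frame(dt)
      out$stars <- p_stars(out$p)
      emit(out, "diversity.csv")
    })
  }

  if (stages$correlation && !is.null(am)) {
    run_stage("correlation", {
      cm <- correlation_matrix(pooled_matrix(am))
      emit(data.frame(trait = rownames(cm$r), round(cm$r, 4)),
           "correlation_r.csv")
      emit(data.frame(trait = rownames(cm$p), cm$stars),
           "correlation_stars.csv")
    })
  }

  if (stages$pca && !is.null(am)) {
    run_stage("pca", {
      pc <- trait_pca(pooled_matrix(am, complete_cases = TRUE))
      emit(data.frame(component = colnames(pc$loadings),
                      eigenvalue = pc$eigenvalues,
                      proportion_pct = pc$proportion,
                      cumulative_pct = pc$cumulative), "pca_eigen.csv")
      imp <- important_loadings(pc, params$loading_threshold)
      emit(data.frame(trait = rownames(pc$loadings),
                      round(pc$loadings, 4),
                      important = apply(imp, 1, function(r)
                        paste(colnames(imp)[r], collapse = "|"))),
           "pca_loadings.csv")
      emit(data.frame(genotype = rownames(pc$scores),
                      round(pc$scores, 4)), "pca_scores.csv")
    })
  }

  if (stages$cluster && !is.null(am)) {
    run_stage("cluster", {
      m <- pooled_matrix(am, complete_cases = TRUE)
      up <- upgma_tree(m, k = params$kmeans_k)
      as_newick(up, file.path(outdir, "dendrogram.nwk"))
      artifacts <- c(artifacts, "dendrogram.nwk")
      km <- kmeans_clusters(m, k = params$kmeans_k, seed = params$seed,
                            rank_trait = params$yield_trait)
      emit(data.frame(genotype = names(km$assignments),
                      kmeans = as.integer(km$assignments),
                      upgma = as.integer(up$assignments[
                        names(km$assignments)])),
           "cluster_assignments.csv")
      cs <- cluster_summary(km, m)
      emit(data.frame(cluster = rownames(cs$cluster_means),
                      n = cs$sizes, round(cs$cluster_means, 2)),
           "cluster_means.csv")
    })
  }

  if (stages$selection && !is.null(am)) {
    run_stage("selection", {
      pm <- pooled_matrix(am)
      if (params$yield_trait %in% colnames(pm)) {
        rep_ <- percent_gain_over_best_check(
          stats::setNames(pm[, params$yield_trait], rownames(pm)),
          checks = am$checks)
        sel <- rank_and_select(rep_, params$min_gain)
        out <- rep_$ranked
        out$selected <- out$genotype %in% sel
        emit(out, "selection_gain.csv")
      }
      if (all(c(params$fe_trait, params$zn_trait) %in% colnames(pm))) {
        sc <- nutrient_screen(
          stats::setNames(pm[, params$fe_trait], rownames(pm)),
          stats::setNames(pm[, params$zn_trait], rownames(pm)),
          fe_min = params$fe_min, zn_min = params$zn_min)
        emit(data.frame(
          genotype = rownames(pm),
          Fe = pm[, params$fe_trait], Zn = pm[, params$zn_trait],
          pass_Fe = rownames(pm) %in% sc$pass_Fe,
          pass_Zn = rownames(pm) %in% sc$pass_Zn),
          "nutrient_screen.csv")
      }
    })
  }

  skipped <- names(stages)[!vapply(stages, isTRUE, logical(1))]
  manifest <- list(
    package = "augtrial",
    version = as.character(utils::packageVersion("augtrial")),
    r_version = as.character(getRversion()),
    params = params,
    stages_skipped = skipped,
    warnings = warnings_log,
    artifacts = artifacts,
    checksums = as.list(tools::md5sum(file.path(outdir, artifacts))))
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
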