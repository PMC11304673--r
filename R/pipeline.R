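#' Default pipeline configuration
#'
#' A pipeline run covers one or more (cohort dialect, sex) strata: synthetic
#' cohort generation, silhouette-based k selection and k-means fitting,
#' rule-based labeling, incidence/disease-count tables, nested-CV random
#' forest classification and TreeSHAP explanation, with all tables exported
#' as CSV and metrics as JSON. `profile = "quick"` is the reduced bundled
#' profile (small cohorts, 2 x 5-fold CV, single-point grid, 100 trees)
#' suitable for smoke runs; `profile = "emulation"` runs the full
#' study-emulation strata at their published sizes with the default
#' [cv_config()].
#'
#' @param strata list of lists with `cohort_dialect`, `sex` and optional
#'   `n`.
#' @param seed master seed.
#' @param profile `"quick"` or `"emulation"`.
#' @param k_range candidate cluster counts.
#' @param shap compute SHAP attributions per stratum.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(strata = list(list(cohort_dialect = "uk",
                                               sex = "female", n = 1000)),
                            seed = 1, profile = c("quick", "emulation"),
                            k_range = 2:8, shap = TRUE) {
  profile <- match.arg(profile)
  structure(list(strata = strata, seed = as.integer(seed),
                 profile = profile, k_range = k_range, shap = shap),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return the config (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("strata", "seed")) {
    if (is.null(raw[[field]]))
      abort("pipeline config %s: missing field '%s'", path, field)
  }
  pipeline_config(strata = raw$strata, seed = raw$seed,
                  profile = if (is.null(raw$profile)) "quick" else raw$profile,
                  k_range = if (is.null(raw$k_range)) 2:8
                            else raw$k_range[1]:raw$k_range[length(raw$k_range)],
                  shap = if (is.null(raw$shap)) TRUE else raw$shap)
}

#' Run the full pattern-discovery and classification pipeline
#'
#' Per stratum: generate the synthetic cohort, encode trajectories, select
#' the number of clusters by average silhouette, fit and label clusters,
#' export incidence / disease-count / cluster-profile tables, run the
#' leakage-controlled nested-CV random forest on the baseline covariates
#' with the discovered pattern labels as outcome, and (optionally) compute
#' TreeSHAP attributions with per-class global importance rankings. All
#' randomness derives from the config seed, so a rerun with the same config
#' reproduces every exported data file byte for byte. Stage timings and the
#' output inventory are written to `manifest.json` (atomically; timings are
#' wall-clock and excluded from reproducibility comparisons).
#'
#' @param config a [pipeline_config()], or a path to its YAML file.
#' @param out_dir output directory (created if needed).
#' @return the run manifest, invisibly: list with `config_hash`, `seed`,
#'   `stages` (per-stratum stage timings), `outputs` (relative paths),
#'   `warnings`, `version`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "pipeline_config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("cmctraj")),
                   stages = list(), outputs = character(0),
                   warnings = character(0))
  quick <- config$profile == "quick"
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)

  for (si in seq_along(config$strata)) {
    st <- config$strata[[si]]
    key <- paste(st$cohort_dialect, st$sex, sep = "_")
    sdir <- file.path(out_dir, key)
    dir.create(sdir, showWarnings = FALSE)
    sseed <- derive_seed(config$seed, 40L, si)
    emit <- function(obj, name) {
      p <- file.path(sdir, name)
      write.csv(obj, p, row.names = FALSE, na = "NA")
      manifest$outputs <<- c(manifest$outputs, file.path(key, name))
    }
    timed <- function(stage, expr) {
      t0 <- proc.time()[["elapsed"]]
      res <- withCallingHandlers(expr, warning = function(w) {
        note(paste0(key, "/", stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
      manifest$stages[[key]][[stage]] <<-
        round(proc.time()[["elapsed"]] - t0, 3)
      res
    }

    coh <- timed("simulate", {
      gcfg <- study_emulation_config(st$cohort_dialect, st$sex,
                                     n = st$n, seed = sseed)
      generate_cohort(gcfg)
    })
    emit(coh$covariates, "cohort.csv")
    emit(coh$trajectories, "trajectories.csv")
    emit(data.frame(participant_id = coh$trajectories$participant_id,
                    true_pattern = coh$labels), "true_labels.csv")

    pat <- timed("cluster", {
      cmc_patterns(coh$trajectories, k_range = config$k_range, seed = sseed,
                   n_init = if (quick) 5 else 10)
    })
    emit(pat$k_scores, "silhouette_by_k.csv")
    emit(profiles_to_table(pat), "cluster_profiles.csv")
    emit(do.call(rbind, lapply(seq_along(pat$profiles), function(i) {
      pt <- pat$profiles[[i]]$patterns
      cbind(cluster = pat$profiles[[i]]$cluster,
            label = unname(pat$cluster_labels[i]), head(pt, 5))
    })), "top_trajectories.csv")
    emit(data.frame(participant_id = coh$trajectories$participant_id,
                    cluster = pat$model$assignments,
                    pattern = pat$labels), "pattern_assignments.csv")

    timed("tables", {
      emit(incidence_table(coh$trajectories, pat$labels), "incidence_by_pattern.csv")
      emit(incidence_table(coh$trajectories), "incidence_overall.csv")
      emit(disease_count_summary(coh$trajectories), "disease_counts.csv")
    })

    cv <- timed("classify", {
      cvc <- if (quick)
        cv_config(outer_folds = 5, repeats = 2, inner_folds = 3,
                  seed = derive_seed(sseed, 41L),
                  grid = data.frame(num_trees = 100, max_depth = 0,
                                    min_node = 5))
      else cv_config(seed = derive_seed(sseed, 41L))
      covs <- coh$covariates[, setdiff(names(coh$covariates),
                                       c("participant_id", "sex",
                                         "follow_up_years")), drop = FALSE]
      run_nested_cv(covs, pat$labels, cvc, keep_models = config$shap)
    })
    emit(cv$metrics, "cv_metrics.csv")
    emit(cv$fold_metrics, "cv_fold_metrics.csv")
    mj <- file.path(sdir, "cv_metrics.json")
    jsonlite::write_json(
      setNames(as.list(cv$metrics$mean), cv$metrics$metric), mj,
      auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, file.path(key, "cv_metrics.json"))

    if (config$shap) {
      shap <- timed("explain", compute_shap_cv(cv))
      gi <- do.call(rbind, lapply(shap$classes, function(cl)
        cbind(class = cl, global_importance(shap, cl))))
      emit(gi, "shap_global_importance.csv")
      top <- head(global_importance(shap, shap$classes[1])$feature, 5)
      loc <- do.call(rbind, lapply(top, function(ft) {
        ds <- directionality_summary(shap, ft, shap$classes[1])
        data.frame(class = shap$classes[1], feature = ft,
                   sign_concordance = ds$sign_concordance)
      }))
      emit(loc, "shap_directionality.csv")
    }
  }

  mpath <- file.path(out_dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, mpath)
  invisible(manifest)
}

# internal: flatten cluster profiles for CSV export
profiles_to_table <- function(pat) {
  do.call(rbind, lapply(seq_along(pat$profiles), function(i) {
    p <- pat$profiles[[i]]
    data.frame(cluster = p$cluster, label = unname(pat$cluster_labels[i]), n = p$n,
               none_fraction = p$none_fraction,
               disease = cmd_codes(),
               incidence_pct = unname(p$incidence_pct),
               time_mean = unname(p$time_mean),
               time_sd = unname(p$time_sd),
               first_frac = as.numeric(p$first_freq[cmd_codes()]) / p$n,
               stringsAsFactors = FALSE)
  }))
}
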