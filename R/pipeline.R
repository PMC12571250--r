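# End-to-end pipeline orchestration: generate scenes, simulate gaze, sample
# sRFs, run the figure-ground statistics and the population model, and write
# tidy CSV/JSON outputs.

#' Pipeline run configuration
#'
#' Every stochastic stage carries an explicit seed derived from
#' `master_seed`, so a run is reproducible from the config alone.  The
#' config round-trips through YAML.
#'
#' @param params generator parameters ([scene_gen_params()]).
#' @param n_scenes scenes to generate.
#' @param n_per_size accepted sRFs per diameter.
#' @param sizes sRF diameters in degrees.
#' @param pursuit_enabled simulate smooth pursuit?
#' @param n_boot bootstrap replicates for ratio-curve CIs.
#' @param master_seed master RNG seed.
#' @param out_dir output directory (NULL = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(params = scene_gen_params(), n_scenes = 60L,
                       n_per_size = 200L, sizes = c(2.5, 5, 10, 15),
                       pursuit_enabled = TRUE, n_boot = 1000L,
                       master_seed = 1L, out_dir = NULL) {
  set.seed(master_seed)
  seeds <- as.list(sample.int(.Machine$integer.max, 3L))
  names(seeds) <- c("scenes", "srf", "boot")
  structure(
    list(params = params, n_scenes = as.integer(n_scenes),
         n_per_size = as.integer(n_per_size), sizes = sizes,
         pursuit_enabled = pursuit_enabled, n_boot = as.integer(n_boot),
         master_seed = as.integer(master_seed), seeds = seeds,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config(params = do.call(scene_gen_params, x$params),
                    n_scenes = x$n_scenes, n_per_size = x$n_per_size,
                    sizes = unlist(x$sizes),
                    pursuit_enabled = x$pursuit_enabled,
                    n_boot = x$n_boot, master_seed = x$master_seed,
                    out_dir = x$out_dir)
  cfg
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full figure-ground statistics pipeline
#'
#' Stages: scene generation, sRF sampling with gaze simulation, per-sRF
#' region summaries, figure-ground tests (one-sample t with Cohen's D,
#' one-way ANOVA over eccentricity with eta^2 and Tukey HSD pairs,
#' proportions with binomial CIs), probability-ratio curves, global
#' per-class distributions, and the bi-speed population-model experiment.
#' When `config$out_dir` is set, tidy CSV tables and a JSON run summary
#' are written there.
#'
#' @param config a [run_config()].
#' @param dataset optionally, a pre-generated `scene_dataset` to reuse
#'   (the scene-generation stage is then skipped).
#' @return list with `config`, `dataset`, `srf_set`, `summaries`,
#'   `tests`, `proportions`, `ratio_curves`, `global`, `population`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    dataset <- stage("generate", generate_dataset(
      config$n_scenes, config$params, config$seeds$scenes))
  }
  srf_set <- stage("sample", build_srf_set(
    dataset, n_per_size = config$n_per_size, sizes = config$sizes,
    seed = config$seeds$srf, pursuit_enabled = config$pursuit_enabled))
  features <- stage("features", srf_features(srf_set, dataset))
  summaries <- stage("summaries",
                     summarize_srf_set(srf_set, dataset,
                                       features = features))

  tests <- stage("tests", {
    ecc <- factor(summaries$diameter)
    list(
      delta_s = one_sample_t(summaries$delta_s),
      delta_v = one_sample_t(summaries$delta_v),
      delta_d = one_sample_t(summaries$delta_d),
      anova_s = anova_eta(summaries$delta_s, ecc),
      anova_v = anova_eta(summaries$delta_v, ecc),
      anova_d = anova_eta(summaries$delta_d, ecc),
      tukey_s = tukey_pairs(summaries$delta_s, ecc),
      tukey_v = tukey_pairs(summaries$delta_v, ecc),
      tukey_d = tukey_pairs(summaries$delta_d, ecc)
    )
  })
  proportions <- fg_proportions(summaries)

  ratio_curves <- stage("ratios", {
    feats <- c("rel_speed", "rel_direction", "disparity")
    stats::setNames(lapply(feats, function(f) {
      ratio_curve(srf_set, dataset, f, n_boot = config$n_boot,
                  seed = config$seeds$boot, features = features)
    }), feats)
  })

  global <- stage("global", global_distributions(dataset))

  population <- stage("popmodel", {
    pop <- build_population()
    run_bispeed_experiment(pop, seed = config$seeds$boot)
  })

  res <- list(config = config, dataset = dataset, srf_set = srf_set,
              summaries = summaries, tests = tests,
              proportions = proportions, ratio_curves = ratio_curves,
              global = global, population = population)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

test_row <- function(name, t) {
  data.frame(test = name, statistic = t$statistic,
             p_value = t$p_value, effect_size = t$effect_size)
}

#' Write pipeline outputs as CSV/JSON
#'
#' @param res result of [run_pipeline()].
#' @param out_dir directory to write into.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(out_dir, f), row.names = FALSE)
  wcsv(res$srf_set$table, "srf_table.csv")
  wcsv(res$summaries, "srf_summaries.csv")
  wcsv(res$proportions, "fg_proportions.csv")
  wcsv(do.call(rbind, lapply(names(res$tests)[1:6], function(n)
    test_row(n, res$tests[[n]]))), "fg_tests.csv")
  for (n in c("tukey_s", "tukey_v", "tukey_d")) {
    wcsv(res$tests[[n]], paste0(n, ".csv"))
  }
  for (f in names(res$ratio_curves)) {
    wcsv(res$ratio_curves[[f]], paste0("ratio_", f, ".csv"))
  }
  wcsv(res$population, "population_decoding.csv")
  summary_json <- list(
    master_seed = res$config$master_seed,
    seeds = res$config$seeds,
    n_scenes = res$config$n_scenes,
    n_srfs = length(res$srf_set$samples),
    pursuit_enabled = res$config$pursuit_enabled,
    reject_counts = as.list(res$srf_set$reject_counts),
    mean_delta_s = mean(res$summaries$delta_s, na.rm = TRUE),
    mean_delta_v = mean(res$summaries$delta_v, na.rm = TRUE),
    mean_delta_d = mean(res$summaries$delta_d, na.rm = TRUE),
    global_medians = lapply(res$global, function(g) as.list(g$medians)),
    r_version = R.version.string
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
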