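#' Read a run configuration
#'
#' YAML (or JSON) run configuration with defaults: `ci_level` 0.90,
#' `certainty_threshold` 0.80, `S` 1000, `model_form` "model1", and the
#' standard composite weights. `seed` is mandatory. Either `simulate:`
#' (with `J`, `counties_per_state`, optional `censor`, optional generator
#' overrides under `params`) or `in_dir:` (a directory of universe CSVs)
#' must be given, plus `out_dir`.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list with the fields above.
#' @export
as_run_config <- function(config) {
  defaults <- list(S = 1000, model_form = "model1", ci_level = 0.90,
                   certainty_threshold = 0.80,
                   weights = measure_config(), run_ppc = TRUE)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) abort("run config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$model_form %in% c("model1", "model2", "both"))
    abort("model_form must be model1, model2, or both")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    abort("ci_level must be in (0, 1)")
  if (cfg$certainty_threshold <= 0 || cfg$certainty_threshold >= 1)
    abort("certainty_threshold must be in (0, 1)")
  if (is.data.frame(cfg$weights)) {
    validate_measure_config(cfg$weights)
  } else {
    w <- unlist(cfg$weights)
    cfg$weights <- measure_config() %>%
      mutate(weight = unname(w[.data$measure]))
    validate_measure_config(cfg$weights)
  }
  if (is.null(cfg$in_dir) && is.null(cfg$simulate))
    abort("config needs either simulate: or in_dir:")
  if (is.null(cfg$out_dir)) abort("config must set out_dir")
  structure(cfg, class = "run_config")
}

#' Run the full ranking pipeline
#'
#' Orchestrates simulate (or read) -> fit -> posterior samples -> composite
#' ranks -> posterior predictive checks, writing every stage artifact as a
#' plain file under `out_dir`: the universe CSVs (and truth CSVs when
#' simulating), per-measure fit summaries (`fits_<model>.json`), the rank
#' table (`ranks_<model>.csv`), PPC results (`ppc_<model>.csv`), a model
#' comparison (`comparison.csv`, when `model_form: both`), and
#' `manifest.json` carrying the config hash, derived stage seeds, package
#' version, and the artifact list. Rerunning with the same config
#' reproduces the rank tables bit-identically. A stage failure aborts with
#' the stage name; artifacts written before the failure persist.
#'
#' @param config A config list/`run_config` or a path to a YAML file.
#' @return Invisibly, a list with the output directory, per-model rank
#'   summaries, PPC tables, the comparison (if any), and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- as_run_config(unclass(config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg[sort(names(cfg))])
  artifacts <- character()
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    inform(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  cat("", file = log_path)  # truncate
  logline("run config hash ", cfg_hash, " (seed ", cfg$seed, ")")

  truth <- NULL
  universe <- stage("universe", {
    if (!is.null(cfg$in_dir)) {
      logline("reading universe from ", cfg$in_dir)
      read_universe(cfg$in_dir)
    } else {
      sim <- cfg$simulate
      params <- do.call(sim_params, c(
        list(model_form = if (cfg$model_form == "model2") "model2"
             else sim$truth_model %||% "model1"),
        sim$params %||% list()))
      logline("simulating universe: J = ", sim$J, ", counties/state = ",
              paste(sim$counties_per_state, collapse = "-"))
      out <- simulate_universe(sim$J, sim$counties_per_state, params,
                               seed = cfg$seed)
      u <- out$universe
      if (isTRUE(sim$censor %||% TRUE)) u <- apply_censoring(u)
      truth <<- out$truth
      udir <- file.path(cfg$out_dir, "universe")
      artifacts <<- c(artifacts, write_universe(u, udir))
      artifacts <<- c(artifacts, write_truth(out$truth, udir))
      u
    }
  })

  forms <- if (cfg$model_form == "both") c("model1", "model2") else
    cfg$model_form
  summaries <- list()
  ppcs <- list()
  for (form in forms) {
    fits <- stage(paste0("fit (", form, ")"), {
      logline("fitting 5 measures under ", form)
      fit_all_measures(universe, form)
    })
    fit_path <- file.path(cfg$out_dir, paste0("fits_", form, ".json"))
    jsonlite::write_json(
      map(fits, ~ list(measure = .x$measure, family = .x$family,
                       model_form = .x$model_form,
                       beta = .x$beta, sigma_state_hat = .x$sigma_state_hat,
                       sigma_county_hat = .x$sigma_county_hat,
                       loglik = .x$loglik, converged = .x$converged,
                       n_obs = .x$n_obs, config_hash = cfg_hash)),
      fit_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    artifacts <- c(artifacts, fit_path)

    seed_base <- cfg$seed + 1000L * match(form, c("model1", "model2"))
    smp <- stage(paste0("sample (", form, ")"), {
      logline("drawing S = ", cfg$S, " posterior samples per measure")
      imap(fits, function(f, ms)
        posterior_measure_samples(f, universe, S = cfg$S,
                                  seed = seed_base + match(ms, MEASURE_NAMES)))
    })
    summ <- stage(paste0("rank (", form, ")"), {
      scores <- composite_scores(smp, cfg$weights)
      summarize_ranks(rank_samples(scores), level = cfg$ci_level,
                      certainty_threshold = cfg$certainty_threshold)
    })
    rank_path <- file.path(cfg$out_dir, paste0("ranks_", form, ".csv"))
    readr::write_csv(
      universe$geography %>%
        select("state_label", "county_label", "county_id") %>%
        left_join(summ, by = "county_id"),
      rank_path)
    artifacts <- c(artifacts, rank_path)
    summaries[[form]] <- summ

    if (isTRUE(cfg$run_ppc)) {
      ppc_tbl <- stage(paste0("ppc (", form, ")"), {
        logline("posterior predictive checks (", form, ")")
        bind_rows(imap(fits, function(f, ms) {
          s <- if (ms == "premature_mortality") {
            draw_samples(eb_condition(f, universe), cfg$S,
                         seed_base + match(ms, MEASURE_NAMES))
          } else smp[[ms]]
          ppc_check(s, universe, seed = seed_base + 100L +
                      match(ms, MEASURE_NAMES))
        }))
      })
      ppc_path <- file.path(cfg$out_dir, paste0("ppc_", form, ".csv"))
      readr::write_csv(ppc_tbl, ppc_path)
      artifacts <- c(artifacts, ppc_path)
      ppcs[[form]] <- ppc_tbl
    }
  }

  comparison <- NULL
  if (length(forms) == 2) {
    comparison <- compare_models(summaries$model1, summaries$model2)
    cmp_path <- file.path(cfg$out_dir, "comparison.csv")
    readr::write_csv(comparison, cmp_path)
    artifacts <- c(artifacts, cmp_path)
    logline(sprintf("model2 - model1 mean CI width: %+.2f percentile ranks",
                    attr(comparison, "delta_mean_ci_width_percentile")))
  }

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed, S = cfg$S,
                   model_form = cfg$model_form,
                   package_version =
                     as.character(utils::packageVersion("countyrank")),
                   artifacts = basename(unname(artifacts)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("done; ", length(artifacts), " artifacts in ", cfg$out_dir)
  invisible(list(out_dir = cfg$out_dir, universe = universe, truth = truth,
                 summaries = summaries, ppc = ppcs,
                 comparison = comparison, manifest = manifest))
}
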