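# End-to-end orchestration: simulate/ingest -> validate -> networks ->
# versatility -> model table -> fit -> trends, with a manifest recording
# the configuration hash and seed so reruns are reproducible.

#' Pipeline configuration
#'
#' @param paths named list of input CSV paths (`focals`, `demography`,
#'   `bouts`); `NULL` to simulate inputs instead.
#' @param sim a [sim_config()] used when `paths` is `NULL`.
#' @param scheme a [partition_scheme()].
#' @param damping,interlayer_weight,coupling versatility parameters (see
#'   [build_supra_transition()]).
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param out_dir artifact directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, sim = sim_config(),
                            scheme = partition_scheme(), damping = 0.85,
                            interlayer_weight = 1,
                            coupling = "categorical",
                            spec = model_spec(), mcmc = mcmc_config(),
                            out_dir = "multiego-artifacts") {
  structure(list(paths = paths, sim = sim, scheme = scheme,
                 damping = damping, interlayer_weight = interlayer_weight,
                 coupling = coupling, spec = spec, mcmc = mcmc,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `paths`, `sim`, `partitions`, `versatility`
#' (`damping`, `interlayer_weight`, `coupling`), `model` (`hurdle`,
#' `predictors`), `mcmc` (`chains`, `iterations`, `warmup`, `thin`,
#' `seed`), `out_dir`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("paths", "sim", "partitions", "versatility", "model", "mcmc",
             "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- pipeline_config()
  if (!is.null(y$paths)) cfg$paths <- y$paths
  if (!is.null(y$sim)) cfg$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$partitions)) {
    cfg$scheme <- partition_scheme(lapply(y$partitions, function(b)
      seq(b[[1]], b[[2]])))
  }
  if (!is.null(y$versatility)) {
    v <- y$versatility
    if (!is.null(v$damping)) cfg$damping <- v$damping
    if (!is.null(v$interlayer_weight)) cfg$interlayer_weight <-
        v$interlayer_weight
    if (!is.null(v$coupling)) cfg$coupling <- v$coupling
  }
  if (!is.null(y$model)) cfg$spec <- do.call(model_spec, y$model)
  if (!is.null(y$mcmc)) cfg$mcmc <- do.call(mcmc_config, y$mcmc)
  if (!is.null(y$out_dir)) cfg$out_dir <- y$out_dir
  cfg
}

#' Run the full pipeline
#'
#' Stages: (1) simulate or read the observation tables, (2) validation
#' report, (3) monthly ego networks assembled into multilayer networks,
#' (4) normalized + zero-populated versatility, (5) yearly ranks and the
#' scaled model table, (6) multivariate model fit with fixed-effect,
#' cross-correlation and Bayes R2 reports, (7) monthly trend aggregates.
#' Every stage writes a CSV artifact under `config$out_dir`, plus a
#' `manifest.json` with the config hash and seed. A stage failure aborts
#' with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param seed integer seed controlling simulation and fitting.
#' @return invisible list of in-memory stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  db <- stage("ingest", {
    if (is.null(config$paths)) {
      simulate_observations(config$sim, seed = seed,
                            scheme = config$scheme)$db
    } else {
      observation_db(read_focals(config$paths$focals),
                     read_demography(config$paths$demography),
                     read_bouts(config$paths$bouts))
    }
  })

  report <- stage("validate", validate_db(db))
  utils::write.csv(report$session_counts,
                   file.path(config$out_dir, "session_counts.csv"),
                   row.names = FALSE)
  if (nrow(report$violations)) {
    stop(sprintf("pipeline stage 'validate' failed: %d referential violation(s)",
                 nrow(report$violations)), call. = FALSE)
  }

  nets <- stage("build-networks", build_ego_networks(db, config$scheme,
                                                     config$sim$max_alter_age))
  n_egos <- length(focal_subjects(db$demography))
  n_parts <- length(config$scheme$partitions)
  potential <- n_egos * length(BEHAVIOURS) * n_parts
  message(sprintf("networks: %d realized of %d potential (%d egos x %d behaviours x %d partitions)",
                  length(nets), potential, n_egos, length(BEHAVIOURS),
                  n_parts))
  utils::write.csv(networks_edge_list(nets),
                   file.path(config$out_dir, "networks.csv"),
                   row.names = FALSE)

  vers <- stage("versatility", {
    vt <- versatility_table(nets, damping = config$damping,
                            interlayer_weight = config$interlayer_weight,
                            coupling = config$coupling)
    zero_populate(vt, db$demography, config$scheme)
  })
  utils::write.csv(vers, file.path(config$out_dir, "versatility.csv"),
                   row.names = FALSE)

  assembled <- stage("assemble", {
    years <- sort(unique(as.integer(format(db$bouts$date, "%Y"))))
    ranks <- do.call(rbind, lapply(years, function(yr)
      estimate_ranks(db$bouts, yr, db$demography)))
    tab <- assemble_model_table(vers, db$demography, ranks, config$scheme)
    sc <- scale_predictors(tab)
    list(ranks = ranks, table = sc$table, scaling = sc$scaling)
  })
  utils::write.csv(assembled$table,
                   file.path(config$out_dir, "model_table.csv"),
                   row.names = FALSE)

  fit <- stage("fit", {
    fit_social_model(assembled$table, config$spec,
                     mcmc_config(config$mcmc$chains, config$mcmc$iterations,
                                 config$mcmc$warmup, config$mcmc$thin,
                                 seed = seed))
  })
  utils::write.csv(fixed_effect_report(fit),
                   file.path(config$out_dir, "fixed_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(re_cross_correlations(fit, "ego"),
                         re_cross_correlations(fit, "alter")),
                   file.path(config$out_dir, "re_cross_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(bayes_r2(fit, "conditional"),
                         bayes_r2(fit, "marginal")),
                   file.path(config$out_dir, "bayes_r2.csv"),
                   row.names = FALSE)

  trends <- stage("trends", monthly_aggregates(db))
  utils::write.csv(trends, file.path(config$out_dir, "trends.csv"),
                   row.names = FALSE)

  manifest <- list(seed = seed,
                   config_hash = config_hash(config),
                   n_egos = n_egos,
                   potential_networks = potential,
                   realized_networks = length(nets),
                   model_rows = nrow(assembled$table),
                   postwarmup_draws = n_postwarmup_draws(config$mcmc))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(db = db, report = report, networks = nets, vers = vers,
                 ranks = assembled$ranks, table = assembled$table,
                 fit = fit, trends = trends, manifest = manifest))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the deparsed configuration; changes iff the configuration
#' changes.
#' @param config a `pipeline_config`.
#' @return character hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}
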