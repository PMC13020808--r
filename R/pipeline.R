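# End-to-end orchestration: generate -> simulate -> score -> fit ->
# report, with a serializable config and a run manifest.

#' The five standard analysis formulas
#'
#' Named list of the model formulas fitted by [run_pipeline()]:
#' self-relevance x criterion on relative allocation; the same with
#' standardized SVO; performance weighting (relative performance
#' crossed with self-relevance and with criterion); contribution
#' structure on the (rescaled) self-allocation bias; and contribution
#' crossed with SVO on the bias.
#'
#' @return named list of formulas.
#' @export
analysis_formulas <- function() {
  list(
    self_relevance = relative_allocation ~ self_relevance * criterion +
      (1 | participant_id),
    svo = relative_allocation ~ self_relevance * criterion * svo_z +
      (1 | participant_id),
    performance = relative_allocation ~
      relative_performance * self_relevance +
      relative_performance * criterion + (1 | participant_id),
    contribution = bias01 ~ contribution_category + (1 | participant_id),
    contribution_svo = bias01 ~ contribution_category * svo_z +
      (1 | participant_id)
  )
}

#' Configuration of a pipeline run
#'
#' @param experiment layout name (`"exp1"`, `"exp2"`, `"exp3"`).
#' @param n_participants cohort size.
#' @param population an [agent_population()].
#' @param perf a [perf_config()].
#' @param engine estimation engine for the fits.
#' @param ndraws posterior draws per fit.
#' @param models names of [analysis_formulas()] entries to fit.
#' @param seed integer seed.
#' @export
pipeline_config <- function(experiment = "exp2", n_participants = 20,
                            population = agent_population(),
                            perf = perf_config(), engine = "laplace",
                            ndraws = 500,
                            models = names(analysis_formulas()),
                            seed = 1L) {
  cfg <- list(experiment = experiment, n_participants = n_participants,
              population = population, perf = perf, engine = engine,
              ndraws = ndraws, models = models, seed = seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  known <- c("experiment", "n_participants", "population", "perf",
             "engine", "ndraws", "models", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(known, names(config))
  if (length(missing)) {
    stop("config lacks key(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(config$experiment %in% c("exp1", "exp2", "exp3"),
            config$n_participants >= 2,
            inherits(config$population, "agent_population"),
            config$engine %in% c("laplace", "mcmc"))
  bad <- setdiff(config$models, names(analysis_formulas()))
  if (length(bad)) stop("unknown model name(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — stimulus generation, cohort
#' simulation, metric scoring, model fitting, contrast reporting —
#' writing CSV tables after each stage so partial failures leave prior
#' outputs intact, and finishing with a JSON run manifest (config,
#' seeds, package version, table checksums). Re-running with the same
#' config and seed reproduces the tables bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the cohort, fits, contrast tables
#'   and the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), out = "allocbias-run",
                         seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  layout <- experiment_layout(config$experiment)

  cohort <- simulate_cohort(config$n_participants, config$population,
                            layout, config$perf, seed = config$seed)
  write_trials(cohort$trials, file.path(out, "trials.csv"))
  utils::write.csv(cohort$records, file.path(out, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$agents, file.path(out, "agents.csv"),
                   row.names = FALSE)

  tab <- analysis_table(cohort)
  btab <- bias_table(cohort)
  utils::write.csv(tab, file.path(out, "analysis_table.csv"),
                   row.names = FALSE)
  utils::write.csv(btab, file.path(out, "bias_table.csv"),
                   row.names = FALSE)

  fits <- list()
  reports <- list()
  for (m in config$models) {
    f <- analysis_formulas()[[m]]
    dat <- if (m %in% c("contribution", "contribution_svo")) btab else tab
    fit <- zoib(f, dat, engine = config$engine, ndraws = config$ndraws,
                seed = config$seed)
    fits[[m]] <- fit
    co <- summary(fit)$coefficients
    utils::write.csv(co, file.path(out, paste0("fit_", m, "_coefficients.csv")),
                     row.names = FALSE)
    emm <- switch(m,
      self_relevance = marginal_means(fit, ~ self_relevance * criterion,
                                      reverse = TRUE),
      svo = marginal_slopes(fit, "svo_z", ~ self_relevance),
      performance = marginal_slopes(fit, "relative_performance",
                                    ~ self_relevance),
      contribution = marginal_means(fit, ~ contribution_category),
      contribution_svo = marginal_slopes(fit, "svo_z",
                                         ~ contribution_category))
    reports[[m]] <- emm
    part <- if (inherits(emm, "zoib_emm")) emm$contrasts else emm$differences
    utils::write.csv(part, file.path(out, paste0("contrasts_", m, ".csv")),
                     row.names = FALSE)
  }

  tables <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package = "allocbias",
    version = as.character(utils::packageVersion("allocbias")),
    seed = config$seed,
    config = config[c("experiment", "n_participants", "engine", "ndraws",
                      "models")],
    population = unclass(config$population),
    perf = config$perf,
    checksums = as.list(tools::md5sum(tables))
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, fits = fits, reports = reports,
                 manifest = manifest_path, out = out))
}

#' Generate the small packaged fixture datasets
#'
#' Writes a symmetric exp2 stimulus list, a 6-participant cohort with
#' its ground-truth agent table, and an SVO response fixture to `dir`,
#' regenerating identically from the pinned seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(seed = 20260101L, dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- experiment_layout("exp2")
  stim <- generate_stimulus_list(layout, seed = seed)
  cohort <- simulate_cohort(6, agent_population(), layout, seed = seed)
  svo <- data.frame(participant_id = sprintf("P%03d", 1:6),
                    t(vapply(1:6, function(i) local_seed(seed + i,
                      sample(1:9, 6, replace = TRUE)), numeric(6))))
  names(svo)[-1] <- paste0("item", 1:6)
  paths <- c(
    trials = file.path(dir, "mini_trials.csv"),
    records = file.path(dir, "mini_cohort.csv"),
    agents = file.path(dir, "mini_agents.csv"),
    svo = file.path(dir, "mini_svo.csv")
  )
  write_trials(stim, paths["trials"])
  utils::write.csv(cohort$records, paths["records"], row.names = FALSE)
  utils::write.csv(cohort$agents, paths["agents"], row.names = FALSE)
  utils::write.csv(svo, paths["svo"], row.names = FALSE)
  invisible(paths)
}
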