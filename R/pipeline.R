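# End-to-end orchestration: simulate -> impute -> estimate -> model ->
# economics, with a YAML-configurable run and reproducible manifests.

#' Default pipeline configuration
#'
#' One nested list drives the whole run: cohort and generating parameters,
#' imputation settings, estimation options, decision-model settings, PSA
#' size, scenario list and one-way analyses. All stage seeds derive from
#' the single master `seed`.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1234L,
    cohort = list(n_per_arm = 398, n_cycles = 10),
    imputation = list(M = 100, donor_pool_k = 5),
    estimation = list(corstr = "independence", prune = TRUE, alpha = 0.05),
    model = list(discount_rate = 0.035, discount_from = "start",
                 intervention_cost = c(FT = 1745, TAU = 250),
                 wtp_threshold = 30000),
    psa = list(n_sims = 10000, horizon = "60m"),
    wtp = list(max = 50000, step = 500),
    scenarios = c("base", "any_hosp", "nice"),
    one_way = c("no_mortality", "discount_0", "discount_6",
                "no_post_trial_nonhosp")
  )
  over <- list(...)
  validate_config(merge_config(cfg, over))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  known <- c("seed", "cohort", "imputation", "estimation", "model", "psa",
             "wtp", "scenarios", "one_way")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop(sprintf("unknown config entries: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  assert_count(cfg$cohort$n_per_arm, "cohort.n_per_arm")
  assert_count(cfg$cohort$n_cycles, "cohort.n_cycles")
  assert_count(cfg$imputation$M, "imputation.M", min = 2L)
  assert_count(cfg$psa$n_sims, "psa.n_sims")
  bad <- setdiff(cfg$scenarios, c("base", "any_hosp", "nice"))
  if (length(bad)) {
    stop(sprintf("unknown scenarios: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(cfg$one_way, c("no_mortality", "discount_0", "discount_6",
                                "no_post_trial_nonhosp"))
  if (length(bad)) {
    stop(sprintf("unknown one-way analyses: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [default_config()]; unknown keys are an error, missing keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$model$intervention_cost)) {
    raw$model$intervention_cost <- unlist(raw$model$intervention_cost)
  }
  do.call(default_config, raw)
}

scenario_model_config <- function(cfg, scenario, one_way = NULL) {
  mc <- cfg$model
  args <- list(
    rsh_definition = if (identical(scenario, "any_hosp")) "any" else "sh",
    horizon_cycles = cfg$cohort$n_cycles,
    discount_rate = mc$discount_rate,
    discount_from = mc$discount_from,
    intervention_cost = mc$intervention_cost,
    wtp = seq(0, cfg$wtp$max, by = cfg$wtp$step),
    wtp_threshold = mc$wtp_threshold,
    value_source = if (identical(scenario, "nice")) "nice" else "empirical"
  )
  if (!is.null(one_way)) {
    args <- switch(one_way,
      no_mortality = c(args[names(args) != "include_mortality"],
                       list(include_mortality = FALSE)),
      discount_0 = { args$discount_rate <- 0; args },
      discount_6 = { args$discount_rate <- 0.06; args },
      no_post_trial_nonhosp = c(args, list(include_post_trial_nonhosp = FALSE))
    )
  }
  do.call(model_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the trial data, multiply imputes, fits and pools
#' the GEE suite, runs the quasi-Markov engine for every configured
#' scenario and one-way analysis, and runs the probabilistic sensitivity
#' analysis on the base case (and, if configured, the NICE scenario). The
#' run is deterministic given the configuration: identical configs yield
#' identical results and manifests.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param data Optional pre-built `trial_data` (skips simulation; e.g. from
#'   [read_trial_data()]).
#' @param params Optional [trajectory_params()] override for simulation.
#' @param out_dir Optional output directory: writes `results.json`,
#'   `econ_summary.csv`, `cycle_ledger.csv`, `ceac.csv`, `psa_draws.csv`
#'   and `manifest.json`.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `pipeline_result`: `data`, `suites`, `econ`
#'   (per scenario/one-way summary tibble), `markov` (per scenario
#'   `markov_result`), `psa`, `ceac`, `ce_plane`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), data = NULL,
                         params = NULL, out_dir = NULL, verbose = TRUE) {
  config <- validate_config(unclass(config))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- sub_seeds(config$seed, 4L)

  params <- params %||% shift_params(n_cycles = config$cohort$n_cycles)
  if (is.null(data)) {
    say("stage simulate: %d patients/arm, %d cycles",
        config$cohort$n_per_arm, config$cohort$n_cycles)
    spec <- cohort_spec(n_per_arm = config$cohort$n_per_arm,
                        n_cycles = config$cohort$n_cycles, seed = seeds[1])
    roster <- generate_cohort(spec)
    complete <- generate_trajectories(roster, params, seed = seeds[2])
    data <- apply_missingness(complete, params, seed = seeds[2] + 1L)
  }

  say("stage impute: M = %d", config$imputation$M)
  imps <- tryCatch(
    multiple_impute(data, imputation_spec(M = config$imputation$M,
                                          donor_pool_k = config$imputation$donor_pool_k,
                                          seed = seeds[3])),
    error = function(e) stop("stage impute failed: ", conditionMessage(e),
                             call. = FALSE)
  )

  say("stage estimate: GEE suite (%s)", config$estimation$corstr)
  need_any <- "any_hosp" %in% config$scenarios
  suites <- tryCatch({
    s <- list(sh = fit_suite_mi(imps, rsh_definition = "sh",
                                corstr = config$estimation$corstr,
                                prune = config$estimation$prune,
                                alpha = config$estimation$alpha))
    if (need_any) {
      s$any <- fit_suite_mi(imps, rsh_definition = "any",
                            corstr = config$estimation$corstr,
                            prune = config$estimation$prune,
                            alpha = config$estimation$alpha)
    }
    s
  }, error = function(e) stop("stage estimate failed: ", conditionMessage(e),
                              call. = FALSE))

  say("stage model: scenarios %s", paste(config$scenarios, collapse = ", "))
  markov <- list()
  econ <- list()
  for (sc in config$scenarios) {
    suite <- if (sc == "any_hosp") suites$any else suites$sh
    mc <- scenario_model_config(config, sc)
    res <- run_markov(suite, mc)
    markov[[sc]] <- res
    econ[[length(econ) + 1]] <- dplyr::mutate(res$result, scenario = sc,
                                              analysis = "deterministic",
                                              .before = 1)
    if (sc == "base") {
      for (ow in config$one_way) {
        mc_ow <- scenario_model_config(config, sc, one_way = ow)
        res_ow <- run_markov(suite, mc_ow)
        econ[[length(econ) + 1]] <- dplyr::mutate(res_ow$result, scenario = sc,
                                                  analysis = ow, .before = 1)
      }
    }
  }
  econ_tbl <- if (length(econ)) dplyr::bind_rows(econ) else
    econ_result(tibble::tibble(arm = character(), horizon = character(),
                               cost = numeric(), qaly = numeric()))

  psa_draws_tbl <- NULL
  ceac_tbl <- NULL
  plane <- NULL
  if ("base" %in% config$scenarios && config$psa$n_sims > 0) {
    say("stage psa: %d simulations", config$psa$n_sims)
    mc <- scenario_model_config(config, "base")
    psa_draws_tbl <- psa_run(suites$sh, mc, n_sims = config$psa$n_sims,
                             seed = seeds[4], horizon = config$psa$horizon)
    ceac_tbl <- ceac(psa_draws_tbl, wtp = seq(0, config$wtp$max,
                                              by = config$wtp$step))
    plane <- ce_plane(psa_draws_tbl)
  }

  manifest <- list(
    package = "qmcea",
    version = as.character(utils::packageVersion("qmcea")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stage_seeds = as.integer(seeds),
    n_patients = nrow(data$patients),
    n_records = nrow(data$cycles),
    scenarios = config$scenarios
  )

  result <- structure(
    list(data = data, suites = suites, econ = econ_tbl, markov = markov,
         psa = psa_draws_tbl, ceac = ceac_tbl, ce_plane = plane,
         manifest = manifest, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(report_results(x)$cost_effectiveness, n = Inf)
  invisible(x)
}

write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- report_results(result)
  readr::write_csv(rep$cost_effectiveness,
                   file.path(out_dir, "econ_summary.csv"), na = "")
  ledger <- dplyr::bind_rows(lapply(names(result$markov), function(sc) {
    m <- result$markov[[sc]]
    dplyr::mutate(dplyr::left_join(m$occupancy, m$payoffs,
                                   by = c("arm", "cycle")),
                  scenario = sc, .before = 1)
  }))
  readr::write_csv(ledger, file.path(out_dir, "cycle_ledger.csv"), na = "")
  if (!is.null(result$ceac)) {
    readr::write_csv(result$ceac, file.path(out_dir, "ceac.csv"), na = "")
    readr::write_csv(result$psa, file.path(out_dir, "psa_draws.csv"), na = "")
  }
  jsonlite::write_json(
    list(econ = result$econ,
         quadrants = if (!is.null(result$ce_plane)) result$ce_plane$quadrants,
         manifest = result$manifest),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable result tables
#'
#' Renders the pipeline bundle as publication-style tables: the
#' cost-effectiveness summary per scenario and horizon (ICER column showing
#' "Dominated"/"Dominant" or the ratio), the per-cycle conditional-cost
#' grid, and the state-occupancy grid.
#'
#' @param result A `pipeline_result`.
#' @return A named list of tibbles: `cost_effectiveness`,
#'   `conditional_costs`, `occupancy`.
#' @export
report_results <- function(result) {
  econ <- result$econ
  ce <- if (nrow(econ)) {
    dplyr::mutate(
      econ,
      icer_display = dplyr::case_when(
        icer_label == "dominated" ~ "Dominated",
        icer_label == "dominant" ~ "Dominant",
        icer_label == "undefined" ~ "Undefined",
        TRUE ~ sprintf("£%s/QALY", format(round(icer), big.mark = ","))
      )
    )
  } else {
    dplyr::mutate(econ, icer_display = character(0))
  }
  cond <- NULL
  occ <- NULL
  if (length(result$markov)) {
    base <- result$markov[[1]]
    cond <- dplyr::select(base$predictions, "arm", "cycle", "p_sh", "p_any",
                          "cost_sh", "cost_nonsh",
                          "cost_nonhosp_given_ev", "cost_nonhosp_given_noev")
    occ <- base$occupancy
  }
  list(cost_effectiveness = ce, conditional_costs = cond, occupancy = occ)
}
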