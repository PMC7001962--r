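#' Experiment configuration
#'
#' Full-factorial design: every site is run under every scenario. Two soil
#' profiles are carried, one for the event-probability indices (default
#' 180 mm AWC) and one for the crop stress model (default the 177 mm
#' "hafren" profile). Per-cell seeds are derived from the master seed by a
#' documented splitting rule, so cells are independent and reproducible in
#' any execution order.
#'
#' @param sites named list of [site_climatology()] objects.
#' @param scenarios list of `list(id = <label>, cf = <change_factor_set or
#'   NULL for baseline>)`; see [scenario_list()].
#' @param n_years generated years per cell (default 300).
#' @param spin_up_years leading years used only to equilibrate the soil and
#'   phenology state (default 50); retained years = n_years - spin_up_years.
#' @param sowing_doy sowing day of year (default 20 October).
#' @param cultivar [cultivar_params()].
#' @param soil_indices,soil_stress [soil_profile()]s (or preset names) for
#'   the adverse-event indices and the stress model.
#' @param master_seed integer master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(sites, scenarios, n_years = 300,
                              spin_up_years = 50,
                              sowing_doy = SOWING_DOY_DEFAULT,
                              cultivar = cultivar_params(),
                              soil_indices = "default180",
                              soil_stress = "hafren177",
                              master_seed = 1L) {
  stopifnot(length(sites) >= 1, length(scenarios) >= 1,
            spin_up_years >= 0, spin_up_years < n_years)
  if (is.null(names(sites)) || any(!nzchar(names(sites))))
    names(sites) <- vapply(sites, function(s)
      if (is.null(s$site$name)) "site" else s$site$name, character(1))
  if (is.character(soil_indices)) soil_indices <- soil_profile(soil_indices)
  if (is.character(soil_stress)) soil_stress <- soil_profile(soil_stress)
  ids <- vapply(scenarios, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate scenario ids")
  structure(list(sites = sites, scenarios = scenarios,
                 n_years = as.integer(n_years),
                 spin_up_years = as.integer(spin_up_years),
                 sowing_doy = as.integer(sowing_doy), cultivar = cultivar,
                 soil_indices = soil_indices, soil_stress = soil_stress,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Baseline-plus-ensemble scenario list
#'
#' @param members list of [change_factor_set()]s (may be empty).
#' @param include_baseline prepend the unperturbed baseline scenario.
#' @return scenario list for [experiment_config()].
#' @export
scenario_list <- function(members = list(), include_baseline = TRUE) {
  sc <- list()
  if (include_baseline) sc[[1]] <- list(id = "baseline", cf = NULL)
  for (cf in members)
    sc[[length(sc) + 1L]] <- list(
      id = paste(cf$gcm_id, cf$scenario, cf$period, sep = "_"), cf = cf)
  sc
}

# deterministic per-cell seed splitting; independent of execution order
cell_seed <- function(master_seed, site_i, scen_i) {
  as.integer((as.numeric(master_seed) + 100003 * site_i + 7919 * scen_i) %%
               2147483629)
}

#' Run one site x scenario cell
#'
#' Generate the daily series, compute radiation and reference
#' evapotranspiration, run the water balance on both soil profiles, predict
#' phenology, evaluate the seven adverse-event detectors and the crop
#' stress model on the post-spin-up years.
#'
#' @param site site_climatology.
#' @param scenario `list(id, cf)` element of the scenario list.
#' @param config [experiment_config()].
#' @param seed integer seed for this cell.
#' @return list with per-year `flags`, `probabilities`, `yields`,
#'   `indices`, `phenology` (retained years only) and metadata.
#' @export
run_cell <- function(site, scenario, config, seed) {
  clim <- if (is.null(scenario$cf)) site
          else apply_change_factors(site, scenario$cf)
  series <- generate_series(clim, config$n_years, seed)
  series <- compute_forcing(series)
  soil_idx <- run_water_balance(series, config$soil_indices)
  soil_str <- run_water_balance(series, config$soil_stress)
  pheno <- season_phenology(series, config$sowing_doy, config$cultivar)
  retained <- pheno$harvest_year > config$spin_up_years
  pheno <- pheno[retained, , drop = FALSE]
  if (!nrow(pheno)) stop("no retained crop years after spin-up")
  flags <- detect_adverse_events(series, soil_idx, pheno)
  yields <- simulate_yield_set(series, soil_str, pheno, config$cultivar)
  list(site = if (is.null(site$site$name)) "site" else site$site$name,
       latitude = site$site$latitude,
       scenario_id = scenario$id, seed = seed,
       co2_ppm = if (is.null(scenario$cf)) scenario_co2("baseline")
                 else scenario$cf$co2_ppm,
       n_retained = nrow(pheno), phenology = pheno, flags = flags,
       probabilities = event_probability(flags), yields = yields,
       indices = compute_stress_indices(yields))
}

#' Run the full experiment
#'
#' Executes every site x scenario cell, then summarises each metric across
#' the ensemble members per site (order statistics over member values).
#' A failing cell is logged and skipped; the bundle records the failures.
#'
#' @param config [experiment_config()].
#' @param quiet suppress per-cell progress messages.
#' @return list of class `experiment_result`: `cells` (per-cell results),
#'   `summary` (per site: baseline values and ensemble order statistics),
#'   `failures`, `config`.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- list()
  failures <- list()
  for (si in seq_along(config$sites)) {
    for (ci in seq_along(config$scenarios)) {
      sc <- config$scenarios[[ci]]
      seed <- cell_seed(config$master_seed, si, ci)
      tag <- paste(names(config$sites)[si], sc$id, sep = "_")
      if (!quiet) message("cell ", tag, " (seed ", seed, ")")
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(run_cell(config$sites[[si]], sc, config, seed),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning("cell ", tag, " failed: ", conditionMessage(res))
        failures[[tag]] <- conditionMessage(res)
        next
      }
      res$site <- names(config$sites)[si]  # config key, not the site label
      res$elapsed_s <- proc.time()[["elapsed"]] - t0
      cells[[tag]] <- res
    }
  }
  structure(list(cells = cells, summary = summarise_experiment(cells, config),
                 failures = failures, config = config),
            class = "experiment_result")
}

# per-site ensemble summaries of every probability and stress metric
summarise_experiment <- function(cells, config) {
  metric_vector <- function(cell) {
    p <- cell$probabilities
    probs <- stats::setNames(p$probability, paste0("p_", p$event))
    s <- cell$indices$summary
    idx <- stats::setNames(c(s$mean, s$p95),
                           c(paste0(s$index, "_mean"), paste0(s$index, "_95")))
    phen <- c(anthesis_doy_mean = mean(cell$phenology$anthesis_doy),
              maturity_doy_mean = mean(cell$phenology$maturity_doy))
    c(probs, idx, phen)
  }
  out <- list()
  for (site in names(config$sites)) {
    site_cells <- cells[startsWith(names(cells), paste0(site, "_"))]
    if (!length(site_cells)) next
    base <- site_cells[[paste0(site, "_baseline")]]
    members <- site_cells[setdiff(names(site_cells),
                                  paste0(site, "_baseline"))]
    entry <- list()
    if (!is.null(base)) entry$baseline <- as.list(metric_vector(base))
    if (length(members)) {
      mat <- do.call(rbind, lapply(members, metric_vector))
      entry$ensemble <- lapply(colnames(mat), function(cn)
        as.list(ensemble_summary(mat[, cn])))
      names(entry$ensemble) <- colnames(mat)
    }
    out[[site]] <- entry
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d cells (%d sites x %d scenarios), %d failures\n",
              length(x$cells), length(x$config$sites),
              length(x$config$scenarios), length(x$failures)))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Declarative experiment description: synthetic sites (name, latitude,
#' rainfall variant), soil profile names, cultivar thermal-time targets, a
#' synthetic change-factor ensemble (seed, members, scenario, period),
#' generated years, spin-up and master seed. See
#' `system.file("extdata", "example-config.yaml", package = "wheatrisk")`.
#'
#' @param path YAML file.
#' @return [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- lapply(y$sites, function(s)
    synthetic_site_climatology(
      name = s$name, latitude = s$latitude,
      variant = if (is.null(s$variant)) "default" else s$variant,
      elevation = if (is.null(s$elevation)) 50 else s$elevation))
  names(sites) <- vapply(y$sites, `[[`, "", "name")
  members <- if (!is.null(y$ensemble) && y$ensemble$n_members > 0)
    make_synthetic_ensemble(y$ensemble$seed, y$ensemble$n_members,
                            y$ensemble$scenario, y$ensemble$period)
  else list()
  cultivar <- if (is.null(y$cultivar)) cultivar_params() else
    do.call(cultivar_params, y$cultivar)
  experiment_config(
    sites = sites,
    scenarios = scenario_list(members,
      include_baseline = is.null(y$include_baseline) || y$include_baseline),
    n_years = if (is.null(y$n_years)) 300 else y$n_years,
    spin_up_years = if (is.null(y$spin_up_years)) 50 else y$spin_up_years,
    sowing_doy = if (is.null(y$sowing_doy)) SOWING_DOY_DEFAULT else y$sowing_doy,
    cultivar = cultivar,
    soil_indices = if (is.null(y$soil_indices)) "default180" else y$soil_indices,
    soil_stress = if (is.null(y$soil_stress)) "hafren177" else y$soil_stress,
    master_seed = if (is.null(y$master_seed)) 1L else y$master_seed)
}
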