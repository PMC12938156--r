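# Small stable provenance hash (not cryptographic): 32-bit polynomial
# hash of the serialized configuration, printed in output headers.
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.curve_to_spec <- function(curve, csv_dir, stem) {
  if (curve$kind == "step") {
    path <- file.path(csv_dir, paste0(stem, ".csv"))
    write_km_csv(curve, path)
    list(kind = "step", csv = basename(path))
  } else {
    list(kind = curve$kind, rate = curve$rate, shape = curve$shape)
  }
}

.curve_from_spec <- function(spec, base_dir, key) {
  if (is.null(spec$kind))
    stop("curve spec `", key, "` is missing `kind`", call. = FALSE)
  if (spec$kind == "step") {
    if (is.null(spec$csv))
      stop("step curve `", key, "` needs a `csv` path", call. = FALSE)
    path <- if (file.exists(spec$csv)) spec$csv else
      file.path(base_dir, spec$csv)
    if (!file.exists(path))
      stop("curve file for `", key, "` not found: ", spec$csv,
           call. = FALSE)
    read_km_csv(path)
  } else if (spec$kind %in% c("exponential", "weibull")) {
    rate <- spec$rate
    if (is.null(rate) && !is.null(spec$median))
      rate <- log(2)^(1 / (spec$shape %||% 1)) / spec$median
    if (is.null(rate))
      stop("parametric curve `", key, "` needs `rate` or `median`",
           call. = FALSE)
    survival_curve(spec$kind, rate = rate, shape = spec$shape %||% 1)
  } else stop("unknown curve kind for `", key, "`: ", spec$kind,
              call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.regimen_from_spec <- function(spec, key) {
  if (is.character(spec) && length(spec) == 1)
    return(regimen_preset(spec))
  phase <- function(p) {
    if (is.null(p)) return(NULL)
    interval <- if (!is.null(p$interval_weeks)) weeks(p$interval_weeks)
      else p$interval
    if (is.null(interval))
      stop("dose phase in `", key,
           "` needs `interval_weeks` or `interval`", call. = FALSE)
    dose_phase(interval, max_doses = p$max_doses %||% Inf,
               fixed_cost = p$fixed_cost %||% 0,
               price_units = p$price_units %||% 0,
               stop_on_progression = p$stop_on_progression %||% TRUE)
  }
  tox <- spec$toxicity
  toxicity <- if (is.null(tox)) toxicity_profile(0, 0) else
    toxicity_profile(tox$probability %||% 0, tox$cost %||% 0,
                     tox$utility %||% 1,
                     if (!is.null(tox$duration_weeks))
                       weeks(tox$duration_weeks)
                     else tox$duration %||% weeks(18))
  regimen(spec$name %||% key, induction = phase(spec$induction),
          maintenance = phase(spec$maintenance),
          guaranteed_doses = spec$guaranteed_doses %||% 3,
          toxicity = toxicity, drug_price = spec$drug_price %||% 0,
          max_treatment_years = spec$max_treatment_years %||% Inf)
}

#' Load a scenario configuration file
#'
#' The file is YAML (JSON, being a YAML subset, is also accepted). Two
#' forms are supported: a preset reference
#' (`preset: dmmr`, optionally overriding `horizon`, `wtp`,
#' `discount_rate`, `utilities`, `curves`, `seed`) or a full definition
#' with a `strategies` list, each entry naming a regimen preset or an
#' inline regimen and PFS/OS curve specs (parametric parameters, or
#' `csv` paths resolved relative to the config file). Defaults are
#' applied (`discount_rate` 0, `wtp` 100000, `horizon` 5); every
#' validation failure names the offending key.
#'
#' @param path path to the configuration file.
#' @return a validated `cea_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  if (!is.null(cfg$preset)) {
    sc <- build_scenario(cfg$preset, curves = cfg$curves %||% "parametric",
                         seed = cfg$seed %||% 1L)
    if (!is.null(cfg$horizon)) sc$horizon <- cfg$horizon
    if (!is.null(cfg$discount_rate)) sc$discount_rate <- cfg$discount_rate
    if (!is.null(cfg$wtp)) sc$wtp <- cfg$wtp
    if (!is.null(cfg$utilities))
      sc$utilities <- utility_set(cfg$utilities$on_treatment %||% 0.84,
                                  cfg$utilities$progressive %||% 0.50)
    if (!is.null(cfg$comparator)) sc$comparator <- cfg$comparator
    if (!is.null(cfg$name)) sc$name <- cfg$name
    sc <- cea_scenario(sc$name, sc$strategies, sc$utilities, sc$horizon,
                       sc$discount_rate, sc$wtp, sc$comparator,
                       sc$mmr_split, sc$seed)
    return(sc)
  }
  if (is.null(cfg$strategies) || length(cfg$strategies) == 0)
    stop("config needs `preset` or a non-empty `strategies` list",
         call. = FALSE)
  strategies <- lapply(cfg$strategies, function(s) {
    if (is.null(s$name)) stop("every strategy needs a `name`",
                              call. = FALSE)
    if (is.null(s$pfs) || is.null(s$os))
      stop("strategy `", s$name, "` needs `pfs` and `os` curve specs",
           call. = FALSE)
    strategy(.regimen_from_spec(s$regimen %||% s$name, s$name),
             pfs = .curve_from_spec(s$pfs, base_dir,
                                    paste0(s$name, ".pfs")),
             os = .curve_from_spec(s$os, base_dir,
                                   paste0(s$name, ".os")),
             name = s$name,
             post_progression_cost_rate =
               s$post_progression_cost_rate %||% 0)
  })
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  comparator <- cfg$comparator %||%
    stop("config is missing `comparator`", call. = FALSE)
  utilities <- utility_set(cfg$utilities$on_treatment %||% 0.84,
                           cfg$utilities$progressive %||% 0.50)
  cea_scenario(cfg$name %||% basename(path), strategies, utilities,
               horizon = cfg$horizon %||% 5,
               discount_rate = cfg$discount_rate %||% 0,
               wtp = cfg$wtp %||% 1e5, comparator = comparator,
               mmr_split = unlist(cfg$mmr_split), seed = cfg$seed %||% 1L)
}

#' Serialize a scenario to a YAML configuration file
#'
#' Step curves are written as digitized-curve CSV files next to the
#' config; parametric curves are embedded. `load_scenario()` on the
#' written file reconstructs a semantically identical scenario.
#'
#' @param scenario a `cea_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cea_scenario"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  strategies <- lapply(scenario$strategies, function(st) {
    reg <- st$regimen
    phase <- function(p) if (is.null(p)) NULL else list(
      interval = p$interval,
      max_doses = if (is.finite(p$max_doses)) p$max_doses else NULL,
      fixed_cost = p$fixed_cost, price_units = p$price_units,
      stop_on_progression = p$stop_on_progression)
    list(
      name = st$name,
      regimen = list(
        name = reg$name,
        induction = phase(reg$induction),
        maintenance = phase(reg$maintenance),
        guaranteed_doses = reg$guaranteed_doses,
        drug_price = reg$drug_price,
        max_treatment_years = if (is.finite(reg$max_treatment_years))
          reg$max_treatment_years else NULL,
        toxicity = list(probability = reg$toxicity$probability,
                        cost = reg$toxicity$cost,
                        utility = reg$toxicity$utility,
                        duration = reg$toxicity$duration)),
      pfs = .curve_to_spec(st$pfs, dirname(path),
                           paste0(st$name, "_pfs")),
      os = .curve_to_spec(st$os, dirname(path), paste0(st$name, "_os")),
      post_progression_cost_rate = st$post_progression_cost_rate)
  })
  cfg <- list(
    name = scenario$name,
    horizon = scenario$horizon, discount_rate = scenario$discount_rate,
    wtp = scenario$wtp, comparator = scenario$comparator,
    utilities = list(on_treatment = scenario$utilities$on_treatment,
                     progressive = scenario$utilities$progressive),
    mmr_split = as.list(scenario$mmr_split),
    seed = scenario$seed,
    strategies = unname(strategies))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# CSV writer with a provenance header comment (config hash + seed)
.write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# psmcea config=%s seed=%d", hash, seed), con)
  utils::write.csv(format(df, trim = TRUE, scientific = FALSE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on a scenario
#'
#' Evaluates the scenario deterministically and (optionally) writes the
#' incremental-analysis table as a CSV laid out like a standard
#' cost-effectiveness results table (strategy, total cost, incremental
#' cost, incremental effectiveness, PFLY, QA-PFLYS, QALY, ICER). The
#' CSV carries a header comment with the configuration hash and seed
#' for provenance; reruns with the same configuration are byte
#' identical.
#'
#' @param scenario a `cea_scenario` or a path to a configuration file.
#' @param out_dir output directory for CSVs, or `NULL` to skip writing.
#' @param effect effectiveness measure for the incremental analysis.
#' @param quiet suppress per-stage log messages.
#' @return the `cea_result` table, invisibly when `out_dir` is given.
#' @export
#' @examples
#' run_pipeline(build_scenario("toy"), quiet = TRUE)
run_pipeline <- function(scenario, out_dir = NULL,
                         effect = c("qa_pflys", "qalys"), quiet = FALSE) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "cea_scenario"))
  effect <- match.arg(effect)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("scenario: %s (%d strategies, horizon %g y, discount %g, WTP $%s)",
      scenario$name, length(scenario$strategies), scenario$horizon,
      scenario$discount_rate, format(scenario$wtp, big.mark = ","))
  res <- run_cea(scenario, effect = effect)
  icer_txt <- ifelse(is.na(res$icer), res$status,
                     sprintf("%.0f", res$icer))
  say("incremental analysis vs %s: %s", scenario$comparator,
      paste(sprintf("%s=%s", res$strategy, icer_txt), collapse = ", "))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- .config_hash(list(name = scenario$name,
                              horizon = scenario$horizon,
                              discount = scenario$discount_rate,
                              wtp = scenario$wtp,
                              strategies = names(scenario$strategies)))
    tab <- as.data.frame(res)[, c("strategy", "total_cost",
                                  "incremental_cost",
                                  "incremental_effect", "pfly",
                                  "qa_pflys", "qalys", "icer", "status")]
    .write_csv_prov(tab, file.path(out_dir, "cea_results.csv"), hash,
                    scenario$seed)
    say("wrote %s", file.path(out_dir, "cea_results.csv"))
    return(invisible(res))
  }
  res
}
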