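# internal: deterministic stage seed derived from the single pipeline seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.double(seed) * 48271 + h * 2654435) %% 2147483399 + 1
}

# internal: read a pipeline config from YAML or JSON, or pass a list through
read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) stop("config file not found: ", config)
  ext <- tolower(tools::file_ext(config))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    cfg <- tryCatch(yaml::read_yaml(config),
                    error = function(e) stop("malformed YAML config: ",
                                             conditionMessage(e)))
  } else if (ext == "json") {
    cfg <- tryCatch(jsonlite::read_json(config, simplifyVector = TRUE),
                    error = function(e) stop("malformed JSON config: ",
                                             conditionMessage(e)))
  } else stop("unsupported config type: ", config)
  if (!is.list(cfg)) stop("malformed config: expected a mapping")
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> aggregate -> corrected trials ->
#' Bayesian hatch and emergence fits -> competitiveness, emergence product,
#' relative risks and efficacy-loss tests -> water-concentration model ->
#' report. Every random stage is seeded from the single `seed` through
#' named substreams, so two runs with the same configuration are
#' byte-identical, and changing the draw count of one stage does not
#' perturb another.
#'
#' @param config A list, or path to a YAML/JSON file, with optional
#'   entries: `input_dir` (read an existing trial; otherwise a synthetic
#'   trial is generated), `generator` (overrides for [generator_params()]),
#'   `seed`, `draws`, `chains`, `warmup`, `out` (output directory; when
#'   given, `report.json` and summary CSVs are written there).
#' @param seed,draws Overrides of the config entries.
#' @return A list of class `sit_report` with all stage summaries and a
#'   structured `log` of flags, exclusions and diagnostics.
#' @export
run_pipeline <- function(config = list(), seed = NULL, draws = NULL) {
  cfg <- read_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  draws <- as.integer(draws %||% cfg$draws %||% 10000L)
  chains <- as.integer(cfg$chains %||% 4L)
  warmup <- as.integer(cfg$warmup %||% 1000L)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- list(stage = stage, message = msg)
  }

  # --- data stage ---
  if (!is.null(cfg$input_dir)) {
    trial <- read_trial(cfg$input_dir)
    note("data", paste("read trial from", cfg$input_dir))
  } else {
    gp <- do.call(generator_params, c(cfg$generator %||% list()))
    trial <- simulate_trial(design = cfg$design %||% canonical_design(),
                            params = gp,
                            seed = stage_seed(seed, "simulate"))
    note("data", "simulated synthetic trial")
  }
  dw <- validate_design(trial$design)
  for (w in dw) note("design", w)

  # --- demography stage ---
  cohorts <- if (nrow(trial$intervals) > 0) {
    aggregate_intervals(trial$intervals, trial$cohorts, trial$design)
  } else trial$cohorts
  ct <- corrected_trials(cohorts)

  # --- Bayesian fits ---
  labels <- cohorts[c("cage_id", "replicate_id")]
  Mh <- fit_binomial_mixed(cohorts$eggs_hatched, cohorts$eggs_total,
                           cohorts$treatment, n_draws = draws,
                           seed = stage_seed(seed, "fit-hatch"),
                           chains = chains, warmup = warmup,
                           row_labels = labels)
  Ma <- fit_binomial_mixed(ct$numerator, ct$denominator_int,
                           cohorts$treatment, n_draws = draws,
                           seed = stage_seed(seed, "fit-emergence"),
                           chains = chains, warmup = warmup,
                           row_labels = labels)
  for (f in c(Mh$flags, Ma$flags)) note("fit", f$detail)

  # --- efficacy stage ---
  Th <- aggregate_by_treatment(Mh)
  Ta <- aggregate_by_treatment(Ma)
  Me <- emergence_product(Mh, Ma)
  Te <- aggregate_by_treatment(Me)
  hatch_summary <- summarize_posterior(Th)
  emergence_summary <- summarize_posterior(Ta)
  egg_to_adult_summary <- summarize_posterior(Te)
  non_control <- setdiff(Th$treatment_labels, "control")
  cp <- do.call(rbind, lapply(non_control, function(tr)
    competitiveness_posterior(Th, tr)))
  rr <- if ("control" %in% Te$treatment_labels)
    relative_risk(Te, "control") else NULL
  deltas <- list()
  for (pair in list(c("bSIT1", "SIT1"), c("bSIT5", "SIT5")))
    if (all(pair %in% Th$treatment_labels))
      deltas[[paste(pair, collapse = "_vs_")]] <-
        delta_test(Th, pair[1], pair[2], B = min(10000L, ncol(Th$draws)))
  deltas <- if (length(deltas)) do.call(rbind, deltas) else NULL

  # --- water stage ---
  water_results <- NULL
  if (is.null(trial$water)) {
    note("water", "no water table; stage skipped")
  } else if (sum(trial$water$concentration_ppb > 0) < 4) {
    note("water", "too few positive concentrations; stage skipped")
  } else {
    w <- trial$water[trial$water$s2f > 0 &
                       treatment_boosted_from_water(trial$water), ,
                     drop = FALSE]
    if (nrow(w) >= 6 && length(unique(w$s2f)) > 1) {
      w$s2f_factor <- factor(w$s2f)
      f0 <- fit_zag(concentration_ppb ~ 1, w)
      f1 <- fit_zag(concentration_ppb ~ s2f_factor, w)
      test <- lrt(f0, f1)
      out_flags <- flag_outliers(w$concentration_ppb)
      if (any(out_flags))
        note("water", paste(sum(out_flags),
                            "outlying concentration(s) flagged, not removed"))
      water_results <- list(null_fit = f0, full_fit = f1, lrt = test,
                            outliers = which(out_flags))
    } else note("water", "not enough boosted samples for the ratio contrast")
  }

  report <- structure(list(
    seed = seed, draws = draws,
    design = trial$design,
    cohorts = cohorts, corrected = ct,
    hatch = hatch_summary, emergence = emergence_summary,
    egg_to_adult = egg_to_adult_summary,
    competitiveness = cp, relative_risk = rr, delta_tests = deltas,
    water = water_results,
    posteriors = list(Mh = Mh, Ma = Ma, Me = Me),
    log = log), class = "sit_report")
  if (!is.null(cfg$out)) write_report(report, cfg$out)
  report
}

# internal: boosted status of water rows (dose > 0 marks boosted cages)
treatment_boosted_from_water <- function(water) {
  water$dose_mg_per_200 > 0
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (all summaries, full precision) and human-readable
#' CSV tables; the relative-risk table is ordered from the most to the
#' least effective treatment (ascending posterior-mean RR). The JSON is
#' deterministic: the same report always serialises to the same bytes.
#'
#' @param report A `sit_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    schema_version = "1.0",
    seed = report$seed, draws = report$draws,
    hatch = report$hatch, emergence = report$emergence,
    egg_to_adult = report$egg_to_adult,
    competitiveness = report$competitiveness,
    relative_risk = report$relative_risk,
    delta_tests = report$delta_tests,
    water_lrt = if (!is.null(report$water)) report$water$lrt,
    diagnostics = list(hatch = report$posteriors$Mh$diagnostics,
                       emergence = report$posteriors$Ma$diagnostics),
    log = report$log)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(report$corrected, file.path(dir, "corrected.csv"),
                   row.names = FALSE)
  if (!is.null(report$relative_risk))
    utils::write.csv(report$relative_risk,
                     file.path(dir, "relative_risk.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.sit_report <- function(x, ...) {
  cat("SIT efficacy report (seed", x$seed, ",", x$draws, "draws)\n\n")
  cat("Hatch probability by treatment:\n")
  print(transform(x$hatch, mean = round(mean, 3), ll = round(ll, 3),
                  ul = round(ul, 3)), row.names = FALSE)
  if (!is.null(x$competitiveness)) {
    cat("\nCompetitiveness of sterile males:\n")
    print(transform(x$competitiveness, cp_mean = round(cp_mean, 3),
                    ll = round(ll, 3), ul = round(ul, 3),
                    cp_plugin = round(cp_plugin, 3)), row.names = FALSE)
  }
  if (!is.null(x$relative_risk)) {
    cat("\nRelative risk of adult emergence vs control",
        "(most to least effective):\n")
    print(transform(x$relative_risk, rr_mean = round(rr_mean, 3),
                    ll = round(ll, 3), ul = round(ul, 3),
                    rr_plugin = round(rr_plugin, 3)), row.names = FALSE)
  }
  if (!is.null(x$delta_tests)) {
    cat("\nEfficacy-loss tests (boosted minus non-boosted hatch):\n")
    print(transform(x$delta_tests, delta_mean = round(delta_mean, 3),
                    p_value = round(p_value, 4)), row.names = FALSE)
  }
  invisible(x)
}
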