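#' Treatment categories of a SIT / boosted-SIT cage trial
#'
#' The canonical trial compares five treatments: an untreated control,
#' standard SIT at sterile-to-fertile male ratios (`s2f`) of 1:1 and 5:1
#' (`SIT1`, `SIT5`), and the same two ratios with pyriproxyfen-boosted
#' sterile males (`bSIT1`, `bSIT5`).
#'
#' @return Character vector of the five labels in canonical order
#'   (control first, then SIT1, SIT5, bSIT1, bSIT5).
#' @export
treatment_levels <- function() {
  c("control", "SIT1", "SIT5", "bSIT1", "bSIT5")
}

#' Treatment category descriptor
#'
#' Maps a treatment label to its sterile-to-fertile male ratio and boosted
#' status. The label/(s2f, boosted) mapping is bijective for the canonical
#' five labels; arbitrary non-negative ratios are accepted when building a
#' descriptor directly.
#'
#' @param label One of [treatment_levels()].
#' @return A list with elements `label`, `s2f` (0 for control, 1 or 5
#'   otherwise) and `boosted` (logical).
#' @examples
#' treatment_category("bSIT5")
#' @export
treatment_category <- function(label) {
  label <- match.arg(label, treatment_levels())
  s2f <- switch(label, control = 0, SIT1 = 1, bSIT1 = 1, SIT5 = 5, bSIT5 = 5)
  list(label = label, s2f = s2f, boosted = label %in% c("bSIT1", "bSIT5"))
}

#' Sterile-to-fertile ratio for each treatment label
#'
#' @param label Character vector of treatment labels.
#' @return Numeric vector of s2f ratios.
#' @export
treatment_s2f <- function(label) {
  vapply(as.character(label), function(l) treatment_category(l)$s2f, numeric(1))
}

#' Is a treatment boosted with pyriproxyfen?
#'
#' @param label Character vector of treatment labels.
#' @return Logical vector.
#' @export
treatment_boosted <- function(label) {
  vapply(as.character(label), function(l) treatment_category(l)$boosted,
         logical(1))
}

#' Construct a trial design
#'
#' A design is the cage-by-replicate layout with released insect counts and
#' the monitoring schedule. The statistical unit of the analysis is the
#' cage-by-replicate cohort; the canonical design has 5 treatments x 4
#' replicates = 20 cohorts.
#'
#' @param cages Data frame with columns `cage_id`, `replicate_id`,
#'   `treatment`, `n_females`, `n_fertile_males`, `n_sterile_males`.
#' @param replicates Number of replicates (default inferred from `cages`).
#' @param observation_interval_days Days between successive examinations of
#'   the immature stages (default 2).
#' @param horizon_days Last day of monitoring after flooding (default 15);
#'   individuals still immature then are right-censored.
#' @return An object of class `sit_design`.
#' @export
sit_design <- function(cages, replicates = length(unique(cages$replicate_id)),
                       observation_interval_days = 2L, horizon_days = 15L) {
  req <- c("cage_id", "replicate_id", "treatment", "n_females",
           "n_fertile_males", "n_sterile_males")
  miss <- setdiff(req, names(cages))
  if (length(miss) > 0)
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  cages <- as.data.frame(cages)[req]
  cages$treatment <- as.character(cages$treatment)
  bad <- setdiff(unique(cages$treatment), treatment_levels())
  if (length(bad) > 0)
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  key <- paste(cages$cage_id, cages$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate cage_id x replicate_id: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  counts <- cages[c("n_females", "n_fertile_males", "n_sterile_males")]
  if (any(unlist(counts) < 0) || any(unlist(counts) != round(unlist(counts))))
    stop("released-insect counts must be non-negative integers")
  s2f <- treatment_s2f(cages$treatment)
  active <- s2f > 0
  if (any(active)) {
    obs <- cages$n_sterile_males[active] / cages$n_fertile_males[active]
    off <- which(abs(obs - s2f[active]) > 1e-8)
    if (length(off) > 0)
      stop("cage ", cages$cage_id[active][off[1]],
           ": n_sterile_males / n_fertile_males = ", signif(obs[off[1]], 4),
           " does not match treatment s2f = ", s2f[active][off[1]])
  }
  stopifnot(observation_interval_days >= 1, horizon_days >= 1)
  structure(list(cages = cages,
                 replicates = as.integer(replicates),
                 observation_interval_days = as.integer(observation_interval_days),
                 horizon_days = as.integer(horizon_days)),
            class = "sit_design")
}

#' The canonical 5-treatment x 4-replicate design
#'
#' One cage per treatment per replicate, `n_base` females and fertile males
#' per cage (control cages get no sterile males; SIT cages get
#' `s2f * n_base` sterile males).
#'
#' @param replicates Number of replicates (default 4).
#' @param n_base Females and fertile males per cage (default 50).
#' @param ... Passed to [sit_design()].
#' @return A `sit_design`.
#' @export
canonical_design <- function(replicates = 4L, n_base = 50L, ...) {
  grid <- expand.grid(treatment = treatment_levels(),
                      replicate_id = seq_len(replicates),
                      stringsAsFactors = FALSE)
  cages <- data.frame(
    cage_id = paste0(grid$treatment, "_r", grid$replicate_id),
    replicate_id = grid$replicate_id,
    treatment = grid$treatment,
    n_females = n_base,
    n_fertile_males = n_base,
    n_sterile_males = as.integer(treatment_s2f(grid$treatment) * n_base),
    stringsAsFactors = FALSE)
  sit_design(cages, replicates = replicates, ...)
}

#' @export
print.sit_design <- function(x, ...) {
  cat("SIT trial design:", nrow(x$cages), "cage-cohorts,",
      x$replicates, "replicate(s)\n")
  cat("  treatments:", paste(unique(x$cages$treatment), collapse = ", "), "\n")
  cat("  monitored every", x$observation_interval_days,
      "day(s) up to day", x$horizon_days, "\n")
  invisible(x)
}

#' Examination days implied by a design
#'
#' Multiples of the observation interval up to the horizon; the horizon
#' itself is always an examination day even when it is not a multiple (the
#' canonical schedule is every 2 days for 15 days: 2, 4, ..., 14, 15).
#'
#' @param design A `sit_design`.
#' @return Integer vector of examination days.
#' @export
examination_days <- function(design) {
  d <- seq(design$observation_interval_days, design$horizon_days,
           by = design$observation_interval_days)
  sort(unique(c(d, design$horizon_days)))
}

#' Warn about deviations from the canonical layout
#'
#' Non-fatal checks: the canonical trial has 5 treatment categories and 4
#' replicates; anything else is legal but flagged so that downstream
#' summaries are read with care.
#'
#' @param design A `sit_design`.
#' @return Character vector of warnings (empty when canonical), invisibly;
#'   each is also raised via [warning()].
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "sit_design"))
  w <- character(0)
  if (design$replicates != 4L)
    w <- c(w, sprintf("non-canonical replicate count: %d (canonical is 4)",
                      design$replicates))
  tr <- unique(design$cages$treatment)
  if (length(tr) != 5L)
    w <- c(w, sprintf("non-canonical treatment count: %d (canonical is 5)",
                      length(tr)))
  n_per <- table(design$cages$treatment, design$cages$replicate_id)
  if (any(n_per != 1L))
    w <- c(w, "some treatment x replicate cells do not have exactly one cage")
  for (m in w) warning(m, call. = FALSE)
  invisible(w)
}

# internal: validate a cohort-count table (one row per cage-cohort)
validate_cohorts <- function(cohorts) {
  req <- c("cage_id", "replicate_id", "treatment", "eggs_total",
           "eggs_hatched", "e_meta", "l_death", "n_death", "n_meta",
           "censored")
  miss <- setdiff(req, names(cohorts))
  if (length(miss) > 0)
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  cohorts <- as.data.frame(cohorts)[req]
  num <- c("eggs_total", "eggs_hatched", "e_meta", "l_death", "n_death",
           "n_meta", "censored")
  for (cl in num) {
    v <- cohorts[[cl]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop("cohort row ", bad[1], " (cage ", cohorts$cage_id[bad[1]],
           "): column '", cl, "' must be a non-negative integer")
    cohorts[[cl]] <- as.integer(v)
  }
  bad <- which(cohorts$eggs_hatched > cohorts$eggs_total)
  if (length(bad) > 0)
    stop("cohort row ", bad[1], " (cage ", cohorts$cage_id[bad[1]],
         "): eggs_hatched > eggs_total")
  tot <- with(cohorts, n_meta + l_death + n_death + censored)
  bad <- which(tot > cohorts$e_meta)
  if (length(bad) > 0)
    stop("cohort row ", bad[1], " (cage ", cohorts$cage_id[bad[1]],
         "): n_meta + l_death + n_death + censored exceeds e_meta")
  cohorts
}

# internal: validate interval-censored event records
validate_intervals <- function(intervals, design = NULL) {
  req <- c("cage_id", "day", "stage", "deaths", "molts")
  miss <- setdiff(req, names(intervals))
  if (length(miss) > 0)
    stop("interval table is missing columns: ", paste(miss, collapse = ", "))
  intervals <- as.data.frame(intervals)[req]
  if (nrow(intervals) == 0) return(intervals)
  if (!all(intervals$stage %in% c("larva", "pupa")))
    stop("interval stage must be 'larva' or 'pupa'")
  num <- c("day", "deaths", "molts")
  for (cl in num) {
    v <- intervals[[cl]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop("interval row ", bad[1], " (cage ", intervals$cage_id[bad[1]],
           "): column '", cl, "' must be a non-negative integer")
    intervals[[cl]] <- as.integer(v)
  }
  if (!is.null(design)) {
    bad <- which(intervals$day > design$horizon_days)
    if (length(bad) > 0)
      stop("interval row ", bad[1], " (cage ", intervals$cage_id[bad[1]],
           "): day ", intervals$day[bad[1]], " is beyond the horizon (",
           design$horizon_days, ")")
  }
  intervals
}

# internal: validate ovitrap water-concentration samples
validate_water <- function(water) {
  req <- c("cage_id", "replicate_id", "concentration_ppb", "females_present",
           "fertile_males_present", "s2f", "dose_mg_per_200")
  miss <- setdiff(req, names(water))
  if (length(miss) > 0)
    stop("water table is missing columns: ", paste(miss, collapse = ", "))
  water <- as.data.frame(water)[req]
  bad <- which(is.na(water$concentration_ppb) | water$concentration_ppb < 0)
  if (length(bad) > 0)
    stop("water row ", bad[1], " (cage ", water$cage_id[bad[1]],
         "): concentration_ppb must be a non-negative number")
  water$females_present <- as.logical(water$females_present)
  water$fertile_males_present <- as.logical(water$fertile_males_present)
  water
}

#' Read a trial from delimited text tables
#'
#' Reads and validates the four tables of a trial: the cage layout
#' (`design`), per-cage cohort tallies (`cohorts.csv`), interval-censored
#' stage events (`intervals.csv`) and ovitrap water concentrations
#' (`water.csv`). All files are CSV with a header row; the design may be a
#' YAML or JSON file holding `replicates`, `horizon_days`,
#' `observation_interval_days` and the cage list, or a CSV of cages.
#'
#' @param dir Directory holding `design.(yaml|json|csv)`, `cohorts.csv`,
#'   `intervals.csv`, `water.csv`. Individual paths may override via the
#'   named arguments.
#' @param design_file,cohorts_file,intervals_file,water_file Optional
#'   explicit paths.
#' @return A list with components `design` (`sit_design`), `cohorts`,
#'   `intervals`, `water` (validated data frames), of class `sit_trial_data`.
#' @export
read_trial <- function(dir = ".",
                       design_file = NULL, cohorts_file = NULL,
                       intervals_file = NULL, water_file = NULL) {
  find1 <- function(given, candidates) {
    if (!is.null(given)) return(given)
    for (f in file.path(dir, candidates)) if (file.exists(f)) return(f)
    NA_character_
  }
  df <- find1(design_file, c("design.yaml", "design.yml", "design.json",
                             "design.csv"))
  if (is.na(df)) stop("no design file found in ", dir)
  design <- read_design(df)
  cf <- find1(cohorts_file, "cohorts.csv")
  if (is.na(cf)) stop("no cohorts.csv found in ", dir)
  cohorts <- validate_cohorts(utils::read.csv(cf, stringsAsFactors = FALSE))
  inf <- find1(intervals_file, "intervals.csv")
  intervals <- if (is.na(inf)) {
    data.frame(cage_id = character(0), day = integer(0), stage = character(0),
               deaths = integer(0), molts = integer(0))
  } else {
    validate_intervals(utils::read.csv(inf, stringsAsFactors = FALSE), design)
  }
  wf <- find1(water_file, "water.csv")
  water <- if (is.na(wf)) NULL else
    validate_water(utils::read.csv(wf, stringsAsFactors = FALSE))
  unknown <- setdiff(cohorts$cage_id, design$cages$cage_id)
  if (length(unknown) > 0)
    stop("cohort rows reference cage ids absent from the design: ",
         paste(unknown, collapse = ", "))
  structure(list(design = design, cohorts = cohorts, intervals = intervals,
                 water = water),
            class = "sit_trial_data")
}

# internal: read a design from yaml/json/csv
read_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML designs requires the 'yaml' package; ",
           "use design.json or design.csv instead")
    spec <- yaml::read_yaml(path)
  } else if (ext == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext == "csv") {
    cages <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(sit_design(cages))
  } else stop("unsupported design file type: ", path)
  cages <- if (is.data.frame(spec$cages)) spec$cages else
    do.call(rbind, lapply(spec$cages, as.data.frame))
  sit_design(cages,
             replicates = spec$replicates %||% length(unique(cages$replicate_id)),
             observation_interval_days = spec$observation_interval_days %||% 2L,
             horizon_days = spec$horizon_days %||% 15L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial to delimited text tables
#'
#' Inverse of [read_trial()]: writes `design.json`, `cohorts.csv`,
#' `intervals.csv` and (when present) `water.csv` under `dir`. A write
#' followed by a read reproduces every count exactly.
#'
#' @param trial A `sit_trial_data` object (e.g. from [simulate_trial()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "sit_trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- trial$design
  spec <- list(replicates = d$replicates,
               observation_interval_days = d$observation_interval_days,
               horizon_days = d$horizon_days,
               cages = lapply(seq_len(nrow(d$cages)),
                              function(i) as.list(d$cages[i, ])))
  jsonlite::write_json(spec, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(trial$cohorts, file.path(dir, "cohorts.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$intervals, file.path(dir, "intervals.csv"),
                   row.names = FALSE)
  if (!is.null(trial$water))
    utils::write.csv(trial$water, file.path(dir, "water.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.sit_trial_data <- function(x, ...) {
  cat("SIT trial data:", nrow(x$cohorts), "cohorts,",
      nrow(x$intervals), "interval records,",
      if (is.null(x$water)) 0 else nrow(x$water), "water samples\n")
  invisible(x)
}
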