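#' Parameters of the synthetic trial generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' hatch probability suppressed by sterile-male competitiveness (the inverse
#' of the Fried-index estimator), between-cage overdispersion as a
#' logit-scale cage-level normal deviate, a two-stage daily competing-risk
#' chain for the immature stages observed every two days, pyriproxyfen
#' emergence inhibition anchored at EI50/EI95, and zero-augmented gamma
#' water concentrations with occasional large outliers (dead boosted males
#' falling into the trap water).
#'
#' @param ph_control Baseline hatch probability of control eggs (0.936).
#' @param cp_by_treatment Named list of true competitiveness values for the
#'   non-control treatments.
#' @param sigma_cage SD of the cage-level (observation-level) logit-scale
#'   random effect on hatch.
#' @param daily_molt_hazard_larva,daily_death_hazard_larva Daily molt/death
#'   probabilities for larvae; defaults give a larval period of about 5-7
#'   days and, with the pupal defaults, a control emergence-from-larva
#'   probability near 0.68 within the 15-day horizon.
#' @param daily_molt_hazard_pupa,daily_death_hazard_pupa Daily molt/death
#'   probabilities for pupae.
#' @param ei50_ppb,ei95_ppb Water concentrations giving 50% and 95% adult
#'   emergence inhibition (0.20 and 0.67).
#' @param conc_zero_prob Probability a trap-water sample from a boosted cage
#'   contains no detectable pyriproxyfen.
#' @param conc_gamma_shape Gamma shape of positive concentrations.
#' @param conc_mean_by_condition Named list of mean positive concentrations
#'   (ppb) by boosted treatment.
#' @param outlier_prob Probability a positive sample is redrawn from the
#'   outlier component.
#' @param outlier_mean Mean of the outlier component (> 6 ppb).
#' @param eggs_per_cage_mean Mean egg total per cage-cohort.
#' @param eggs_dispersion Negative-binomial size of egg totals.
#' @param seed Base seed for the per-cage substreams.
#' @return A list of class `sit_generator_params`.
#' @export
generator_params <- function(ph_control = 0.936,
                             cp_by_treatment = list(SIT1 = 0.229, SIT5 = 0.562,
                                                    bSIT1 = 0.211,
                                                    bSIT5 = 0.125),
                             sigma_cage = 0.3,
                             daily_molt_hazard_larva = 0.15,
                             daily_death_hazard_larva = 0.05,
                             daily_molt_hazard_pupa = 0.40,
                             daily_death_hazard_pupa = 0.035,
                             ei50_ppb = 0.20, ei95_ppb = 0.67,
                             conc_zero_prob = 0.3,
                             conc_gamma_shape = 1.5,
                             conc_mean_by_condition = list(bSIT1 = 0.30,
                                                           bSIT5 = 0.60),
                             outlier_prob = 0.05, outlier_mean = 8,
                             eggs_per_cage_mean = 200,
                             eggs_dispersion = 20,
                             seed = 20201101L) {
  p <- list(ph_control = ph_control, cp_by_treatment = cp_by_treatment,
            sigma_cage = sigma_cage,
            daily_molt_hazard_larva = daily_molt_hazard_larva,
            daily_death_hazard_larva = daily_death_hazard_larva,
            daily_molt_hazard_pupa = daily_molt_hazard_pupa,
            daily_death_hazard_pupa = daily_death_hazard_pupa,
            ei50_ppb = ei50_ppb, ei95_ppb = ei95_ppb,
            conc_zero_prob = conc_zero_prob,
            conc_gamma_shape = conc_gamma_shape,
            conc_mean_by_condition = conc_mean_by_condition,
            outlier_prob = outlier_prob, outlier_mean = outlier_mean,
            eggs_per_cage_mean = eggs_per_cage_mean,
            eggs_dispersion = eggs_dispersion,
            seed = as.integer(seed))
  probs <- c(p$ph_control, p$sigma_cage >= 0,
             p$daily_molt_hazard_larva, p$daily_death_hazard_larva,
             p$daily_molt_hazard_pupa, p$daily_death_hazard_pupa,
             p$conc_zero_prob, p$outlier_prob)
  if (any(unlist(p[c("daily_molt_hazard_larva", "daily_death_hazard_larva",
                     "daily_molt_hazard_pupa", "daily_death_hazard_pupa",
                     "conc_zero_prob", "outlier_prob")]) < 0) ||
      any(unlist(p[c("daily_molt_hazard_larva", "daily_death_hazard_larva",
                     "daily_molt_hazard_pupa", "daily_death_hazard_pupa",
                     "conc_zero_prob", "outlier_prob")]) > 1))
    stop("all hazard and probability parameters must lie in [0, 1]")
  if (p$ph_control <= 0 || p$ph_control > 1)
    stop("ph_control must lie in (0, 1]")
  if (p$ei95_ppb <= p$ei50_ppb || p$ei50_ppb <= 0)
    stop("ei95_ppb must exceed ei50_ppb > 0")
  if (p$sigma_cage < 0) stop("sigma_cage must be non-negative")
  if (any(unlist(p$cp_by_treatment) < 0))
    stop("competitiveness values must be non-negative")
  class(p) <- "sit_generator_params"
  p
}

#' Hatch probability implied by sterile-male competitiveness
#'
#' Inverts the Fried-index estimator: if control eggs hatch with probability
#' `ph_control` and sterile males of competitiveness `cp` are released at
#' `s2f` per fertile male, the treated hatch probability is
#' `ph_control / (1 + cp * s2f)`. Feeding the result back through
#' [competitiveness_plugin()] recovers `cp` exactly, which is what makes
#' parameter recovery on synthetic trials self-consistent.
#'
#' @param ph_control Control hatch probability in (0, 1].
#' @param cp True competitiveness (>= 0).
#' @param s2f Sterile-to-fertile male ratio (>= 0; 0 for control).
#' @return The treated hatch probability.
#' @examples
#' hatch_under_treatment(0.936, 0.125, 5)  # 0.936 / 1.625 = 0.576
#' @export
hatch_under_treatment <- function(ph_control, cp, s2f) {
  if (any(ph_control <= 0) || any(ph_control > 1))
    stop("ph_control must lie in (0, 1]")
  if (any(cp < 0)) stop("cp must be non-negative")
  if (any(s2f < 0)) stop("s2f must be non-negative")
  ph_control / (1 + cp * s2f)
}

#' Pyriproxyfen emergence inhibition from water concentration
#'
#' Two-parameter log-logistic dose-response, uniquely determined by its two
#' anchors: `EI(ei50) = 0.50` and `EI(ei95) = 0.95` exactly, with
#' `EI(0) = 0`. On the log-concentration scale the curve is
#' `plogis((log(c) - log(ei50)) / s)` with slope
#' `s = log(ei95/ei50) / qlogis(0.95)`.
#'
#' @param conc_ppb Water concentration(s), ppb, >= 0.
#' @param ei50 Concentration giving 50% inhibition (default 0.20).
#' @param ei95 Concentration giving 95% inhibition (default 0.67); must
#'   exceed `ei50`.
#' @return Inhibition probability in [0, 1).
#' @examples
#' emergence_inhibition(c(0, 0.20, 0.67))
#' @export
emergence_inhibition <- function(conc_ppb, ei50 = 0.20, ei95 = 0.67) {
  if (any(conc_ppb < 0)) stop("concentration must be non-negative")
  if (!(ei95 > ei50 && ei50 > 0)) stop("need ei95 > ei50 > 0")
  s <- log(ei95 / ei50) / stats::qlogis(0.95)
  out <- numeric(length(conc_ppb))
  pos <- conc_ppb > 0
  out[pos] <- stats::plogis((log(conc_ppb[pos]) - log(ei50)) / s)
  out
}

#' Simulate one cage-cohort through the immature stages
#'
#' A daily two-stage competing-risk chain: each larva independently dies,
#' molts to pupa, or stays, with the daily hazards in `params`; each pupa
#' dies, attempts emergence, or stays. Pyriproxyfen multiplies the
#' pupa-to-adult success probability by `1 - EI(conc)`; blocked emergence
#' attempts move the pupa to an absorbing "blocked" state which is tallied
#' as a pupal death on the final examination day, keeping the competing-risk
#' bookkeeping closed. Events are recorded only at examination days, so the
#' returned records are interval-censored aggregates; survivors at the
#' horizon are censored.
#'
#' @param n_larvae Number of hatched larvae entering monitoring.
#' @param params A `sit_generator_params`.
#' @param conc_ppb Pyriproxyfen water concentration acting on this cohort.
#' @param cage_id Identifier stamped on the interval records.
#' @param observation_interval_days,horizon_days Monitoring schedule.
#' @return A list with `counts` (one-row data frame: `e_meta`, `l_death`,
#'   `n_death`, `n_meta`, `censored`) and `intervals` (interval records).
#' @export
simulate_cohort <- function(n_larvae, params, conc_ppb = 0,
                            cage_id = "cage", observation_interval_days = 2L,
                            horizon_days = 15L) {
  stopifnot(n_larvae >= 0, n_larvae == round(n_larvae))
  ei <- emergence_inhibition(conc_ppb, params$ei50_ppb, params$ei95_ppb)
  # numerically negligible inhibition is treated as none, so the RNG path
  # is identical to the uncontaminated one
  if (ei < 1e-12) ei <- 0
  exam <- sort(unique(c(seq(observation_interval_days, horizon_days,
                            by = observation_interval_days), horizon_days)))
  larvae <- n_larvae; pupae <- 0L; blocked <- 0L
  acc <- list(l_death = 0L, l_molt = 0L, n_death = 0L, n_molt = 0L)
  tot <- list(l_death = 0L, n_death = 0L, n_meta = 0L)
  rec <- vector("list", 2L * length(exam))
  k <- 0L
  for (day in seq_len(horizon_days)) {
    # pupae first, so a larva cannot molt and emerge on the same day
    if (pupae > 0) {
      pd <- params$daily_death_hazard_pupa
      pm <- params$daily_molt_hazard_pupa
      ev <- stats::rmultinom(1, pupae, c(pd, pm * (1 - ei), pm * ei,
                                         1 - pd - pm))
      acc$n_death <- acc$n_death + ev[1L]
      acc$n_molt <- acc$n_molt + ev[2L]
      blocked <- blocked + ev[3L]
      pupae <- ev[4L]
    }
    if (larvae > 0) {
      ld <- params$daily_death_hazard_larva
      lm <- params$daily_molt_hazard_larva
      ev <- stats::rmultinom(1, larvae, c(ld, lm, 1 - ld - lm))
      acc$l_death <- acc$l_death + ev[1L]
      acc$l_molt <- acc$l_molt + ev[2L]
      pupae <- pupae + ev[2L]
      larvae <- ev[3L]
    }
    if (day %in% exam) {
      if (day == horizon_days && blocked > 0) {
        # blocked pupae are recorded as pupal deaths at the horizon
        acc$n_death <- acc$n_death + blocked
        blocked <- 0L
      }
      if (acc$l_death + acc$l_molt > 0) {
        k <- k + 1L
        rec[[k]] <- data.frame(cage_id = cage_id, day = day, stage = "larva",
                               deaths = acc$l_death, molts = acc$l_molt,
                               stringsAsFactors = FALSE)
      }
      if (acc$n_death + acc$n_molt > 0) {
        k <- k + 1L
        rec[[k]] <- data.frame(cage_id = cage_id, day = day, stage = "pupa",
                               deaths = acc$n_death, molts = acc$n_molt,
                               stringsAsFactors = FALSE)
      }
      tot$l_death <- tot$l_death + acc$l_death
      tot$n_death <- tot$n_death + acc$n_death
      tot$n_meta <- tot$n_meta + acc$n_molt
      acc <- list(l_death = 0L, l_molt = 0L, n_death = 0L, n_molt = 0L)
    }
  }
  censored <- n_larvae - tot$l_death - tot$n_death - tot$n_meta
  intervals <- if (k == 0L) {
    data.frame(cage_id = character(0), day = integer(0), stage = character(0),
               deaths = integer(0), molts = integer(0))
  } else do.call(rbind, rec[seq_len(k)])
  list(counts = data.frame(e_meta = n_larvae, l_death = tot$l_death,
                           n_death = tot$n_death, n_meta = tot$n_meta,
                           censored = censored),
       intervals = intervals)
}

# internal: deterministic per-cage seed below 2^31, stable under cage addition
cage_seed <- function(base_seed, cage_index) {
  (as.double(base_seed) * 7919 + cage_index * 104729) %% 2147483629
}

# internal: draw one trap-water concentration for a cage
draw_concentration <- function(params, treatment) {
  if (!treatment_boosted(treatment)) return(0)
  if (stats::runif(1) < params$conc_zero_prob) return(0)
  mu <- params$conc_mean_by_condition[[treatment]]
  if (is.null(mu)) mu <- mean(unlist(params$conc_mean_by_condition))
  if (stats::runif(1) < params$outlier_prob) mu <- params$outlier_mean
  stats::rgamma(1, shape = params$conc_gamma_shape,
                rate = params$conc_gamma_shape / mu)
}

#' Simulate a complete trial
#'
#' Per cage: an overdispersed (negative-binomial) egg total; a hatch count
#' that is binomial with probability `logit^-1(logit(p_t) + u)`, where `p_t`
#' is [hatch_under_treatment()] for the cage's treatment and `u` is a
#' cage-level normal deviate of SD `sigma_cage`; two ovitrap water samples
#' drawn from a zero-augmented gamma with outlier contamination (boosted
#' cages only; all other cages get structural zeros); and a
#' [simulate_cohort()] run on the hatched larvae with the pyriproxyfen
#' inhibition implied by the mean trap concentration. Each cage uses its own
#' deterministically derived RNG substream, so adding cages never reshuffles
#' existing ones and the same seed always reproduces the same dataset.
#'
#' @param design A `sit_design` (default [canonical_design()]).
#' @param params A `sit_generator_params`.
#' @param seed Optional override of `params$seed`.
#' @return A `sit_trial_data` list: `design`, `cohorts`, `intervals`,
#'   `water`.
#' @export
simulate_trial <- function(design = canonical_design(),
                           params = generator_params(), seed = NULL) {
  stopifnot(inherits(design, "sit_design"),
            inherits(params, "sit_generator_params"))
  base_seed <- if (is.null(seed)) params$seed else as.integer(seed)
  cages <- design$cages
  coh <- vector("list", nrow(cages))
  ivl <- vector("list", nrow(cages))
  wat <- vector("list", nrow(cages))
  for (i in seq_len(nrow(cages))) {
    set.seed(cage_seed(base_seed, i))
    tr <- cages$treatment[i]
    s2f <- unname(treatment_s2f(tr))
    cp <- if (s2f > 0) params$cp_by_treatment[[tr]] else 0
    if (is.null(cp)) stop("no competitiveness value for treatment ", tr)
    p_t <- hatch_under_treatment(params$ph_control, cp, s2f)
    u <- stats::rnorm(1, 0, params$sigma_cage)
    p_cage <- stats::plogis(stats::qlogis(p_t) + u)
    eggs_total <- stats::rnbinom(1, size = params$eggs_dispersion,
                                 mu = params$eggs_per_cage_mean)
    eggs_hatched <- stats::rbinom(1, eggs_total, p_cage)
    conc <- c(draw_concentration(params, tr), draw_concentration(params, tr))
    sim <- simulate_cohort(eggs_hatched, params, conc_ppb = mean(conc),
                           cage_id = cages$cage_id[i],
                           observation_interval_days =
                             design$observation_interval_days,
                           horizon_days = design$horizon_days)
    coh[[i]] <- data.frame(cage_id = cages$cage_id[i],
                           replicate_id = cages$replicate_id[i],
                           treatment = tr,
                           eggs_total = eggs_total,
                           eggs_hatched = eggs_hatched,
                           e_meta = sim$counts$e_meta,
                           l_death = sim$counts$l_death,
                           n_death = sim$counts$n_death,
                           n_meta = sim$counts$n_meta,
                           censored = sim$counts$censored,
                           stringsAsFactors = FALSE)
    ivl[[i]] <- sim$intervals
    wat[[i]] <- data.frame(cage_id = cages$cage_id[i],
                           replicate_id = cages$replicate_id[i],
                           concentration_ppb = conc,
                           females_present = TRUE,
                           fertile_males_present = cages$n_fertile_males[i] > 0,
                           s2f = s2f,
                           dose_mg_per_200 = if (treatment_boosted(tr)) 2 else 0,
                           stringsAsFactors = FALSE)
  }
  cohorts <- validate_cohorts(do.call(rbind, coh))
  intervals <- do.call(rbind, ivl)
  rownames(cohorts) <- rownames(intervals) <- NULL
  water <- do.call(rbind, wat)
  rownames(water) <- NULL
  structure(list(design = design, cohorts = cohorts,
                 intervals = validate_intervals(intervals, design),
                 water = validate_water(water)),
            class = "sit_trial_data")
}
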