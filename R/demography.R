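#' Aggregate interval-censored stage events into per-cage counts
#'
#' Sums the interval records of each cage-cohort into the demographic
#' tallies used by the corrected emergence probability: `l_death` (larval
#' deaths), `n_death` (pupal deaths) and `n_meta` (emergences, i.e. pupal
#' molts); `censored` is whatever remains of `e_meta` by conservation.
#' Consistency is enforced day by day: the running numbers of live larvae
#' and pupae may never go negative.
#'
#' @param intervals Interval records (`cage_id`, `day`, `stage`, `deaths`,
#'   `molts`).
#' @param cohorts A cohort table carrying at least `cage_id` and `e_meta`
#'   (plus any id columns, which are passed through).
#' @param design Optional `sit_design` used to validate days.
#' @return The cohort table with `l_death`, `n_death`, `n_meta`, `censored`
#'   recomputed from the records.
#' @export
aggregate_intervals <- function(intervals, cohorts, design = NULL) {
  intervals <- validate_intervals(intervals, design)
  cohorts <- as.data.frame(cohorts)
  stopifnot(all(c("cage_id", "e_meta") %in% names(cohorts)))
  unknown <- setdiff(unique(intervals$cage_id), cohorts$cage_id)
  if (length(unknown) > 0)
    stop("interval records reference unknown cage(s): ",
         paste(unknown, collapse = ", "))
  out <- cohorts
  out$l_death <- out$n_death <- out$n_meta <- 0L
  for (j in seq_len(nrow(out))) {
    cg <- out$cage_id[j]
    rec <- intervals[intervals$cage_id == cg, , drop = FALSE]
    rec <- rec[order(rec$day), , drop = FALSE]
    larvae <- out$e_meta[j]; pupae <- 0L
    for (d in unique(rec$day)) {
      lr <- rec[rec$day == d & rec$stage == "larva", , drop = FALSE]
      pr <- rec[rec$day == d & rec$stage == "pupa", , drop = FALSE]
      l_out <- sum(lr$deaths) + sum(lr$molts)
      if (l_out > larvae)
        stop("cage ", cg, ", day ", d, ": ", l_out,
             " larval events but only ", larvae, " larvae available")
      p_out <- sum(pr$deaths) + sum(pr$molts)
      if (p_out > pupae + sum(lr$molts))
        stop("cage ", cg, ", day ", d, ": ", p_out,
             " pupal events but only ", pupae + sum(lr$molts),
             " pupae available")
      larvae <- larvae - l_out
      pupae <- pupae + sum(lr$molts) - p_out
      out$l_death[j] <- out$l_death[j] + sum(lr$deaths)
      out$n_death[j] <- out$n_death[j] + sum(pr$deaths)
      out$n_meta[j] <- out$n_meta[j] + sum(pr$molts)
    }
  }
  out$censored <- out$e_meta - out$l_death - out$n_death - out$n_meta
  out
}

#' Competing-risks-corrected emergence probability
#'
#' The plug-in estimate of the probability that a hatched larva emerges as
#' an adult, corrected for the demographic interference between molting and
#' death: each larval or pupal death removes, on average, half an
#' exposure-equivalent from the denominator, so
#' `Pa = n_meta / (e_meta - (l_death + n_death) / 2)`.
#' Individuals still immature at the horizon count as non-emergences (they
#' stay in the denominator); set `drop_censored = TRUE` to exclude them from
#' exposure instead.
#'
#' @param counts A data frame (or one-row list) with `e_meta`, `l_death`,
#'   `n_death`, `n_meta` (and `censored` if `drop_censored`).
#' @param drop_censored Exclude horizon survivors from the denominator
#'   (default `FALSE`).
#' @return Numeric vector of corrected emergence probabilities.
#' @examples
#' corrected_emergence(data.frame(e_meta = 100, l_death = 10, n_death = 6,
#'                                n_meta = 60))  # 60 / 92
#' @export
corrected_emergence <- function(counts, drop_censored = FALSE) {
  counts <- as.data.frame(counts)
  denom <- counts$e_meta - (counts$l_death + counts$n_death) / 2
  if (drop_censored) denom <- denom - counts$censored
  if (any(denom <= 0))
    stop("undefined estimate: corrected denominator <= 0 for cage(s) ",
         paste(counts$cage_id[denom <= 0], collapse = ", "))
  pa <- counts$n_meta / denom
  inconsistent <- pa > 1
  if (any(inconsistent))
    warning("corrected emergence > 1 (numerator exceeds corrected ",
            "denominator) for ", sum(inconsistent), " cohort(s); reported ",
            "unclipped", call. = FALSE)
  pa
}

#' Corrected binomial trials for the emergence fit
#'
#' The corrected denominator `e_meta - (l_death + n_death)/2` is generally
#' non-integer; for the binomial likelihood it is rounded half-to-even,
#' biasing exposure by at most half a trial. Both the raw and the integer
#' denominators are returned, along with the plug-in probability.
#'
#' @inheritParams corrected_emergence
#' @return Data frame with the cohort id columns plus `numerator`,
#'   `denominator_raw`, `denominator_int`, `pa_plugin` and a `flagged`
#'   logical marking cohorts whose numerator exceeds the integer
#'   denominator.
#' @export
corrected_trials <- function(counts, drop_censored = FALSE) {
  counts <- as.data.frame(counts)
  denom <- counts$e_meta - (counts$l_death + counts$n_death) / 2
  if (drop_censored) denom <- denom - counts$censored
  if (any(denom <= 0))
    stop("undefined estimate: corrected denominator <= 0 for cage(s) ",
         paste(counts$cage_id[denom <= 0], collapse = ", "))
  ids <- intersect(c("cage_id", "replicate_id", "treatment"), names(counts))
  out <- counts[ids]
  out$numerator <- counts$n_meta
  out$denominator_raw <- denom
  out$denominator_int <- as.integer(round(denom))  # round-half-to-even
  out$pa_plugin <- counts$n_meta / denom
  out$flagged <- out$numerator > out$denominator_int
  if (any(out$flagged))
    warning(sum(out$flagged), " cohort(s) have numerator > corrected ",
            "denominator; flagged, not clipped", call. = FALSE)
  out
}
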