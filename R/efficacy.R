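#' Plug-in Fried competitiveness index
#'
#' The competitiveness of sterile males — their capacity to mate with
#' females in the presence of fertile males — inferred from hatch
#' suppression and scaled by the release ratio:
#' `Cp = (Ph_control - Ph_i) / Ph_i * 1 / s2f`.
#'
#' @param ph_control Control hatch probability.
#' @param ph_i Treated hatch probability (> 0; a zero denominator signals a
#'   separated cohort upstream).
#' @param s2f Sterile-to-fertile male ratio (> 0).
#' @return The competitiveness index (0 when `ph_i == ph_control`).
#' @examples
#' competitiveness_plugin(0.936, 0.576, 5)  # 0.125
#' @export
competitiveness_plugin <- function(ph_control, ph_i, s2f) {
  if (any(s2f <= 0)) stop("s2f must be positive (control has no Cp)")
  if (any(ph_i <= 0))
    stop("ph_i must be positive: a zero hatch probability leaves Cp ",
         "undefined (separation-linked; see detect_separation)")
  (ph_control - ph_i) / ph_i / s2f
}

#' Posterior competitiveness summary
#'
#' Applies [competitiveness_plugin()] draw by draw to the control and
#' treatment rows of a treatment-level hatch posterior, then summarises by
#' the posterior mean and equal-tailed 95% interval. Draws where the
#' treatment probability is exactly zero are excluded with a logged count
#' (they are impossible under the logistic model, so any occurrence points
#' at an upstream bug).
#'
#' @param Th A `sit_treatment_posterior` of hatch probabilities.
#' @param treatment Treatment whose competitiveness is wanted (not
#'   `control`).
#' @param s2f Sterile-to-fertile ratio of that treatment; looked up from
#'   the label by default.
#' @param control Label of the reference rows (default `"control"`).
#' @param alpha Interval miss probability (default 0.05).
#' @return Data frame with `treatment`, `cp_mean`, `ll`, `ul`, `cp_plugin`
#'   (the index of posterior-mean probabilities) and `excluded_draws`.
#' @export
competitiveness_posterior <- function(Th, treatment,
                                      s2f = treatment_s2f(treatment),
                                      control = "control", alpha = 0.05) {
  stopifnot(inherits(Th, "sit_treatment_posterior"))
  if (identical(treatment, control))
    stop("competitiveness is undefined for the control category")
  labs <- Th$treatment_labels
  if (!control %in% labs) stop("control rows absent from the posterior")
  if (!treatment %in% labs) stop("treatment ", treatment,
                                 " absent from the posterior")
  pc <- Th$draws[match(control, labs), ]
  pi_ <- Th$draws[match(treatment, labs), ]
  drop <- pi_ <= 0
  n_drop <- sum(drop)
  if (n_drop > 0) {
    message("competitiveness_posterior: excluded ", n_drop,
            " draw(s) with zero treatment probability")
    pc <- pc[!drop]; pi_ <- pi_[!drop]
  }
  cp <- (pc - pi_) / pi_ / s2f
  qs <- stats::quantile(cp, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  data.frame(treatment = treatment, cp_mean = mean(cp),
             ll = qs[1], ul = qs[2],
             cp_plugin = competitiveness_plugin(mean(pc), mean(pi_), s2f),
             excluded_draws = n_drop, stringsAsFactors = FALSE)
}

#' Posterior matrix of emergence-from-egg probabilities
#'
#' The probability that an adult emerges from an egg is the product of the
#' hatch and the larva-to-adult probabilities; at the level of posterior
#' draw matrices this is the elementwise product `Me = Mh * Ma`, aligned by
#' row label and draw index. Misaligned labels are an error, never silently
#' reindexed.
#'
#' @param Mh,Ma `sit_posterior` objects (hatch and emergence) with
#'   identical row labels and draw counts.
#' @return A `sit_posterior` whose conditional and marginal draws are the
#'   elementwise products.
#' @export
emergence_product <- function(Mh, Ma) {
  stopifnot(inherits(Mh, "sit_posterior"), inherits(Ma, "sit_posterior"))
  if (!identical(dim(Mh$draws), dim(Ma$draws)))
    stop("posterior matrices have different shapes: ",
         paste(dim(Mh$draws), collapse = "x"), " vs ",
         paste(dim(Ma$draws), collapse = "x"))
  if (!identical(Mh$row_labels$cage_id, Ma$row_labels$cage_id) ||
      !identical(Mh$treatment, Ma$treatment))
    stop("row labels of the hatch and emergence matrices do not align")
  out <- Mh
  out$draws <- Mh$draws * Ma$draws
  out$draws_marginal <- Mh$draws_marginal * Ma$draws_marginal
  out$beta <- NULL
  out$sigma <- NULL
  out$diagnostics <- rbind(Mh$diagnostics, Ma$diagnostics)
  out$converged <- isTRUE(Mh$converged) && isTRUE(Ma$converged)
  out$flags <- c(Mh$flags, Ma$flags)
  out
}

#' Relative risks of emergence versus a reference treatment
#'
#' Draw-wise ratio `RR_i = P_i / P_ref` on a treatment-level posterior,
#' summarised by the posterior mean and equal-tailed 95% interval. The
#' reference against itself is identically 1. Draws with a zero reference
#' are excluded with a logged count.
#'
#' @param Te A `sit_treatment_posterior` (typically of emergence-from-egg
#'   probabilities).
#' @param reference Reference label (default `"control"`).
#' @param alpha Interval miss probability (default 0.05).
#' @return Data frame with one row per non-reference treatment:
#'   `treatment`, `rr_mean`, `ll`, `ul`, `rr_plugin` (ratio of posterior
#'   means), `reference`, `excluded_draws`; ordered most to least
#'   effective (ascending `rr_mean`).
#' @export
relative_risk <- function(Te, reference = "control", alpha = 0.05) {
  stopifnot(inherits(Te, "sit_treatment_posterior"))
  labs <- Te$treatment_labels
  if (!reference %in% labs) stop("reference ", reference, " not present")
  ref <- Te$draws[match(reference, labs), ]
  drop <- ref <= 0
  n_drop <- sum(drop)
  if (n_drop > 0)
    message("relative_risk: excluded ", n_drop, " draw(s) with zero ",
            "reference probability")
  out <- do.call(rbind, lapply(setdiff(labs, reference), function(tr) {
    pi_ <- Te$draws[match(tr, labs), ]
    rr <- pi_[!drop] / ref[!drop]
    qs <- stats::quantile(rr, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    data.frame(treatment = tr, rr_mean = mean(rr), ll = qs[1], ul = qs[2],
               rr_plugin = mean(pi_) / mean(ref),
               reference = reference, excluded_draws = n_drop,
               stringsAsFactors = FALSE)
  }))
  out[order(out$rr_mean), , drop = FALSE]
}

#' Posterior simulation test for a loss of efficacy
#'
#' Compares two treatments on a posterior draw scale: `delta` draws are the
#' draw-wise differences `group_a - group_b` (boosted minus non-boosted
#' when asking whether the pyriproxyfen coating costs hatch suppression).
#' The p-value is the one-sided posterior tail probability on the
#' alternative's side, ties counted as consistent: for
#' `direction = "less"` (H1: delta < 0) it is the fraction of draws with
#' `delta <= 0`; for `"greater"`, the fraction with `delta >= 0`.
#'
#' @param Th A `sit_treatment_posterior`.
#' @param group_a,group_b Treatment labels; `delta = a - b`.
#' @param B Number of draws used (default `10^4`, capped by availability).
#' @param direction Alternative hypothesis direction for `delta`
#'   (default `"less"`).
#' @return Data frame (class row) with `group_a`, `group_b`, `delta_mean`,
#'   `p_value`, `B`, `direction`.
#' @export
delta_test <- function(Th, group_a, group_b, B = 10000L,
                       direction = c("less", "greater")) {
  stopifnot(inherits(Th, "sit_treatment_posterior"))
  direction <- match.arg(direction)
  labs <- Th$treatment_labels
  if (!all(c(group_a, group_b) %in% labs))
    stop("both groups must be present in the posterior")
  n_avail <- ncol(Th$draws)
  if (B > n_avail)
    stop("B = ", B, " exceeds the ", n_avail, " available draws")
  idx <- seq_len(B)
  delta <- Th$draws[match(group_a, labs), idx] -
    Th$draws[match(group_b, labs), idx]
  p <- switch(direction,
              less = mean(delta <= 0),
              greater = mean(delta >= 0))
  data.frame(group_a = group_a, group_b = group_b,
             delta_mean = mean(delta), p_value = p, B = as.integer(B),
             direction = direction, stringsAsFactors = FALSE)
}
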