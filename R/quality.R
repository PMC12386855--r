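#' Rearing-quality indicators with the 0.70 threshold
#'
#' Estimates per-category hatch or flight-test escape probabilities from
#' batch counts, reusing the overdispersed binomial machinery with the
#' batch as the observation level. Quality is called good when the point
#' estimate exceeds 0.70 (the trial's rule); the posterior probability
#' `Pr(P > threshold)` is reported alongside for a calibrated reading.
#'
#' @param batches Data frame with `batch_id`, `category` (e.g. `fertile`,
#'   `sterile`, `boosted_sterile`, `control`), `n_total`, `n_event`
#'   (hatched eggs or escaped males).
#' @param threshold Quality threshold (default 0.70).
#' @param n_draws,seed,... Passed to [fit_binomial_mixed()].
#' @return Data frame with one row per category: `category`, `mean`, `ll`,
#'   `ul`, `pass` (point estimate above threshold), `pr_above_threshold`.
#'   The fitted posterior is attached as attribute `"posterior"`.
#' @export
quality_estimate <- function(batches, threshold = 0.70, n_draws = 4000L,
                             seed = 1L, ...) {
  batches <- as.data.frame(batches)
  req <- c("batch_id", "category", "n_total", "n_event")
  miss <- setdiff(req, names(batches))
  if (length(miss) > 0)
    stop("batch table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(batches) == 0) stop("empty batch table")
  if (any(batches$n_event < 0 | batches$n_event > batches$n_total))
    stop("need 0 <= n_event <= n_total in every batch")
  fit <- fit_binomial_mixed(batches$n_event, batches$n_total,
                            batches$category, n_draws = n_draws, seed = seed,
                            row_labels = data.frame(
                              cage_id = as.character(batches$batch_id),
                              replicate_id = NA_integer_,
                              stringsAsFactors = FALSE), ...)
  Tq <- aggregate_by_treatment(fit)
  summ <- summarize_posterior(Tq)
  names(summ)[names(summ) == "treatment"] <- "category"
  summ$pass <- summ$mean > threshold
  summ$pr_above_threshold <- apply(Tq$draws > threshold, 1, mean)
  attr(summ, "posterior") <- fit
  summ
}

#' Relative risk of quality indicators versus a reference category
#'
#' Draw-wise ratio of two aligned posterior draw vectors (shared machinery
#' with [relative_risk()]): mean and equal-tailed 95% interval of
#' `P_i / P_ref`. Zero reference draws are excluded with a logged count.
#'
#' @param p_i,p_ref Aligned numeric draw vectors.
#' @param alpha Interval miss probability (default 0.05).
#' @return Data frame with `rr_mean`, `ll`, `ul`, `excluded_draws`.
#' @export
quality_rr <- function(p_i, p_ref, alpha = 0.05) {
  if (length(p_i) != length(p_ref))
    stop("draw vectors must be aligned (same length)")
  drop <- p_ref <= 0
  n_drop <- sum(drop)
  if (n_drop > 0)
    message("quality_rr: excluded ", n_drop,
            " draw(s) with zero reference probability")
  rr <- p_i[!drop] / p_ref[!drop]
  qs <- stats::quantile(rr, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  data.frame(rr_mean = mean(rr), ll = qs[1], ul = qs[2],
             excluded_draws = n_drop)
}
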