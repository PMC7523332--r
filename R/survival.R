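#' Binarize signature expression against per-gene cohort medians
#'
#' A patient's value for a gene is 1 if its expression is equal to or
#' greater than the gene's median across all cohort patients, else 0
#' (median = midpoint of the two central order statistics for even
#' cohorts, so a constant gene is 1 everywhere). Signature genes absent
#' from the cohort are dropped with a warning, shrinking the score range
#' rather than imputing.
#'
#' @param cohort A `BulkCohort`.
#' @param signature Character vector of signature genes.
#' @return Integer 0/1 matrix patients x present signature genes.
#' @export
binarize_vs_median <- function(cohort, signature) {
  stopifnot(inherits(cohort, "BulkCohort"))
  present <- intersect(signature, colnames(cohort$expr))
  if (length(present) == 0) stop("no signature gene present in the cohort")
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present),
            " signature gene(s) absent from the cohort were dropped")
  }
  x <- cohort$expr[, present, drop = FALSE]
  med <- apply(x, 2, stats::median)
  bin <- sweep(x, 2, med, ">=") + 0L
  storage.mode(bin) <- "integer"
  bin
}

#' Per-patient signature score
#'
#' Row sums of the binarized matrix: an integer in `[0, k]` where k is
#' the number of signature genes present.
#'
#' @param bin 0/1 matrix from [binarize_vs_median()].
#' @return Named integer vector of scores.
#' @export
score_patients <- function(bin) {
  stats::setNames(as.integer(rowSums(bin)), rownames(bin))
}

#' Stratify patients into extreme score quartiles
#'
#' High = the `ceiling(n/4)` highest-scoring patients, low = the
#' `ceiling(n/4)` lowest; patients tied with the boundary score are all
#' included in the adjacent group (integer scores make boundary ties
#' common, and a deterministic inclusive rule keeps the stratification
#' auditable and invariant to monotone transforms of the score). The
#' middle patients are excluded.
#'
#' @param scores Named numeric vector of per-patient scores (n >= 8).
#' @return Named character vector over patients: "high", "low" or
#'   "excluded".
#' @export
stratify_quartiles <- function(scores) {
  n <- length(scores)
  if (n < 8) stop("need at least 8 patients to stratify")
  if (length(unique(scores)) == 1) {
    stop("all scores identical: no stratification possible")
  }
  k <- ceiling(n / 4)
  sorted <- sort(scores)
  low_cut <- sorted[k]            # k-th smallest
  high_cut <- sorted[n - k + 1]   # k-th largest
  group <- rep("excluded", n)
  names(group) <- names(scores)
  group[scores <= low_cut] <- "low"
  is_high <- scores >= high_cut
  if (any(is_high & group == "low")) {
    stop("degenerate score distribution: quartile boundaries overlap")
  }
  group[is_high] <- "high"
  group
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: subjects censored at t remain at risk for events
#' at t; survival is 1 at time 0 and non-increasing. With no censoring
#' the estimate equals the empirical survival function.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame: time, n_risk, n_event, n_censor, survival — one
#'   row per distinct observed time.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times)
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Mantel-Cox log-rank test and hazard ratio for two groups
#'
#' At each distinct event time the observed events in the high group are
#' compared with the expectation under the hypergeometric null;
#' `chi_square = (sum O1 - sum E1)^2 / sum V` with p from a 1-df
#' chi-squared distribution. The hazard ratio is the Mantel-Haenszel
#' observed/expected ratio `(O1/E1) / (O2/E2)` with group 1 = high and a
#' log-scale 95% CI `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`. A
#' partial-likelihood (Cox) HR is available as a cross-check via
#' `hr_method = "cox"`.
#'
#' @param high,low Lists with elements `times` and `events`.
#' @param hr_method "mantel-haenszel" (default) or "cox".
#' @return A `SurvivalResult` list: `km_high`, `km_low`, `chi_square`,
#'   `p_value`, `hr`, `ci95`, `o_e` (observed/expected table),
#'   `hr_method`.
#' @export
logrank_hr <- function(high, low, hr_method = c("mantel-haenszel", "cox")) {
  hr_method <- match.arg(hr_method)
  stopifnot(length(high$times) > 0, length(low$times) > 0)
  times <- c(high$times, low$times)
  events <- c(high$events, low$events)
  grp1 <- c(rep(TRUE, length(high$times)), rep(FALSE, length(low$times)))
  if (sum(events) == 0) stop("no events in either group")

  ev_times <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  o2 <- sum(events) - o1
  e2 <- sum(events) - e1
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)

  if (hr_method == "cox") {
    fit <- survival::coxph(survival::Surv(times, events) ~ grp1)
    hr <- unname(exp(stats::coef(fit)))
    ci <- unname(exp(stats::confint(fit)))
    ci95 <- c(ci[1], ci[2])
  } else {
    hr <- (o1 / e1) / (o2 / e2)
    se <- sqrt(1 / e1 + 1 / e2)
    ci95 <- exp(log(hr) + c(-1, 1) * 1.96 * se)
  }
  res <- list(km_high = kaplan_meier(high$times, high$events),
              km_low = kaplan_meier(low$times, low$events),
              chi_square = chi, p_value = p, hr = hr, ci95 = ci95,
              o_e = data.frame(group = c("high", "low"),
                               observed = c(o1, o2), expected = c(e1, e2)),
              hr_method = hr_method)
  class(res) <- "SurvivalResult"
  res
}

#' @export
print.SurvivalResult <- function(x, ...) {
  cat(sprintf("Log-rank chi-square = %.4g, p = %.4g\nHR (%s) = %.4g [%.4g, %.4g]\n",
              x$chi_square, x$p_value, x$hr_method, x$hr,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Signature-score survival analysis of a bulk cohort
#'
#' The full procedure: binarize each signature gene against its cohort
#' median, sum to a per-patient integer score, stratify into the extreme
#' score quartiles, and compare overall survival of the high and low
#' groups by Kaplan-Meier and the Mantel-Cox log-rank test with a
#' Mantel-Haenszel hazard ratio. Middle-half patients never enter the
#' comparison.
#'
#' @param cohort A `BulkCohort`.
#' @param signature Character vector of signature genes.
#' @param hr_method Passed to [logrank_hr()].
#' @return A `SurvivalResult` with audit fields `scores` and `groups`
#'   attached.
#' @export
signature_survival <- function(cohort, signature,
                               hr_method = c("mantel-haenszel", "cox")) {
  bin <- binarize_vs_median(cohort, signature)
  scores <- score_patients(bin)
  groups <- stratify_quartiles(scores)
  clin <- cohort$clinical
  hi <- groups == "high"
  lo <- groups == "low"
  res <- logrank_hr(
    high = list(times = clin$os_time[hi], events = clin$os_event[hi]),
    low = list(times = clin$os_time[lo], events = clin$os_event[lo]),
    hr_method = hr_method)
  res$scores <- scores
  res$groups <- groups
  res
}
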