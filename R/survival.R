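# Median-split Kaplan-Meier screen: for each feature, split the analyzed
# subjects at the feature's median (at-or-below versus above; subjects
# exactly at the median go to the lower group), compare the TTT curves by
# the two-group log-rank test, and Benjamini-Hochberg-adjust across the
# screened features. By default only subjects who actually started
# treatment enter the screen (all-event data); right-censoring is supported
# for general use. The product-limit and log-rank machinery is the standard
# one from the survival package.

#' Kaplan-Meier product-limit curve
#'
#' @param times event/censoring times (> 0).
#' @param events logical, TRUE = event observed.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`: the product-limit estimate at each distinct time.
#' @export
kmCurve <- function(times, events) {
  if (!length(times)) stop("empty input", call. = FALSE)
  stopifnot(all(times > 0), length(times) == length(events))
  sf <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed minus expected events with
#' hypergeometric variance), referred to chi-square with 1 df.
#'
#' @param timesA,eventsA,timesB,eventsB the two groups.
#' @return list with `chisq`, `p_value`, `n` (group sizes).
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB))
    stop("both groups must be nonempty", call. = FALSE)
  ev <- c(as.logical(eventsA), as.logical(eventsB))
  if (!any(ev)) stop("no events: log-rank test undefined", call. = FALSE)
  grp <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(
    survival::Surv(c(timesA, timesB), ev) ~ grp)
  list(chisq = sd$chisq, p_value = pchisq(sd$chisq, df = 1,
                                          lower.tail = FALSE),
       n = c(A = length(timesA), B = length(timesB)))
}

#' Median-split Kaplan-Meier feature screen
#'
#' @param fs a [RadiomicFeatureSet-class] with outcome.
#' @param treatedOnly analyze only subjects with `event = TRUE` (default),
#'   mirroring a screen restricted to patients who started treatment.
#' @param alpha FDR significance level.
#' @return data.frame, one row per feature: `feature`, `cutpoint` (the
#'   median), `n_low`, `n_high`, `chisq`, `p_raw`, `p_adj`, `significant`,
#'   `skipped` (degenerate split, e.g. a heavily tied feature). Adjustment
#'   spans the non-skipped features.
#' @export
medianSplitScreen <- function(fs, treatedOnly = TRUE, alpha = 0.05) {
  stopifnot(is(fs, "RadiomicFeatureSet"))
  oc <- outcomeTable(fs)
  keep <- if (treatedOnly) oc$event else rep(TRUE, nrow(oc))
  if (sum(keep) < 4L)
    stop("need at least 4 analyzed subjects", call. = FALSE)
  X <- featureMatrix(fs)[, keep, drop = FALSE]
  times <- oc$ttt_months[keep]; events <- oc$event[keep]
  res <- lapply(rownames(X), function(f) {
    v <- X[f, ]
    med <- median(v)
    high <- v > med
    if (sum(high) < 2L || sum(!high) < 2L) {
      warning("feature '", f, "' skipped: degenerate median split",
              call. = FALSE)
      return(data.frame(feature = f, cutpoint = med,
                        n_low = sum(!high), n_high = sum(high),
                        chisq = NA_real_, p_raw = NA_real_,
                        skipped = TRUE))
    }
    lr <- logrankTest(times[!high], events[!high], times[high], events[high])
    data.frame(feature = f, cutpoint = med, n_low = sum(!high),
               n_high = sum(high), chisq = lr$chisq, p_raw = lr$p_value,
               skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[!out$skipped] <- adjustFdr(out$p_raw[!out$skipped])
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Kaplan-Meier curves of a median split
#'
#' Convenience for plotting/reporting: the two product-limit curves for
#' one feature's median split.
#'
#' @param fs a [RadiomicFeatureSet-class] with outcome.
#' @param feature feature name.
#' @param treatedOnly as in [medianSplitScreen()].
#' @return data.frame with columns `group` ("low"/"high"), `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
medianSplitCurves <- function(fs, feature, treatedOnly = TRUE) {
  oc <- outcomeTable(fs)
  keep <- if (treatedOnly) oc$event else rep(TRUE, nrow(oc))
  v <- featureMatrix(fs)[feature, keep]
  high <- v > median(v)
  times <- oc$ttt_months[keep]; events <- oc$event[keep]
  rbind(cbind(group = "low", kmCurve(times[!high], events[!high])),
        cbind(group = "high", kmCurve(times[high], events[high])))
}
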