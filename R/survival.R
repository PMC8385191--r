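## Kaplan-Meier estimation and log-rank testing of survival stratified
## by subtype.  The product-limit and score machinery is delegated to
## the survival package; this layer enforces the module's contracts and
## returns tidy per-group curves.

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator per group; censored subjects leave the risk
#' set at their censoring time (and, when tied with an event time,
#' remain at risk for the events at that time).
#'
#' @param times non-negative follow-up times
#' @param events logical (or 0/1) event indicators
#' @param groups group label per subject
#' @return data.frame with columns group, time, survival, at_risk,
#'   n_event, n_censor; each group's curve starts at S(0) = 1
#' @export
kmEstimate <- function(times, events, groups) {
    stopifnot(length(times) == length(events),
              length(times) == length(groups))
    if (any(times < 0)) stop("negative follow-up time")
    events <- as.logical(events)
    if (!length(groups) || (is.factor(groups) && any(table(groups) == 0L)))
        stop("empty group")
    groups <- as.character(groups)
    fit <- survival::survfit(
        survival::Surv(times, events) ~ group,
        data = data.frame(times = times, events = events, group = groups))
    strata <- if (is.null(fit$strata))
        rep(unique(groups)[1L], length(fit$time))
    else rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- data.frame(group = strata, time = fit$time,
                      survival = fit$surv, at_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      row.names = NULL)
    anchor <- data.frame(group = unique(out$group), time = 0,
                         survival = 1,
                         at_risk = as.vector(table(groups)[unique(out$group)]),
                         n_event = 0L, n_censor = 0L)
    out <- rbind(anchor, out)
    out[order(match(out$group, unique(groups)), out$time), , drop = FALSE]
}

#' K-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with k - 1 degrees of
#' freedom; the p-value comes from the chi-square upper tail.
#'
#' @inheritParams kmEstimate
#' @return list with chi_square, df, p_value
#' @export
logrankTest <- function(times, events, groups) {
    events <- as.logical(events)
    if (length(unique(groups)) < 2L) stop("need >= 2 groups")
    if (!any(events)) stop("log-rank test needs at least one event")
    sd <- survival::survdiff(
        survival::Surv(times, events) ~ group,
        data = data.frame(times = times, events = events, group = groups))
    df <- length(sd$n) - 1L
    list(chi_square = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Per-group censoring percentages
#'
#' Fraction of subjects without an event in each group, on the percent
#' scale.
#'
#' @inheritParams kmEstimate
#' @return named numeric vector of percent censored per group
#' @export
censoringSummary <- function(times, events, groups) {
    stopifnot(length(times) == length(events),
              length(times) == length(groups))
    events <- as.logical(events)
    cens <- tapply(!events, groups, mean)
    stats::setNames(100 * as.numeric(cens), names(cens))
}

#' Survival analysis of a called cohort
#'
#' Joins subtype calls with clinical follow-up and runs the KM/log-rank
#' stratification; unclassified samples are dropped with a message.
#'
#' @param calls \linkS4class{SubtypeCallSet} or named label vector
#' @param clinical clinical data.frame (sample_id, followup_time,
#'   event_death, event_bc)
#' @param event \code{"os"} for overall survival (death from any cause)
#'   or \code{"bc"} for the breast-cancer-specific composite event
#' @return list with curves (from \code{\link{kmEstimate}}), logrank
#'   (from \code{\link{logrankTest}}) and censoring (percent per group)
#' @export
survivalBySubtype <- function(calls, clinical, event = c("os", "bc")) {
    event <- match.arg(event)
    labels <- .labelsOf(calls)
    clinical <- clinical[match(names(labels), clinical$sample_id), ]
    if (anyNA(clinical$sample_id))
        stop("clinical record missing for some called samples")
    keep <- labels != UNCLASSIFIED
    if (any(!keep))
        message(sum(!keep), " unclassified sample(s) dropped from survival analysis")
    ev <- if (event == "os") clinical$event_death else clinical$event_bc
    list(curves = kmEstimate(clinical$followup_time[keep], ev[keep],
                             labels[keep]),
         logrank = logrankTest(clinical$followup_time[keep], ev[keep],
                               labels[keep]),
         censoring = censoringSummary(clinical$followup_time[keep],
                                      ev[keep], labels[keep]))
}
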