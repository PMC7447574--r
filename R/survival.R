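#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function under right censoring,
#' computed with \pkg{survival}. The curve starts at 1, is non-increasing,
#' and drops only at observed event times (ties between events and
#' censorings at the same time: events precede censorings in the risk
#' set, the standard convention).
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return A \code{km_estimate}: data frame with columns \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{survival}, one
#'   row per distinct observed time.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop_("need at least one observation")
  if (any(!is.finite(times)) || any(times < 0))
    stop_("times must be finite and non-negative")
  if (!all(events %in% c(0, 1))) stop_("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d time points, %d events, final S = %.3f\n",
              nrow(x), sum(x$n_event), x$survival[nrow(x)]))
  invisible(x)
}

## Evaluate the KM step function at arbitrary times (right-continuous).
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (!length(idx)) 1 else km$survival[max(idx)]
  }, 0)
}

## Median survival: smallest time with S(t) <= 0.5; NA if never reached.
km_median <- function(km) {
  idx <- which(km$survival <= 0.5)
  if (!length(idx)) NA_real_ else km$time[min(idx)]
}

## Restricted mean survival time: area under the KM curve up to `horizon`.
km_rmst <- function(km, horizon) {
  keep <- km$time < horizon
  knots <- c(0, km$time[keep], horizon)
  s <- c(1, km$survival[keep])  # S on each inter-knot interval
  sum(diff(knots) * s)
}

#' Two-group log-rank test
#'
#' Compares the survival experience of two groups: at each distinct event
#' time the observed number of events in group 1 is compared with its
#' hypergeometric expectation given the risk sets, and the statistic
#' \eqn{(\sum O - E)^2 / \sum V} is referred to a chi-square distribution
#' with one degree of freedom (two-sided). Computed with
#' \code{survival::survdiff}.
#'
#' @param times,events As in \code{\link{km_estimate}}.
#' @param groups 0/1 (or two-level) group membership, both groups
#'   non-empty.
#' @return List with \code{statistic}, \code{p_value} and \code{df}.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(!is.finite(times)) || any(times < 0))
    stop_("times must be finite and non-negative")
  if (!all(events %in% c(0, 1))) stop_("events must be 0/1")
  g <- as.integer(factor(groups))
  if (length(unique(g)) != 2L)
    stop_("log-rank test requires exactly two non-empty groups")
  if (sum(events) == 0L)
    stop_("log-rank test undefined: no events observed")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Map two clusters to Low/High risk groups
#'
#' The cluster with the smaller Kaplan-Meier median survival is labelled
#' High risk (1); when a median is undefined for either cluster, the
#' restricted mean survival time up to the largest observed time is used
#' instead. Identical survival gives the deterministic tie-break: the
#' first cluster index is Low.
#'
#' @param cluster_result A \code{cluster_result} with k = 2.
#' @param clinical Clinical data frame (sample_id, time, event) covering
#'   the clustered samples.
#' @return List with \code{mapping} (named vector cluster -> 0 Low / 1
#'   High), \code{risk_group} (per-sample 0/1 named by sample ID) and the
#'   per-cluster summary used for the decision.
#' @export
assign_risk_groups <- function(cluster_result, clinical) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  if (cluster_result$k != 2L)
    stop_("risk-group assignment is defined for k = 2 (got k = %d)",
          cluster_result$k)
  validate_clinical(clinical)
  ids <- names(cluster_result$labels)
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) stop_("clinical table does not cover all clustered samples")
  cl <- clinical[idx, ]
  horizon <- max(cl$time)
  summ <- lapply(1:2, function(c) {
    sel <- cluster_result$labels == c
    km <- km_estimate(cl$time[sel], cl$event[sel])
    list(median = km_median(km), rmst = km_rmst(km, horizon))
  })
  med <- vapply(summ, `[[`, 0, "median")
  score <- if (anyNA(med)) vapply(summ, `[[`, 0, "rmst") else med
  ## smaller survival -> High (1); ties -> cluster 1 Low
  high <- if (score[2] < score[1]) 2L else if (score[1] < score[2]) 1L else 2L
  mapping <- c(`1` = as.integer(high == 1L), `2` = as.integer(high == 2L))
  risk <- mapping[as.character(cluster_result$labels)]
  names(risk) <- ids
  list(mapping = mapping, risk_group = risk,
       cluster_summary = data.frame(cluster = 1:2, median = med,
                                    rmst = vapply(summ, `[[`, 0, "rmst")))
}

#' Write Kaplan-Meier step tables per group
#'
#' One CSV row per distinct time per group; columns group, time, n_risk,
#' n_event, n_censor, survival.
#'
#' @param times,events As in \code{\link{km_estimate}}.
#' @param groups Group labels.
#' @param path Output CSV path.
#' @export
write_km_tables <- function(times, events, groups, path) {
  tabs <- lapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    cbind(group = g, as.data.frame(km_estimate(times[sel], events[sel])))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
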