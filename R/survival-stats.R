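#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function under right
#' censoring, computed via \code{\link[survival]{survfit}}.
#'
#' @param time positive survival/censoring times (days).
#' @param event 0 = censored, 1 = death.
#' @return list of class \code{"KMEstimate"} with the event-time grid,
#'   survival probabilities, numbers at risk and event counts.
#' @seealso \code{\link{survProb}} to evaluate the step function.
#' @export
kmEstimate <- function(time, event) {
    if (length(time) == 0L) stop("no survival records supplied")
    stopifnot(length(time) == length(event), all(time > 0),
              all(event %in% c(0, 1)))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                   n_event = fit$n.event),
              class = "KMEstimate")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a \code{"KMEstimate"}.
#' @param t times at which to evaluate.
#' @return survival probabilities; 1 before the first observed time
#'   (the estimate starts at 1 and is non-increasing).
#' @export
survProb <- function(km, t) {
    vapply(t, function(tt) {
        i <- which(km$time <= tt)
        if (length(i)) km$surv[max(i)] else 1
    }, numeric(1))
}

#' @export
print.KMEstimate <- function(x, ...) {
    cat("Kaplan-Meier estimate over", length(x$time), "time points;",
        "final S(t) =", signif(x$surv[length(x$surv)], 4), "\n")
    invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD; the log-rank covariance can be
# singular when a group leaves the risk set immediately
.pinv <- function(m, tol = 1e-10) {
    s <- svd(m)
    pos <- s$d > tol * max(s$d, 0)
    if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
    s$v[, pos, drop = FALSE] %*%
        (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' k-sample log-rank test
#'
#' Tests equality of survival curves across k groups with the standard
#' log-rank chi-square: at each distinct event time the observed
#' per-group event counts are compared with their hypergeometric
#' expectation given the risk sets, tied events handled with the
#' hypergeometric variance correction, and the summed observed-minus-
#' expected vector is standardised by its covariance (df = k - 1).
#'
#' @param time positive survival/censoring times.
#' @param event 0 = censored, 1 = death.
#' @param groups group labels (>= 2 nonempty groups); samples with a
#'   missing label are dropped.
#' @return list of class \code{"LogrankResult"} with \code{statistic},
#'   \code{df}, \code{p_value}, and the per-group observed and expected
#'   event counts.
#' @export
logrankTest <- function(time, event, groups) {
    stopifnot(length(time) == length(event), length(time) == length(groups))
    keep <- !is.na(groups) & !is.na(time) & !is.na(event)
    time <- time[keep]; event <- event[keep]
    g <- factor(groups[keep])
    g <- droplevels(g)
    k <- nlevels(g)
    if (k < 2L) stop("log-rank test needs at least 2 nonempty groups")
    stopifnot(all(time > 0), all(event %in% c(0, 1)))
    etimes <- sort(unique(time[event == 1]))
    O <- E <- setNames(numeric(k), levels(g))
    V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
    for (t0 in etimes) {
        at <- time >= t0
        n <- sum(at)
        if (n < 2L) next
        nj <- vapply(levels(g), function(l) sum(at & g == l), numeric(1))
        dj <- vapply(levels(g), function(l)
            sum(at & g == l & time == t0 & event == 1), numeric(1))
        d <- sum(dj)
        if (d == 0) next
        O <- O + dj
        E <- E + d * nj / n
        fac <- d * (n - d) / (n - 1)
        V <- V + fac * (diag(nj / n, k) - tcrossprod(nj / n))
    }
    u <- (O - E)[-k]
    stat <- drop(t(u) %*% .pinv(V[-k, -k, drop = FALSE]) %*% u)
    stat <- max(stat, 0)
    structure(list(statistic = stat, df = k - 1L,
                   p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
                   observed = O, expected = E),
              class = "LogrankResult")
}

#' @export
print.LogrankResult <- function(x, ...) {
    cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
                x$statistic, x$df, x$p_value))
    invisible(x)
}

#' Export Kaplan-Meier curves per group as a tidy table
#'
#' @param time,event,groups as in \code{\link{logrankTest}}.
#' @return data.frame with columns \code{group}, \code{time},
#'   \code{survival}, \code{n_risk}, \code{n_event}.
#' @export
kmTable <- function(time, event, groups) {
    g <- factor(groups)
    do.call(rbind, lapply(levels(g), function(l) {
        km <- kmEstimate(time[g == l], event[g == l])
        data.frame(group = l, time = km$time, survival = km$surv,
                   n_risk = km$n_risk, n_event = km$n_event,
                   stringsAsFactors = FALSE)
    }))
}
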