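# Marker evaluation: ROC/AUC for two-class discrimination, median
# dichotomization, Kaplan-Meier curves, the log-rank test with an
# observed/expected hazard-ratio summary, and hypergeometric
# over-representation analysis against GMT gene sets.

#' ROC curve and AUC for a two-class score
#'
#' Sweeps every distinct score as a threshold (predicting "positive"
#' at or above it), reports the (FPR, TPR) curve, and computes the AUC
#' by the trapezoid rule — identical, ties counted 1/2, to the
#' Mann-Whitney rank statistic. Significance against AUC = 0.5 uses the
#' tie-corrected normal approximation to that rank statistic.
#'
#' @param score Numeric score per sample (higher = more "positive").
#' @param label Binary labels (1 = positive class, e.g. tumor); both
#'   classes must be present.
#' @return List: `auc`, `p` (two-sided vs 0.5), `curve` (data frame
#'   `threshold`, `fpr`, `tpr`; the first row is the "call nothing"
#'   corner).
#' @export
roc_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop_input("`label` must be binary 0/1")
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0 || n0 == 0) stop_input("both classes must be present")

  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & label == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & label == 0L) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)

  # Normal approximation to the Mann-Whitney U with tie correction.
  n <- n1 + n0
  r <- rank(score)
  u <- sum(r[label == 1L]) - n1 * (n1 + 1) / 2
  ties <- table(score)
  sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - n1 * n0 / 2) / sqrt(sigma2)
  list(auc = auc, p = 2 * stats::pnorm(-abs(z)), curve = curve)
}

#' Dichotomize a sample vector at its median
#'
#' High = strictly above the median; ties at the median go to "low".
#'
#' @param values Numeric vector (length >= 2, not all identical).
#' @return Integer vector: 1 = high, 0 = low, named like `values`.
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2) stop_input("need at least 2 values")
  if (length(unique(values)) == 1) {
    stop_input("all values identical: no median split possible")
  }
  m <- stats::median(values)
  out <- as.integer(values > m)
  names(out) <- names(values)
  out
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator per group with the median survival time
#' (smallest time at which the estimate drops to 0.5 or below, `NA` if
#' never reached).
#'
#' @param records Data frame (`time`, `event`, `group`); `time >= 0`.
#' @return List: `table` (data frame `group`, `time`, `n_risk`,
#'   `n_event`, `survival`) and `median` (named numeric per group).
#' @export
km_curve <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  if (any(records$time < 0)) stop_input("survival times must be >= 0")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = records
  )
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(as.character(records$group[1]), length(sm$time))
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  tab <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, survival = sm$surv,
                    stringsAsFactors = FALSE)
  med <- vapply(split(tab, tab$group), function(d) {
    hit <- d$time[d$survival <= 0.5]
    if (length(hit) == 0) NA_real_ else min(hit)
  }, numeric(1))
  list(table = tab, median = med)
}

#' Two-group log-rank test with observed/expected hazard ratio
#'
#' Tallies observed and expected events per group over the pooled event
#' times; `chi2 = (O1 - E1)^2 / E1 + (O0 - E0)^2 / E0` with 1 df. The
#' hazard ratio of group 1 vs group 0 is `(O1 / E1) / (O0 / E0)` with
#' `exp(log HR +- 1.96 sqrt(1/E1 + 1/E0))` as the 95% CI — the summary a
#' two-curve comparison supports without fitting a regression model.
#'
#' @param records Data frame (`time`, `event`, `group` with two levels,
#'   at least one event).
#' @return List: `chi2`, `p`, `hazard_ratio`, `hr_ci` (length 2),
#'   `observed`, `expected` (named per group).
#' @export
logrank <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  groups <- sort(unique(records$group))
  if (length(groups) != 2) stop_input("exactly two groups are required")
  if (sum(records$event) == 0) stop_input("no events observed")
  g1 <- records$group == groups[2]

  event_times <- sort(unique(records$time[records$event == 1]))
  o <- c(0, 0)   # observed events: group0, group1
  e <- c(0, 0)   # expected under the null
  for (t in event_times) {
    at_risk <- records$time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(records$time == t & records$event == 1)
    d1_t <- sum(records$time == t & records$event == 1 & g1)
    o <- o + c(d_t - d1_t, d1_t)
    e <- e + d_t * c(n_t - n1_t, n1_t) / n_t
  }
  chi2 <- sum((o - e)^2 / e)
  hr <- (o[2] / e[2]) / (o[1] / e[1])
  se_log <- sqrt(1 / e[1] + 1 / e[2])
  names(o) <- names(e) <- as.character(groups)
  list(
    chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    hazard_ratio = hr,
    hr_ci = exp(log(hr) + c(-1.96, 1.96) * se_log),
    observed = o, expected = e
  )
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query list within
#' the background universe (upper-tail hypergeometric), with
#' Benjamini-Hochberg FDR across sets. Results are ranked by descending
#' overlap count, then ascending p.
#'
#' @param query Character vector of genes of interest; must be a subset
#'   of `background`.
#' @param background Character vector: the gene universe.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]);
#'   members outside the background are ignored.
#' @param ease If `TRUE`, apply the conservative EASE variant that
#'   subtracts 1 from each overlap before testing (default `FALSE`).
#' @return Data frame (`set`, `set_size`, `count`, `p`, `bh_fdr`).
#' @export
ora <- function(query, background, sets, ease = FALSE) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  check_flag(ease, "ease")
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    stop_input("query gene(s) outside the background: ",
               paste(utils::head(outside, 5), collapse = ", "))
  }
  stopifnot(is.list(sets))
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(as.character(sets[[nm]])), background)
    k <- length(intersect(query, members))
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1, length(members), n_bg - length(members),
                       n_q, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(members), count = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), set_size = integer(0),
                      count = integer(0), p = numeric(0),
                      bh_fdr = numeric(0)))
  }
  out$bh_fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$count, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
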