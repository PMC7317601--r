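# Standardized-mean-difference meta-analysis: Hedges' g per study,
# inverse-variance fixed-effect and DerSimonian-Laird random-effects
# pooling, Cochran's Q / I-squared heterogeneity, the usual
# model-selection rule (random if p_Q < 0.05 or I2 > 50%), and Egger's
# regression test for funnel-plot asymmetry.

#' Per-study standardized mean difference (Hedges' g)
#'
#' Cohen's d = (mean_case - mean_control) / s_pooled, corrected for
#' small-sample bias with J = 1 - 3 / (4 (n1 + n2 - 2) - 1), giving
#' g = J * d with variance
#' var_g = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2)).
#'
#' @param study List with `study_id`, `case` and `control` numeric
#'   vectors (each length >= 2), or the equivalent of a
#'   [generate_multi_study()] element.
#' @return One-row data frame (`study_id`, `g`, `var_g`, `n_case`,
#'   `n_control`).
#' @export
study_smd <- function(study) {
  stopifnot(is.list(study), !is.null(study$case), !is.null(study$control))
  x <- as.numeric(study$case)
  y <- as.numeric(study$control)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_input("both groups need at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_input("pooled SD is zero in study ", study$study_id)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  data.frame(
    study_id = if (is.null(study$study_id)) NA_character_ else study$study_id,
    g = g,
    var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)),
    n_case = n1, n_control = n2,
    stringsAsFactors = FALSE
  )
}

#' Standardized mean differences for a list of studies
#'
#' @param studies List of study tables (see [study_smd()]).
#' @return Data frame with one row per study.
#' @export
study_smd_all <- function(studies) {
  do.call(rbind, lapply(studies, study_smd))
}

# Summary-level SMD (Hedges' g) from n/mean/sd per group; lets
# summary-only TSV input enter the same pooling path.
smd_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                             study_id = NA_character_) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_input("pooled SD is zero")
  d <- (mean1 - mean2) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  data.frame(study_id = study_id, g = g,
             var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)),
             n_case = n1, n_control = n2, stringsAsFactors = FALSE)
}

check_effects <- function(effects, min_n = 2L) {
  stopifnot(is.data.frame(effects), all(c("g", "var_g") %in% names(effects)))
  if (nrow(effects) < min_n) {
    stop_input("need at least ", min_n, " studies")
  }
  if (any(effects$var_g <= 0)) stop_input("all `var_g` must be positive")
  effects
}

# Q, tau2 and I2 from inverse-variance weights (DerSimonian-Laird).
heterogeneity <- function(effects) {
  w <- 1 / effects$var_g
  pooled_f <- sum(w * effects$g) / sum(w)
  q <- sum(w * (effects$g - pooled_f)^2)
  df <- nrow(effects) - 1L
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_dl)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(Q = q, df = df, p_Q = stats::pchisq(q, df, lower.tail = FALSE),
       I2 = i2, tau2 = tau2)
}

meta_result <- function(pooled, se, model, het) {
  structure(list(
    pooled = pooled, se = se,
    ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
    p = 2 * stats::pnorm(-abs(pooled / se)),
    model = model,
    Q = het$Q, df = het$df, p_Q = het$p_Q, I2 = het$I2, tau2 = het$tau2
  ), class = "meta_result")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pooled effect `sum(w g) / sum(w)` with `w = 1 / var_g`, standard
#' error `1 / sqrt(sum(w))`, and a 95% normal CI.
#'
#' @param effects Data frame from [study_smd_all()] (columns `g`,
#'   `var_g`).
#' @return A `meta_result` list (`pooled`, `se`, `ci_low`, `ci_high`,
#'   `p`, `model`, `Q`, `df`, `p_Q`, `I2`, `tau2`).
#' @export
pool_fixed <- function(effects) {
  check_effects(effects)
  w <- 1 / effects$var_g
  meta_result(sum(w * effects$g) / sum(w), 1 / sqrt(sum(w)),
              "fixed", heterogeneity(effects))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, then pooling
#' with weights `w* = 1 / (var_g + tau2)`.
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` list; `tau2 = 0` makes it coincide with
#'   [pool_fixed()].
#' @export
pool_random <- function(effects) {
  check_effects(effects)
  het <- heterogeneity(effects)
  w <- 1 / (effects$var_g + het$tau2)
  meta_result(sum(w * effects$g) / sum(w), 1 / sqrt(sum(w)),
              "random", het)
}

#' Heterogeneity-driven model selection
#'
#' Random effects if `p_Q < p_cut` OR `I2 > i2_cut`; fixed otherwise.
#'
#' @param het A `meta_result` or any list with `p_Q` and `I2`.
#' @param p_cut Heterogeneity p cutoff (default 0.05).
#' @param i2_cut I-squared percentage cutoff (default 50).
#' @return `"random"` or `"fixed"`.
#' @export
select_model <- function(het, p_cut = 0.05, i2_cut = 50) {
  stopifnot(!is.null(het$p_Q), !is.null(het$I2))
  if (het$p_Q < p_cut || het$I2 > i2_cut) "random" else "fixed"
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standard normal deviate `g / se` on precision `1 / se`;
#' the intercept estimates funnel asymmetry, tested two-sided against 0.
#' Asymmetry is flagged at `p < alpha` (conventionally 0.1).
#'
#' @param effects Data frame with `g` and `var_g` for at least 3
#'   studies.
#' @param alpha Asymmetry flag level (default 0.1).
#' @return List (`intercept`, `se`, `p`, `asymmetric`).
#' @export
egger_test <- function(effects, alpha = 0.1) {
  check_effects(effects, min_n = 3L)
  se <- sqrt(effects$var_g)
  fit <- stats::lm(I(effects$g / se) ~ I(1 / se))
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm[1, 1]), se = unname(sm[1, 2]),
       p = unname(sm[1, 4]), asymmetric = unname(sm[1, 4]) < alpha)
}

#' Full SMD meta-analysis of a study list
#'
#' Computes per-study Hedges' g, both pooling models, applies the
#' model-selection rule, and (with >= 3 studies) Egger's test.
#'
#' @param studies List of study tables (see [study_smd()]).
#' @param p_cut,i2_cut Model-selection cutoffs (see [select_model()]).
#' @param egger_alpha Egger asymmetry flag level.
#' @return List: `effects` (per-study table with 95% CIs and weight
#'   percentages under the selected model), `fixed`, `random`,
#'   `selected` (the chosen `meta_result`), `model`, `egger`.
#' @export
meta_analyze <- function(studies, p_cut = 0.05, i2_cut = 50,
                         egger_alpha = 0.1) {
  effects <- study_smd_all(studies)
  fixed <- pool_fixed(effects)
  random <- pool_random(effects)
  model <- select_model(random, p_cut, i2_cut)
  selected <- if (model == "random") random else fixed
  w <- if (model == "random") {
    1 / (effects$var_g + random$tau2)
  } else {
    1 / effects$var_g
  }
  effects$ci_low <- effects$g - 1.96 * sqrt(effects$var_g)
  effects$ci_high <- effects$g + 1.96 * sqrt(effects$var_g)
  effects$weight_pct <- 100 * w / sum(w)
  egger <- if (nrow(effects) >= 3) egger_test(effects, egger_alpha) else NULL
  list(effects = effects, fixed = fixed, random = random,
       selected = selected, model = model, egger = egger)
}
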