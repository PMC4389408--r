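## Survival and group-comparison statistics used throughout cluster
## annotation; thin, validated surfaces over `survival` and base `stats`.

validate_survival <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and > 0")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group; censoring at tied times is handled
#' after events (the standard convention).
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param groups Group label per subject (single group when omitted).
#' @return Data.frame (group, time, n_risk, n_event, survival); survival
#'   starts at 1 and is non-increasing within a group.
#' @export
kaplan_meier <- function(time, event, groups = rep("all", length(time))) {
  validate_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = as.factor(groups)))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(as.factor(groups))[1L], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             stringsAsFactors = FALSE)
}

#' Logrank test across groups
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param groups Group labels (2 or more levels).
#' @return List (statistic, df, p_value). With no events at all the
#'   statistic is 0 and p = 1.
#' @export
logrank_test <- function(time, event, groups) {
  validate_survival(time, event)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("at least two groups required")
  if (sum(event) == 0) {
    return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = groups))
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. With
#' `scale = "per_sd"` the covariate is divided by its standard deviation
#' first, so the hazard ratio is per one SD of the covariate.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (>= 2 events required).
#' @param covariate Numeric covariate, one value per subject.
#' @param scale `"per_sd"` (default) or `"per_unit"`.
#' @return A `CoxFit` list: hazard_ratio, ci95 (length-2), p_value,
#'   log_hr, se, scale, converged.
#' @export
cox_univariate <- function(time, event, covariate,
                           scale = c("per_sd", "per_unit")) {
  scale <- match.arg(scale)
  validate_survival(time, event)
  if (sum(event) < 2) stop("at least 2 events required")
  if (stats::sd(covariate) == 0) stop("covariate does not vary")
  x <- if (scale == "per_sd") covariate / stats::sd(covariate) else covariate
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"))
      attr(f, "warned") <- conditionMessage(w)
      f
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  structure(list(hazard_ratio = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 log_hr = beta, se = se, scale = scale,
                 converged = is.null(attr(fit, "warned"))),
            class = "CoxFit")
}

#' Group comparison tests used for cluster annotation
#'
#' Dispatches the three comparison kinds used to annotate clusters:
#' `anova_tukey` (one-way ANOVA F-test plus Tukey HSD pairwise adjusted
#' p-values) for a numeric outcome across groups, `fisher_exact` for an
#' r x c contingency table, and `pearson_cor` for two paired numeric
#' vectors (r plus its t-based p-value).
#'
#' @param kind One of `"anova_tukey"`, `"fisher_exact"`, `"pearson_cor"`.
#' @param values Numeric outcome (anova_tukey) or first vector
#'   (pearson_cor).
#' @param groups Group labels (anova_tukey).
#' @param table Contingency matrix (fisher_exact).
#' @param values2 Second vector (pearson_cor).
#' @return A list of test summaries, by kind:
#'   anova_tukey: p_value, f_statistic, tukey (pairwise data.frame);
#'   fisher_exact: p_value;
#'   pearson_cor: r, p_value.
#' @export
group_compare <- function(kind = c("anova_tukey", "fisher_exact", "pearson_cor"),
                          values = NULL, groups = NULL, table = NULL,
                          values2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "anova_tukey") {
    groups <- as.factor(groups)
    if (nlevels(groups) < 2) stop("need at least two groups")
    if (any(tapply(values, groups, length) < 2)) {
      stop("each group needs at least 2 values")
    }
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$groups
    list(kind = kind, f_statistic = tab$`F value`[1L],
         p_value = tab$`Pr(>F)`[1L],
         tukey = data.frame(comparison = rownames(tk),
                            difference = tk[, "diff"],
                            p_adjusted = tk[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE))
  } else if (kind == "fisher_exact") {
    table <- as.matrix(table)
    if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
      stop("contingency table has a zero margin")
    }
    list(kind = kind, p_value = stats::fisher.test(table)$p.value)
  } else {
    if (stats::sd(values) == 0 || stats::sd(values2) == 0) {
      stop("constant vector; correlation undefined")
    }
    ct <- stats::cor.test(values, values2, method = "pearson")
    list(kind = kind, r = unname(ct$estimate), p_value = ct$p.value)
  }
}
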