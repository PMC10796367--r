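# Kaplan-Meier, log-rank and covariate-adjusted Cox evaluation of risk
# groups, following the reporting conventions of clinical pathomics studies
# (low-risk reference; male vs female, age > 60 vs <= 60, smoking yes vs no,
# stage III-IV vs I-II contrasts; Efron ties).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate as a step function table. Survival starts at 1
#' and is non-increasing; at-risk counts are non-increasing.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("invalid input: no subjects", call. = FALSE)
  if (any(time < 0)) stop("invalid input: negative times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test across risk groups
#'
#' Standard K-group log-rank chi-square comparing Kaplan-Meier curves.
#'
#' @param time,event Survival outcome.
#' @param group Group labels (>= 2 distinct values; >= 1 event overall).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("invalid input: need at least 2 groups", call. = FALSE)
  if (sum(event) < 1L) stop("invalid input: no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

# Coerce clinical covariates to the printed contrasts.
encode_covariates <- function(data, covariates) {
  out <- list()
  if ("sex" %in% covariates && "sex" %in% names(data))
    out$sex <- factor(data$sex, levels = c("female", "male"))
  if ("age" %in% covariates && "age" %in% names(data)) {
    a <- data$age
    out$age <- if (is.numeric(a))
      factor(ifelse(a > 60, ">60", "<=60"), levels = c("<=60", ">60"))
    else factor(a, levels = c("<=60", ">60"))
  }
  if ("smoking" %in% covariates && "smoking" %in% names(data))
    out$smoking <- factor(data$smoking, levels = c("no", "yes"))
  if ("stage" %in% covariates && "stage" %in% names(data))
    out$stage <- factor(data$stage, levels = c("I-II", "III-IV"))
  if (length(out) == 0L) return(NULL)
  as.data.frame(out)
}

#' Covariate-adjusted Cox model of risk groups
#'
#' Joint proportional-hazards fit of the three-tier risk label (low as
#' reference, encoded as intermediate and high indicators) together with
#' clinical covariates: sex (male vs female), age (> 60 vs <= 60), smoking
#' (yes vs no) and stage (III-IV vs I-II). Ties use Efron's method.
#'
#' @param data `data.frame` with a `risk` column (`low` / `intermediate` /
#'   `high`), outcome columns `<outcome>_time` and `<outcome>_event`, and
#'   any of the covariate columns.
#' @param outcome `"os"` or `"dfs"`.
#' @param covariates Covariates to adjust for (subset of sex, age, smoking,
#'   stage; only those present in `data` are used).
#' @return `data.frame` with `term`, `hr`, `lo`, `hi`, `p` per non-reference
#'   term.
#' @export
adjusted_cox <- function(data, outcome = c("os", "dfs"),
                         covariates = c("sex", "age", "smoking", "stage")) {
  outcome <- match.arg(outcome)
  time <- data[[paste0(outcome, "_time")]]
  event <- data[[paste0(outcome, "_event")]]
  if (is.null(time) || is.null(event))
    stop("outcome columns ", outcome, "_time/_event not found", call. = FALSE)
  risk <- factor(data$risk, levels = intersect(c("low", "intermediate", "high"),
                                               unique(as.character(data$risk))))
  if (!"low" %in% levels(risk))
    stop("risk must contain a 'low' reference group", call. = FALSE)
  covs <- encode_covariates(data, covariates)
  df <- data.frame(time = time, event = event, risk = risk)
  if (!is.null(covs)) df <- cbind(df, covs)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ . - time - event,
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge", conditionMessage(w)))
        stop("diagnostic error: complete separation or non-convergence in ",
             "adjusted Cox fit (", conditionMessage(w), ")", call. = FALSE)
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ . - time - event,
                        data = df, ties = "efron"))
    })
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = unname(s$conf.int[, "exp(coef)"]),
             lo = unname(s$conf.int[, "lower .95"]),
             hi = unname(s$conf.int[, "upper .95"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             row.names = NULL)
}

#' Grouped survival evaluation of risk strata
#'
#' Convenience wrapper producing the standard risk-group report: per-group
#' Kaplan-Meier curves, the K-group log-rank test, pairwise unadjusted
#' hazard ratios against the low-risk reference, and the covariate-adjusted
#' Cox fit.
#'
#' @inheritParams adjusted_cox
#' @return List with `km` (named list of per-group curves), `logrank`,
#'   `pairwise` (unadjusted HRs vs low) and `adjusted`.
#' @export
evaluate_risk_groups <- function(data, outcome = c("os", "dfs"),
                                 covariates = c("sex", "age", "smoking", "stage")) {
  outcome <- match.arg(outcome)
  time <- data[[paste0(outcome, "_time")]]
  event <- data[[paste0(outcome, "_event")]]
  groups <- split(seq_len(nrow(data)), data$risk)
  km <- lapply(groups, function(i) km_curve(time[i], event[i]))
  lr <- logrank(time, event, data$risk)
  risk <- factor(data$risk, levels = intersect(c("low", "intermediate", "high"),
                                               unique(as.character(data$risk))))
  pw_fit <- survival::coxph(survival::Surv(time, event) ~ risk, ties = "efron")
  s <- summary(pw_fit)
  pairwise <- data.frame(term = rownames(s$coefficients),
                         hr = unname(s$conf.int[, "exp(coef)"]),
                         lo = unname(s$conf.int[, "lower .95"]),
                         hi = unname(s$conf.int[, "upper .95"]),
                         p = unname(s$coefficients[, "Pr(>|z|)"]),
                         row.names = NULL)
  list(km = km, logrank = lr, pairwise = pairwise,
       adjusted = adjusted_cox(data, outcome, covariates))
}
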