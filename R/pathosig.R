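# HPC-proportion featurization, Cox-based signature construction,
# time-dependent ROC threshold selection, and slide/patient risk labels.

#' Per-slide HPC proportion features
#'
#' The feature vector of a slide is the proportion of its tiles assigned to
#' each of the M clusters; entries are non-negative and sum to 1.
#'
#' @param assignments Integer vector of 0-based cluster ids for one slide's
#'   tiles.
#' @param M Number of clusters.
#' @return Numeric length-M vector named `hpc_0 ... hpc_{M-1}`.
#' @export
slide_features <- function(assignments, M) {
  if (length(assignments) == 0L)
    stop("missing feature: slide has no assigned tiles", call. = FALSE)
  if (any(assignments < 0L | assignments >= M))
    stop("cluster ids must lie in [0, M)", call. = FALSE)
  p <- tabulate(assignments + 1L, nbins = M) / length(assignments)
  names(p) <- paste0("hpc_", seq_len(M) - 1L)
  p
}

#' Slide-by-HPC feature matrix from per-slide assignments
#'
#' @param assignments Named list of 0-based cluster-id vectors (one per slide).
#' @param M Number of clusters.
#' @return `n_slides x M` matrix with slide ids as row names.
#' @export
feature_matrix <- function(assignments, M) {
  t(vapply(assignments, slide_features, numeric(M), M = M))
}

# --- feature scaling -------------------------------------------------------

fit_feature_scaling <- function(X, method = c("zscore", "identity")) {
  method <- match.arg(method)
  if (method == "identity") return(list(method = "identity"))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(method = "zscore", center = ctr, scale = scl)
}

apply_feature_scaling <- function(X, scaling) {
  if (is.null(scaling) || identical(scaling$method, "identity")) return(X)
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
}

# --- Cox screening ---------------------------------------------------------

#' Univariate Cox screen of HPC features
#'
#' Fits one single-covariate proportional-hazards model per HPC feature
#' against the outcome and selects features with Wald `p < p_threshold`.
#' Hazard ratios are reported per unit of the scaled feature (default:
#' z-score standardized proportions). Constant features are skipped with a
#' warning (non-identifiable).
#'
#' @param X `n x M` matrix of slide-level HPC proportions (rows may repeat a
#'   patient's outcome across slides, following the slide-level design).
#' @param time,event Outcome per row of `X`.
#' @param p_threshold Selection threshold (default 0.05).
#' @param scaling `"zscore"` (default) or `"identity"`.
#' @return List with `table` (`data.frame`: hpc, coef, hr, lo, hi, p,
#'   selected), `selected` (0-based indices), and the fitted `scaling`.
#' @export
univariate_screen <- function(X, time, event, p_threshold = 0.05,
                              scaling = c("zscore", "identity")) {
  X <- as.matrix(X)
  sc <- fit_feature_scaling(X, match.arg(scaling))
  Xs <- apply_feature_scaling(X, sc)
  M <- ncol(X)
  rows <- vector("list", M)
  for (k in seq_len(M)) {
    x <- Xs[, k]
    if (sd(x) < 1e-12) {
      warning("hpc_", k - 1L, " is constant; skipped (non-identifiable)")
      rows[[k]] <- data.frame(hpc = k - 1L, coef = NA_real_, hr = NA_real_,
                              lo = NA_real_, hi = NA_real_, p = NA_real_,
                              selected = FALSE)
      next
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ x)
    s <- summary(fit)
    rows[[k]] <- data.frame(hpc = k - 1L,
                            coef = unname(coef(fit)),
                            hr = unname(s$conf.int[1, "exp(coef)"]),
                            lo = unname(s$conf.int[1, "lower .95"]),
                            hi = unname(s$conf.int[1, "upper .95"]),
                            p = unname(s$coefficients[1, "Pr(>|z|)"]),
                            selected = FALSE)
    rows[[k]]$selected <- rows[[k]]$p < p_threshold
  }
  tab <- do.call(rbind, rows)
  list(table = tab, selected = tab$hpc[which(tab$selected)], scaling = sc)
}

#' Multivariate Cox fit and signature extraction
#'
#' Jointly fits all screened features; terms with multivariate Wald
#' `p < p_threshold` are retained and their fitted log-hazard ratios become
#' the signature coefficients.
#'
#' @param X `n x M` feature matrix (raw proportions).
#' @param time,event Outcome per row.
#' @param selected 0-based indices of screened features (>= 2 required).
#' @param p_threshold Retention threshold (default 0.05).
#' @param scaling A fitted scaling (from [univariate_screen()]) or
#'   `"zscore"` / `"identity"` to fit one here.
#' @return List with `signature` (a `pathosig` object, threshold unset) and
#'   `table` (all screened terms with HR, CI, p, retained flag).
#' @export
multivariate_fit <- function(X, time, event, selected, p_threshold = 0.05,
                             scaling = "zscore") {
  X <- as.matrix(X)
  if (length(selected) < 2L)
    stop("need at least 2 selected features for a multivariate fit", call. = FALSE)
  sc <- if (is.character(scaling)) fit_feature_scaling(X, scaling) else scaling
  Xs <- apply_feature_scaling(X, sc)[, selected + 1L, drop = FALSE]
  if (qr(cbind(1, Xs))$rank < ncol(Xs) + 1L)
    stop("collinearity: selected features are linearly dependent", call. = FALSE)
  df <- data.frame(Xs)
  names(df) <- paste0("hpc_", selected)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
  if (any(!is.finite(coef(fit))))
    stop("convergence error: non-finite coefficients in multivariate fit",
         call. = FALSE)
  s <- summary(fit)
  tab <- data.frame(hpc = selected,
                    coef = unname(coef(fit)),
                    hr = unname(s$conf.int[, "exp(coef)"]),
                    lo = unname(s$conf.int[, "lower .95"]),
                    hi = unname(s$conf.int[, "upper .95"]),
                    p = unname(s$coefficients[, "Pr(>|z|)"]))
  tab$retained <- tab$p < p_threshold
  keep <- tab[tab$retained, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no feature reached multivariate significance; no signature formed",
         call. = FALSE)
  sig <- new_signature(terms = data.frame(hpc = keep$hpc, beta = keep$coef),
                       scaling = sc, threshold = NA_real_)
  list(signature = sig, table = tab)
}

#' Construct a pathomics signature object
#'
#' @param terms `data.frame` with columns `hpc` (0-based index) and `beta`.
#' @param scaling Feature scaling: `list(method = "identity")` or a z-score
#'   scaling with `center` and `scale`.
#' @param threshold Risk-score cutoff (may be `NA` until fitted).
#' @return A `pathosig` object.
#' @export
new_signature <- function(terms, scaling = list(method = "identity"),
                          threshold = NA_real_) {
  stopifnot(is.data.frame(terms), nrow(terms) >= 1L,
            all(c("hpc", "beta") %in% names(terms)))
  structure(list(terms = terms[, c("hpc", "beta")], scaling = scaling,
                 threshold = threshold),
            class = "pathosig")
}

#' @export
print.pathosig <- function(x, ...) {
  cat("Pathomics signature:",
      paste(sprintf("(%+.4f * hpc_%d)", x$terms$beta, x$terms$hpc),
            collapse = " + "), "\n")
  cat("  scaling:", x$scaling$method %||% "identity",
      " threshold:", format(x$threshold), "\n")
  invisible(x)
}

#' Score slides with a pathomics signature
#'
#' Linear risk score `sum_k beta_k * scaled_feature[hpc_k]`. Under identity
#' scaling the score is exactly linear in the raw feature vector.
#'
#' @param features Length-M feature vector or `n x M` matrix.
#' @param signature A `pathosig` object.
#' @return Numeric score (vector of length n for a matrix input).
#' @export
signature_score <- function(features, signature) {
  stopifnot(inherits(signature, "pathosig"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  idx <- signature$terms$hpc + 1L
  if (any(idx > ncol(X)) || any(signature$terms$hpc < 0L))
    stop("invalid signature: HPC index out of range for these features",
         call. = FALSE)
  Xs <- apply_feature_scaling(X, signature$scaling)
  as.vector(Xs[, idx, drop = FALSE] %*% signature$terms$beta)
}

# --- threshold selection ---------------------------------------------------

# Left-continuous Kaplan-Meier evaluation S(t-) from a survfit object.
km_left <- function(fit, t) {
  vapply(t, function(tt) {
    idx <- fit$time < tt
    if (!any(idx)) 1 else fit$surv[max(which(idx))]
  }, numeric(1))
}

km_right <- function(fit, t) {
  vapply(t, function(tt) {
    idx <- fit$time <= tt
    if (!any(idx)) 1 else fit$surv[max(which(idx))]
  }, numeric(1))
}

#' Optimal risk-score threshold from time-dependent ROC analysis
#'
#' Builds the cumulative/dynamic ROC at the horizon (default 5 years):
#' cases are subjects with an observed event by the horizon, controls are
#' subjects still at risk past it; censoring is handled with inverse
#' probability of censoring weights from a Kaplan-Meier estimate of the
#' censoring distribution. Returns the candidate threshold (an observed
#' score) maximizing Youden's J = sensitivity + specificity - 1 under the
#' classification rule "high risk iff score > threshold"; exact ties go to
#' the lower threshold.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival outcome (event 1 = event, 0 = censored).
#' @param horizon_years ROC horizon (default 5).
#' @return The selected threshold, with attributes `sensitivity`,
#'   `specificity`, `youden` (at the selected threshold) and `auc` (IPCW
#'   estimate).
#' @export
optimal_cutoff <- function(scores, time, event, horizon_years = 5) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  cases <- which(time <= horizon_years & event == 1)
  controls <- which(time > horizon_years)
  if (length(cases) == 0L)
    stop("undefined ROC: no events observed before the horizon", call. = FALSE)
  if (length(controls) == 0L)
    stop("undefined ROC: no subjects at risk past the horizon", call. = FALSE)
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  w_case <- 1 / pmax(km_left(cens_fit, time[cases]), 1e-10)
  w_ctrl <- rep(1 / pmax(km_right(cens_fit, horizon_years), 1e-10),
                length(controls))
  cand <- sort(unique(scores))
  s_case <- scores[cases]; s_ctrl <- scores[controls]
  sens <- vapply(cand, function(cc) sum(w_case[s_case > cc]) / sum(w_case), 1)
  spec <- vapply(cand, function(cc) sum(w_ctrl[s_ctrl <= cc]) / sum(w_ctrl), 1)
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1]      # ties -> lower threshold
  # IPCW AUC via weighted rank comparison
  num <- sum(vapply(seq_along(s_case), function(i)
    w_case[i] * sum(w_ctrl * ((s_case[i] > s_ctrl) + 0.5 * (s_case[i] == s_ctrl))),
    numeric(1)))
  auc <- num / (sum(w_case) * sum(w_ctrl))
  structure(cand[best], sensitivity = sens[best], specificity = spec[best],
            youden = J[best], auc = auc)
}

# --- risk labels -----------------------------------------------------------

#' Slide-level risk label
#'
#' High risk iff the score strictly exceeds the threshold; scores at or
#' below the threshold are low risk.
#'
#' @param score Numeric score(s).
#' @param threshold Fitted threshold.
#' @return Character vector of `"high"` / `"low"`.
#' @export
slide_risk <- function(score, threshold) {
  if (is.na(threshold)) stop("threshold has not been fitted", call. = FALSE)
  ifelse(score > threshold, "high", "low")
}

#' Patient-level risk by voting over slide labels
#'
#' All slides high -> high; all low -> low; conflicting labels ->
#' intermediate. A single slide contributes its own label.
#'
#' @param slide_labels Character vector of `"high"` / `"low"` labels from
#'   one patient's slides.
#' @return One of `"low"`, `"intermediate"`, `"high"`.
#' @export
patient_risk <- function(slide_labels) {
  if (length(slide_labels) == 0L)
    stop("invalid input: patient has no slide labels", call. = FALSE)
  if (!all(slide_labels %in% c("low", "high")))
    stop("slide labels must be 'low' or 'high'", call. = FALSE)
  u <- unique(slide_labels)
  if (length(u) == 1L) u else "intermediate"
}

#' Stratify patients from slide scores
#'
#' Applies [slide_risk()] per slide and [patient_risk()] voting per patient.
#'
#' @param slide_scores `data.frame` with `slide_id`, `patient_id`, `score`.
#' @param threshold Fitted risk-score threshold.
#' @return `data.frame` with `patient_id` and `risk`
#'   (low/intermediate/high).
#' @export
stratify_patients <- function(slide_scores, threshold) {
  stopifnot(all(c("patient_id", "score") %in% names(slide_scores)))
  lab <- slide_risk(slide_scores$score, threshold)
  sp <- split(lab, slide_scores$patient_id)
  data.frame(patient_id = names(sp),
             risk = vapply(sp, patient_risk, character(1)),
             row.names = NULL)
}

# --- signature I/O ---------------------------------------------------------

#' Write a signature to JSON
#'
#' @param signature A `pathosig` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path) {
  obj <- list(terms = signature$terms,
              threshold = if (is.na(signature$threshold)) NULL else signature$threshold,
              scaling = if (identical(signature$scaling$method, "identity"))
                "identity" else signature$scaling)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a signature from JSON
#'
#' @param path File written by [write_signature()] (or the bundled
#'   published signature).
#' @return A `pathosig` object.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- if (is.character(obj$scaling) || is.null(obj$scaling))
    list(method = "identity")
  else list(method = obj$scaling$method,
            center = unlist(obj$scaling$center), scale = unlist(obj$scaling$scale))
  new_signature(terms = as.data.frame(obj$terms), scaling = scaling,
                threshold = if (is.null(obj$threshold)) NA_real_ else obj$threshold)
}

#' The published SCLC pathomics signature
#'
#' The two-term signature reported for small cell lung cancer overall
#' survival — coefficient +0.2398 on HPC 39 and -0.3393 on HPC 19 of a
#' 50-cluster model — transcribed with identity scaling (the original
#' feature scale is not stated; scores are comparable only in relative
#' terms). No threshold is bundled: the published cutoff depends on the
#' private testing cohort.
#'
#' @return A `pathosig` object.
#' @export
published_signature <- function() {
  read_signature(system.file("extdata", "pathosig_sclc.json",
                             package = "pathoclust", mustWork = TRUE))
}
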