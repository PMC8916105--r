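#' Specification of a patient-level seizure-freedom model
#'
#' Three nested logistic models of postsurgical seizure freedom:
#' `"location"` uses lesion location alone (vertexwise, see
#' [vertexwise_outcome_model()]); `"presurgical"` uses the presurgically
#' available factors duration of epilepsy, age at onset, ever-MRI-negative
#' status, scanner field strength, lesion overlap with eloquent cortex and
#' lesion size; `"with_histology"` adds the postoperative histopathological
#' subtype and a histopathology-by-lesion-size interaction. Age at scan can
#' replace duration (the two are collinear).
#'
#' @param model_id `"location"`, `"presurgical"` or `"with_histology"`.
#' @param variant `"with_duration"` (default) or `"with_age_at_scan"`.
#' @param cv_folds folds for [crossvalidate()] (default 10).
#' @return an object of class `outcome_model_spec`.
#' @export
outcome_model_spec <- function(model_id = c("presurgical", "location",
                                            "with_histology"),
                               variant = c("with_duration",
                                           "with_age_at_scan"),
                               cv_folds = 10) {
  model_id <- match.arg(model_id)
  variant <- match.arg(variant)
  time_var <- if (variant == "with_duration") "duration" else "age_at_scan"
  predictors <- switch(model_id,
    location = character(0),
    presurgical = c(time_var, "age_at_onset", "ever_mri_negative",
                    "scanner", "eloquent_overlap", "lesion_size_pct"),
    with_histology = c(time_var, "age_at_onset", "ever_mri_negative",
                       "scanner", "eloquent_overlap", "lesion_size_pct",
                       "histopathology"))
  structure(list(model_id = model_id, variant = variant,
                 predictors = predictors, cv_folds = cv_folds,
                 interaction = model_id == "with_histology"),
            class = "outcome_model_spec")
}

# Restrict to operated patients with a valid outcome and complete
# predictors, and put predictors on the modelling scale: continuous
# variables Box-Cox-normalized then standardized (so coefficient
# magnitudes are comparable), eloquent_overlap kept on its natural 0-1
# scale, scanner a factor with 1.5 T as reference. Internal.
prepare_outcome_data <- function(cohort, spec) {
  d <- cohort[cohort$operated %in% TRUE & !is.na(cohort$seizure_free) &
                !is.na(cohort$follow_up) & cohort$follow_up >= 1, ,
              drop = FALSE]
  use <- c("seizure_free", spec$predictors)
  keep_cols <- c(intersect("patient_id", names(d)), use)
  d <- d[complete.cases(d[, use, drop = FALSE]), keep_cols, drop = FALSE]
  if (!nrow(d)) stop("no usable patients for the outcome model")
  if (length(unique(d$seizure_free)) < 2)
    stop("outcome has a single class; model cannot be fitted")
  continuous <- intersect(c("duration", "age_at_scan", "age_at_onset",
                            "lesion_size_pct"), spec$predictors)
  for (v in continuous) {
    z <- boxcox_normalize(d[[v]])$transformed
    d[[v]] <- (z - mean(z)) / max(sd(z), 1e-12)
  }
  if ("scanner" %in% names(d))
    d$scanner <- stats::relevel(factor(d$scanner, levels = c("1.5", "3")),
                                ref = "1.5")
  if ("histopathology" %in% names(d))
    d$histopathology <- factor(d$histopathology)
  d$seizure_free <- as.integer(d$seizure_free)
  d
}

# model formula for a spec (internal)
outcome_formula <- function(spec) {
  rhs <- spec$predictors
  if (spec$interaction)
    rhs <- c(rhs, "histopathology:lesion_size_pct")
  as.formula(paste("seizure_free ~", paste(rhs, collapse = " + ")))
}

#' Fit a patient-level logistic model of seizure freedom
#'
#' Maximum-likelihood logistic regression on the operated subcohort with a
#' recorded (>= 1 year follow-up) outcome. Continuous predictors are
#' Box-Cox-normalized and standardized; eloquent overlap enters on its raw
#' 0-1 scale so its coefficient translates directly into probability drops
#' via [predicted_probability()]; scanner is coded with 1.5 T as the
#' reference level. Zero-variance predictors are dropped with a warning.
#'
#' @param cohort a [cohort_table()] with derived lesion features.
#' @param spec an [outcome_model_spec()] (not `"location"`).
#' @return object of class `outcome_model_fit`: `coefficients`,
#'   `predicted_prob` (per modelled patient), `model` (the `glm`),
#'   `data` (the prepared modelling frame), `spec`.
#' @export
fit_outcome_model <- function(cohort, spec) {
  if (spec$model_id == "location")
    stop("use vertexwise_outcome_model() for the location-only model")
  d <- prepare_outcome_data(cohort, spec)
  drop <- spec$predictors[vapply(spec$predictors, function(v) {
    x <- d[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) < 2 else sd(x) < 1e-12
  }, logical(1))]
  if (length(drop)) {
    warning("zero-variance predictor(s) dropped: ",
            paste(drop, collapse = ", "))
    spec$predictors <- setdiff(spec$predictors, drop)
    if (spec$interaction && "histopathology" %in% drop)
      spec$interaction <- FALSE
  }
  fit <- glm(outcome_formula(spec), family = binomial(), data = d)
  structure(list(coefficients = coef(fit),
                 predicted_prob = as.numeric(predict(fit,
                                                     type = "response")),
                 model = fit, data = d, spec = spec),
            class = "outcome_model_fit")
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat("outcome_model_fit (", x$spec$model_id, "), n =", nrow(x$data), "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Vertexwise seizure-freedom model (location only)
#'
#' At each vertex with at least `min_coverage` overlapping lesions from
#' outcome patients, a logistic regression of seizure freedom on the
#' binary lesion-presence indicator. Also returns the descriptive
#' percent-seizure-free map and the per-patient predicted likelihood,
#' aggregated as the mean fitted probability over the patient's lesional
#' vertices.
#'
#' @param cohort a [cohort_table()].
#' @param masks list of [lesion_mask()], one per cohort row.
#' @param min_coverage minimum covering lesions per modelled vertex
#'   (default 5).
#' @return list with `coef` (per-vertex location coefficient, `NA` where
#'   not modelled), `included_vertices`, `percent_map` (from
#'   [percent_seizure_free_map()]), `predicted_prob` (per outcome
#'   patient).
#' @export
vertexwise_outcome_model <- function(cohort, masks, min_coverage = 5) {
  keep <- which(cohort$operated %in% TRUE & !is.na(cohort$seizure_free))
  if (!length(keep)) stop("no operated patient with recorded outcome")
  y <- as.integer(cohort$seizure_free[keep])
  if (length(unique(y)) < 2) stop("outcome has a single class")
  m <- masks_to_matrix(pool_to_left(masks[keep]))
  n <- length(y)
  coverage <- rowSums(m)
  included <- which(coverage >= min_coverage & coverage <= n - min_coverage)
  nv <- nrow(m)
  beta <- rep(NA_real_, nv)
  prob_lesion <- rep(NA_real_, nv)   # fitted P(seizure-free | lesion at v)
  for (v in included) {
    X <- cbind(1, m[v, ])
    b <- .ridge_logistic_batch(X, matrix(y, ncol = 1), ridge = 1e-4)
    beta[v] <- b[2, 1]
    prob_lesion[v] <- plogis(b[1, 1] + b[2, 1])
  }
  pred <- vapply(seq_len(n), function(i) {
    vs <- which(m[, i] == 1L & !is.na(prob_lesion))
    if (!length(vs)) NA_real_ else mean(prob_lesion[vs])
  }, numeric(1))
  list(coef = beta, included_vertices = included,
       percent_map = percent_seizure_free_map(cohort[keep, , drop = FALSE],
                                              masks[keep]),
       predicted_prob = pred)
}

#' Translate a logistic coefficient into a probability change
#'
#' Applies a coefficient to a baseline probability on the log-odds scale:
#' `invlogit(logit(baseline) + beta * delta)`. E.g., with the
#' eloquent-overlap coefficient -1.39 and a 70% baseline, a 0.5 overlap
#' gives 53.8% - a 16-point drop.
#'
#' @param beta logistic coefficient (per unit of its covariate).
#' @param baseline_prob baseline probability in (0, 1).
#' @param delta covariate change.
#' @return predicted probability.
#' @export
predicted_probability <- function(beta, baseline_prob, delta) {
  if (baseline_prob <= 0 || baseline_prob >= 1)
    stop("baseline_prob must lie strictly inside (0, 1)")
  plogis(qlogis(baseline_prob) + beta * delta)
}

#' Permutation significance of outcome-model coefficients
#'
#' The outcome labels are permuted across patients `n_perm` times and the
#' model refitted; a predictor is flagged when its observed coefficient
#' falls outside the 2.5-97.5 percentile band of its permutation-null
#' coefficients.
#'
#' @param cohort a [cohort_table()].
#' @param spec an [outcome_model_spec()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame with per-coefficient `observed`, `lower`, `upper`,
#'   `significant`.
#' @export
outcome_permutation_significance <- function(cohort, spec, n_perm = 1000,
                                             seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit <- fit_outcome_model(cohort, spec)
  X <- stats::model.matrix(fit$model)
  y <- fit$data$seizure_free
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(b) sample(y), numeric(length(y)))
  null_b <- .ridge_logistic_batch(X, Y, ridge = 0)   # p x n_perm
  obs <- fit$coefficients
  # pool the observed coefficients into the null so observed and permuted
  # cohorts are exchangeable (calibrates the band at small n_perm)
  qs <- apply(cbind(obs, null_b), 1, quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(term = names(obs), observed = as.numeric(obs),
             lower = qs[1, ], upper = qs[2, ],
             significant = obs < qs[1, ] | obs > qs[2, ],
             row.names = NULL)
}

#' Cross-validated classification metrics for an outcome model
#'
#' Stratified k-fold cross-validation of a patient-level outcome model:
#' each held-out patient's predicted probability is dichotomised at
#' `threshold` and the confusion matrix pooled over all held-out
#' predictions. Sensitivity, specificity, PPV and NPV are computed with
#' seizure freedom as the positive class.
#'
#' @param cohort a [cohort_table()].
#' @param spec an [outcome_model_spec()].
#' @param k folds (default `spec$cv_folds`).
#' @param seed integer RNG seed for fold assignment.
#' @param threshold classification threshold (default 0.5).
#' @return list with `metrics` (sensitivity, specificity, ppv, npv),
#'   `confusion` (2 x 2 table), `predictions` (per-patient data.frame).
#' @export
crossvalidate <- function(cohort, spec, k = spec$cv_folds, seed = 1L,
                          threshold = 0.5) {
  stopifnot(k >= 2)
  d <- prepare_outcome_data(cohort, spec)
  n <- nrow(d)
  set.seed(seed)
  fold <- integer(n)
  for (cls in sort(unique(d$seizure_free))) {
    idx <- which(d$seizure_free == cls)
    # anchor on patient id so folds do not depend on row order
    if (!is.null(d$patient_id)) idx <- idx[order(d$patient_id[idx])]
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  form <- outcome_formula(spec)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    train <- d[fold != f, , drop = FALSE]
    if (length(unique(train$seizure_free)) < 2) {
      warning("fold ", f, " training set single-class; fold skipped")
      next
    }
    fit <- suppressWarnings(glm(form, family = binomial(), data = train))
    pred[fold == f] <- suppressWarnings(
      predict(fit, newdata = d[fold == f, , drop = FALSE],
              type = "response"))
  }
  yhat <- as.integer(pred >= threshold)
  y <- d$seizure_free
  tp <- sum(yhat == 1 & y == 1, na.rm = TRUE)
  tn <- sum(yhat == 0 & y == 0, na.rm = TRUE)
  fp <- sum(yhat == 1 & y == 0, na.rm = TRUE)
  fn <- sum(yhat == 0 & y == 1, na.rm = TRUE)
  list(metrics = c(sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   ppv = tp / (tp + fp),
                   npv = tn / (tn + fn)),
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(predicted = c("free", "not_free"),
                                          actual = c("free", "not_free"))),
       predictions = data.frame(fold = fold, prob = pred,
                                predicted = yhat, actual = y))
}
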