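#' Factor specification for vertexwise association models
#'
#' The clinical factors entered jointly into the per-vertex logistic models.
#' Because duration of epilepsy and age at scan are strongly collinear, the
#' two live in separate model variants: `with_duration` (the default set:
#' sex, age at onset, duration, ever-MRI-negative, lesion size, lesion
#' hemisphere) and `with_age_at_scan` (age at scan replacing duration).
#'
#' @param variant `"with_duration"` or `"with_age_at_scan"`.
#' @param factors optional custom factor list; must not contain both
#'   `duration` and `age_at_scan`.
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(variant = c("with_duration", "with_age_at_scan"),
                        factors = NULL) {
  variant <- match.arg(variant)
  if (is.null(factors)) {
    factors <- c("sex", "age_at_onset",
                 if (variant == "with_duration") "duration" else "age_at_scan",
                 "ever_mri_negative", "lesion_size_pct", "lesion_hemisphere")
  }
  if (all(c("duration", "age_at_scan") %in% factors))
    stop("duration and age_at_scan are collinear; use separate variants")
  structure(list(factors = factors, variant = variant),
            class = "factor_spec")
}

# Encode cohort columns into a standardized numeric design matrix with an
# intercept in column 1. Binary variables become 0/1; continuous variables
# are centred and scaled. Zero-variance columns are dropped with a warning.
# Internal.
build_design <- function(cohort, factors) {
  cols <- lapply(factors, function(f) {
    if (!f %in% names(cohort)) stop("unknown cohort field: ", f)
    x <- cohort[[f]]
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x) || is.factor(x)) {
      x <- as.factor(x)
      if (nlevels(x) > 2)
        stop("factor ", f, " has >2 levels; not supported in the ",
             "vertexwise design")
      return(as.numeric(x) - 1)
    }
    as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- factors
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    s <- sd(X[, j])
    if (is.na(s) || s < 1e-12) {
      warning("factor ", factors[j], " has zero variance; dropped")
      keep[j] <- FALSE
    } else {
      X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  X <- X[, keep, drop = FALSE]
  cbind(`(intercept)` = 1, X)
}

#' Vertexwise multivariate logistic association models
#'
#' At every template vertex covered by at least `min_coverage` lesions (and
#' at most n - `min_coverage`, so both outcome classes are represented), a
#' logistic regression of lesion presence at that vertex on all factors in
#' `spec` is fitted jointly. Predictors are standardized; a small ridge
#' penalty (default 1e-4, settable to 0) stabilises vertices close to
#' separation. Masks are pooled to the left hemisphere before fitting.
#'
#' @param cohort a [cohort_table()].
#' @param masks list of [lesion_mask()], one per cohort row.
#' @param spec a [factor_spec()].
#' @param min_coverage minimum lesional patients per included vertex
#'   (default 5).
#' @param ridge ridge penalty on standardized predictors (default 1e-4).
#' @return list with `coef` (factor x vertex matrix over included vertices;
#'   `NA` columns mark non-converged fits), `included_vertices`,
#'   `factors`, `design` (the standardized design matrix), and `Y`
#'   (vertex-presence outcomes for the included vertices).
#' @export
vertexwise_logistic <- function(cohort, masks, spec,
                                min_coverage = 5, ridge = 1e-4) {
  stopifnot(inherits(spec, "factor_spec"))
  m <- masks_to_matrix(pool_to_left(masks))
  n <- ncol(m)
  coverage <- rowSums(m)
  included <- which(coverage >= min_coverage & coverage <= n - min_coverage)
  if (!length(included)) stop("no vertex passes the coverage filter")
  X <- build_design(cohort, spec$factors)
  Y <- t(m[included, , drop = FALSE])   # n x V
  B <- .ridge_logistic_batch(X, Y, ridge)
  rownames(B) <- colnames(X)
  coefs <- B[-1, , drop = FALSE]        # drop intercept row
  colnames(coefs) <- included
  list(coef = coefs, included_vertices = included,
       factors = rownames(coefs), design = X, Y = Y, ridge = ridge,
       min_coverage = min_coverage)
}

#' Permutation null for the vertexwise models
#'
#' Re-fits the vertexwise models on cohorts in which the covariate rows are
#' shuffled as whole rows against the lesion masks (preserving the
#' correlation structure among covariates while breaking any link to lesion
#' location). Stores the full per-vertex null coefficient distributions and,
#' per permutation, the number of vertices each factor would flag under the
#' two-sided 2.5/97.5 percentile rule.
#'
#' @param fit result of [vertexwise_logistic()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return list with `null_coef` (factor x vertex x permutation array),
#'   `null_sig_counts` (factor x permutation matrix), `lower`/`upper`
#'   (factor x vertex percentile bands) and `n_perm`.
#' @export
permutation_null <- function(fit, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- fit$design
  n <- nrow(X)
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  raw <- .ridge_logistic_perms(X, fit$Y, perms, fit$ridge)
  p <- ncol(X)
  V <- ncol(fit$Y)
  null_coef <- array(raw, dim = c(p, V, n_perm))[-1, , , drop = FALSE]
  dimnames(null_coef) <- list(fit$factors, colnames(fit$coef), NULL)
  nf <- length(fit$factors)
  lower <- matrix(NA_real_, nf, V, dimnames = dimnames(fit$coef))
  upper <- lower
  null_sig_counts <- matrix(0L, nf, n_perm,
                            dimnames = list(fit$factors, NULL))
  for (f in seq_len(nf)) {
    # pool the observed coefficient into the null distribution so the
    # observed and permuted cohorts are exchangeable under the null
    # (keeps the vertex rule calibrated at small permutation counts)
    nv <- cbind(fit$coef[f, ], null_coef[f, , , drop = TRUE])  # V x (B+1)
    qs <- apply(nv, 1, function(z) {
      if (all(is.na(z))) c(NA_real_, NA_real_)
      else quantile(z, probs = c(0.025, 0.975), na.rm = TRUE)
    })
    lower[f, ] <- qs[1, ]
    upper[f, ] <- qs[2, ]
    flags <- nv[, -1, drop = FALSE] < lower[f, ] |
             nv[, -1, drop = FALSE] > upper[f, ]  # recycled by column
    null_sig_counts[f, ] <- colSums(flags, na.rm = TRUE)
  }
  list(null_coef = null_coef, null_sig_counts = null_sig_counts,
       lower = lower, upper = upper, n_perm = n_perm, seed = seed)
}

#' Vertices significantly associated with each factor
#'
#' A vertex is flagged for a factor when the observed coefficient falls
#' below the 2.5th or above the 97.5th percentile of that vertex's null
#' coefficients. Under the null roughly 5% of vertices are flagged by
#' chance.
#'
#' @param fit result of [vertexwise_logistic()].
#' @param null result of [permutation_null()].
#' @return logical factor x vertex matrix (`FALSE` where the observed fit
#'   did not converge).
#' @export
significant_vertices <- function(fit, null) {
  flags <- fit$coef < null$lower | fit$coef > null$upper
  flags[is.na(flags)] <- FALSE
  flags
}

#' Map-level significance of a factor
#'
#' A factor is significantly related to lesion location when its observed
#' count of flagged vertices exceeds the (100 - 5/n)th percentile of the
#' null significant-vertex counts, n being the number of factors tested —
#' a Bonferroni-style tightening of the map-level rule across factors.
#'
#' @param observed_counts named integer vector of flagged-vertex counts.
#' @param null_sig_counts factor x permutation matrix of null counts.
#' @param n_factors number of factors tested (defaults to the number of
#'   rows).
#' @return data.frame with per-factor `observed`, `threshold`,
#'   `significant`.
#' @export
map_level_significance <- function(observed_counts, null_sig_counts,
                                   n_factors = nrow(null_sig_counts)) {
  stopifnot(n_factors >= 1)
  pct <- (100 - 5 / n_factors) / 100
  thr <- apply(null_sig_counts, 1, quantile, probs = pct, na.rm = TRUE)
  data.frame(factor = rownames(null_sig_counts),
             observed = as.integer(observed_counts),
             threshold = as.numeric(thr),
             significant = as.integer(observed_counts) > as.numeric(thr),
             row.names = NULL)
}

#' Full vertexwise inference pass
#'
#' Convenience wrapper: fit the observed vertexwise models, build the
#' permutation null, flag vertices and render the map-level verdicts.
#'
#' @inheritParams vertexwise_logistic
#' @inheritParams permutation_null
#' @return list with the `fit`, `null`, `sig_vertices` (logical matrix),
#'   `observed_counts` and `map_level` verdict table.
#' @export
vertexwise_inference <- function(cohort, masks, spec, n_perm = 1000,
                                 seed = 1L, min_coverage = 5,
                                 ridge = 1e-4) {
  fit <- vertexwise_logistic(cohort, masks, spec, min_coverage, ridge)
  null <- permutation_null(fit, n_perm, seed)
  sig <- significant_vertices(fit, null)
  observed_counts <- rowSums(sig)
  map_level <- map_level_significance(observed_counts,
                                      null$null_sig_counts)
  list(fit = fit, null = null, sig_vertices = sig,
       observed_counts = observed_counts, map_level = map_level)
}

#' Mean clinical-variable value by lesion location
#'
#' At each vertex covered by at least one lesion, the mean of a numeric
#' cohort variable over the patients whose lesion covers that vertex
#' (e.g., the average age at epilepsy onset by lesion location). Vertices
#' with no coverage are `NA`.
#'
#' @param cohort a [cohort_table()].
#' @param masks list of [lesion_mask()], one per cohort row (pooled to the
#'   left hemisphere internally).
#' @param variable name of a numeric cohort column.
#' @return list with `mean` (numeric per vertex, `NA` where undefined) and
#'   `coverage`.
#' @export
mean_value_map <- function(cohort, masks, variable) {
  x <- cohort[[variable]]
  if (is.null(x)) stop("unknown cohort field: ", variable)
  if (!is.numeric(x)) stop("variable ", variable, " is not numeric")
  keep <- which(!is.na(x))
  m <- masks_to_matrix(pool_to_left(masks[keep]))
  coverage <- as.integer(rowSums(m))
  total <- as.vector(m %*% x[keep])
  list(mean = ifelse(coverage > 0, total / coverage, NA_real_),
       coverage = coverage)
}
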