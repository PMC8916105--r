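test_that("outcome model specs nest as documented", {
  m2 <- outcome_model_spec("presurgical")
  m3 <- outcome_model_spec("with_histology")
  expect_true(all(m2$predictors %in% m3$predictors))
  expect_true("histopathology" %in% m3$predictors)
  expect_true(m3$interaction)
  alt <- outcome_model_spec("presurgical", variant = "with_age_at_scan")
  expect_true("age_at_scan" %in% alt$predictors)
  expect_false("duration" %in% alt$predictors)
})

test_that("outcome model fits, drops degenerate predictors, and rejects
           single-class outcomes", {
  cm <- fix_null_cohort()
  fit <- fit_outcome_model(cm$cohort, outcome_model_spec("presurgical"))
  expect_true(all(fit$predicted_prob > 0 & fit$predicted_prob < 1))
  expect_true("eloquent_overlap" %in% names(fit$coefficients))
  # reference level: scanner coefficient is named for the 3-T contrast
  expect_true("scanner3" %in% names(fit$coefficients))
  same_scanner <- cm$cohort
  same_scanner$scanner <- 3
  expect_warning(fit_outcome_model(same_scanner,
                                   outcome_model_spec("presurgical")),
                 "zero-variance")
  all_free <- cm$cohort
  all_free$seizure_free[!is.na(all_free$seizure_free)] <- TRUE
  expect_error(fit_outcome_model(all_free,
                                 outcome_model_spec("presurgical")),
               "single class")
})

test_that("planted coefficients fall inside their 95% Wald intervals", {
  mesh <- fix_mesh()
  parc <- fix_parc()
  planted <- c(intercept = 0, eloquent_overlap = -1.39, duration = -0.35,
               scanner3 = 1.04, lesion_size_pct = -0.2,
               ever_mri_negative = -0.32)
  hits <- matrix(NA, 12, 3,
                 dimnames = list(NULL, c("eloquent_overlap", "scanner3",
                                         "duration")))
  for (r in 1:12) {
    cm <- sample_cohort(mesh, parc,
                        simulation_params(n_patients = 800,
                                          couplings = NULL,
                                          outcome_betas = planted,
                                          seed = 3000 + r))
    fit <- fit_outcome_model(cm$cohort, outcome_model_spec("presurgical"))
    s <- summary(fit$model)$coefficients
    for (term in colnames(hits)) {
      truth <- planted[[if (term == "scanner3") "scanner3" else term]]
      hits[r, term] <- abs(s[term, "Estimate"] - truth) <=
        1.96 * s[term, "Std. Error"]
    }
  }
  expect_gte(mean(hits[, "eloquent_overlap"]), 0.9)
  expect_gte(mean(hits[, "scanner3"]), 0.75)
})

test_that("probability translation matches the logistic arithmetic", {
  # 50% eloquent overlap at beta -1.39 from a 70% baseline
  expect_equal(predicted_probability(-1.39, 0.70, 0.5), 0.538,
               tolerance = 5e-3)
  # moving from 3 T to 1.5 T at beta 1.04
  expect_equal(predicted_probability(1.04, 0.70, -1), 0.452,
               tolerance = 5e-3)
  expect_equal(predicted_probability(-2.7, 0.6, 0), 0.6)
  # monotone in delta for fixed negative beta
  deltas <- seq(0, 1, 0.1)
  probs <- vapply(deltas, function(d)
    predicted_probability(-1.39, 0.7, d), numeric(1))
  expect_true(all(diff(probs) < 0))
  expect_equal(plogis(qlogis(0.371)), 0.371, tolerance = 1e-12)
  expect_error(predicted_probability(1, 1, 0.5), "strictly inside")
})

test_that("outcome permutation flags calibrate under the null and detect
           a strong planted predictor", {
  mesh <- fix_mesh()
  parc <- fix_parc()
  null_betas <- c(intercept = 0.6, eloquent_overlap = 0, duration = 0,
                  scanner3 = 0, lesion_size_pct = 0,
                  ever_mri_negative = 0)
  flags <- sapply(1:120, function(r) {
    cm <- sample_cohort(mesh, parc,
                        simulation_params(n_patients = 150,
                                          couplings = NULL,
                                          outcome_betas = null_betas,
                                          seed = 17000 + r))
    pm <- outcome_permutation_significance(
      cm$cohort, outcome_model_spec("presurgical"), n_perm = 99,
      seed = 18000 + r)
    pm$significant[pm$term != "(Intercept)"]
  })
  expect_gt(mean(flags), 0.02)
  expect_lt(mean(flags), 0.095)
  expect_true(all(rowMeans(flags) <= 0.13))
  strong <- sapply(1:15, function(r) {
    cm <- sample_cohort(mesh, parc, simulation_params(
      n_patients = 400, couplings = NULL,
      outcome_betas = c(intercept = 0.3, eloquent_overlap = -3,
                        duration = 0, scanner3 = 0,
                        lesion_size_pct = 0, ever_mri_negative = 0),
      seed = 9000 + r))
    pm <- outcome_permutation_significance(
      cm$cohort, outcome_model_spec("presurgical"), n_perm = 99,
      seed = 9500 + r)
    pm$significant[pm$term == "eloquent_overlap"]
  })
  expect_gte(mean(strong), 0.95)
  # reproducible for a fixed seed
  cm <- fix_null_cohort()
  p1 <- outcome_permutation_significance(cm$cohort,
                                         outcome_model_spec("presurgical"),
                                         n_perm = 30, seed = 5)
  p2 <- outcome_permutation_significance(cm$cohort,
                                         outcome_model_spec("presurgical"),
                                         n_perm = 30, seed = 5)
  expect_identical(p1, p2)
})

test_that("vertexwise outcome model finds planted low-outcome regions", {
  mesh <- fix_mesh()
  nv <- n_vertices(mesh)
  # region A around vertex 1, region B around its antipode
  anti <- which.min(mesh$sphere_coords %*% mesh$sphere_coords[1, ])
  n_per <- 30
  masks <- c(lapply(1:n_per, function(i)
    disc_mask(mesh, 1, 2, paste0("A", i))),
    lapply(1:n_per, function(i)
      disc_mask(mesh, anti, 2, paste0("B", i))))
  set.seed(77)
  sf <- c(runif(n_per) < 0.3, runif(n_per) < 0.7)
  cohort <- toy_cohort(2 * n_per, seizure_free = sf)
  vx <- vertexwise_outcome_model(cohort, masks, min_coverage = 5)
  in_a <- geodesic_disc(mesh, 1, 2)
  in_b <- geodesic_disc(mesh, anti, 2)
  expect_lt(mean(vx$coef[in_a], na.rm = TRUE), 0)
  expect_gt(mean(vx$coef[in_b], na.rm = TRUE),
            mean(vx$coef[in_a], na.rm = TRUE))
  # vertices covered by no lesion are not modelled
  expect_true(all(is.na(vx$coef[-c(in_a, in_b)])))
  # balanced outcomes in and out of coverage give a near-zero effect
  bal <- toy_cohort(8, seizure_free = c(TRUE, FALSE, TRUE, FALSE,
                                        TRUE, FALSE, TRUE, FALSE))
  bal_masks <- c(lapply(1:4, function(i)
    disc_mask(mesh, 1, 1, paste0("C", i))),
    lapply(1:4, function(i) disc_mask(mesh, anti, 1, paste0("D", i))))
  vb <- vertexwise_outcome_model(bal, bal_masks, min_coverage = 2)
  expect_lt(max(abs(vb$coef), na.rm = TRUE), 1e-3)
})

test_that("cross-validation metrics behave on separable and degenerate
           classifiers", {
  cohort <- toy_cohort(40)
  set.seed(13)
  cohort$seizure_free <- rep(c(TRUE, FALSE), each = 20)
  cohort$lesion_size_pct <- ifelse(cohort$seizure_free, 5, 25) +
    rnorm(40, 0, 0.5)
  cohort$eloquent_overlap <- runif(40, 0, 0.2)
  spec <- outcome_model_spec("presurgical")
  cv <- suppressWarnings(crossvalidate(cohort, spec, k = 5, seed = 2))
  expect_equal(unname(cv$metrics[c("sensitivity", "specificity")]),
               c(1, 1))
  # threshold 0 labels everyone positive
  cv0 <- suppressWarnings(crossvalidate(cohort, spec, k = 5, seed = 2,
                                        threshold = 0))
  expect_equal(unname(cv0$metrics[["sensitivity"]]), 1)
  expect_equal(unname(cv0$metrics[["specificity"]]), 0)
  expect_equal(unname(cv0$metrics[["ppv"]]), 0.5)  # prevalence
})

test_that("pooled CV confusion matrix equals a hand-counted oracle and is
           invariant to row order", {
  mesh <- fix_mesh()
  parc <- fix_parc()
  cm <- sample_cohort(mesh, parc,
                      simulation_params(n_patients = 70, seed = 19))
  spec <- outcome_model_spec("presurgical")
  cv <- crossvalidate(cm$cohort, spec, k = 5, seed = 3)
  # oracle: replay the documented procedure with plain loops
  d <- fcdmap:::prepare_outcome_data(cm$cohort, spec)
  set.seed(3)
  fold <- integer(nrow(d))
  for (cls in sort(unique(d$seizure_free))) {
    idx <- which(d$seizure_free == cls)
    idx <- idx[order(d$patient_id[idx])]
    idx <- sample(idx)
    fold[idx] <- rep_len(1:5, length(idx))
  }
  form <- fcdmap:::outcome_formula(spec)
  tp <- tn <- fp <- fn <- 0
  for (f in 1:5) {
    g <- suppressWarnings(glm(form, binomial(), data = d[fold != f, ]))
    pr <- suppressWarnings(predict(g, d[fold == f, ], type = "response"))
    yh <- as.integer(pr >= 0.5)
    y <- d$seizure_free[fold == f]
    tp <- tp + sum(yh == 1 & y == 1)
    tn <- tn + sum(yh == 0 & y == 0)
    fp <- fp + sum(yh == 1 & y == 0)
    fn <- fn + sum(yh == 0 & y == 1)
  }
  expect_equal(unname(cv$confusion), matrix(c(tp, fn, fp, tn), 2, 2))
  # shuffling patient rows leaves the pooled metrics unchanged
  set.seed(23)
  shuffled <- cm$cohort[sample(nrow(cm$cohort)), ]
  cv2 <- crossvalidate(shuffled, spec, k = 5, seed = 3)
  expect_equal(cv$metrics, cv2$metrics)
})
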