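test_that("factor spec enforces the duration/age-at-scan exclusivity", {
  expect_true("duration" %in% factor_spec("with_duration")$factors)
  expect_true("age_at_scan" %in% factor_spec("with_age_at_scan")$factors)
  expect_false("age_at_scan" %in% factor_spec("with_duration")$factors)
  expect_error(factor_spec(factors = c("duration", "age_at_scan")),
               "collinear")
})

test_that("vertexwise coefficients agree with per-vertex glm at ridge 0", {
  cm <- fix_null_cohort()
  fit <- vertexwise_logistic(cm$cohort, cm$masks, null_factor_spec(),
                             min_coverage = 10, ridge = 0)
  X <- fit$design
  set.seed(51)
  converged <- which(!is.na(fit$coef[1, ]))
  for (j in sample(converged, 5)) {
    y <- fit$Y[, j]
    g <- suppressWarnings(glm(y ~ X - 1, family = binomial()))
    expect_equal(unname(fit$coef[, j]), unname(coef(g))[-1],
                 tolerance = 1e-5)
  }
})

test_that("coverage filter and zero-variance factors are respected", {
  cm <- fix_null_cohort()
  fit <- vertexwise_logistic(cm$cohort, cm$masks, null_factor_spec(),
                             min_coverage = 8)
  cov <- rowSums(masks_to_matrix(pool_to_left(cm$masks)))
  expect_true(all(cov[fit$included_vertices] >= 8))
  expect_true(all(cov[fit$included_vertices] <= length(cm$masks) - 8))
  expect_true(all(cov[-fit$included_vertices] < 8 |
                    cov[-fit$included_vertices] > length(cm$masks) - 8))
  cohort2 <- cm$cohort
  cohort2$sex <- "female"
  expect_warning(
    vertexwise_logistic(cohort2, cm$masks, null_factor_spec()),
    "zero variance")
})

test_that("permutation null is reproducible and preserves dimensions", {
  cm <- fix_null_cohort()
  fit <- vertexwise_logistic(cm$cohort, cm$masks, null_factor_spec())
  n1 <- permutation_null(fit, n_perm = 20, seed = 9)
  n2 <- permutation_null(fit, n_perm = 20, seed = 9)
  expect_identical(n1$null_sig_counts, n2$null_sig_counts)
  expect_identical(n1$null_coef, n2$null_coef)
  expect_equal(dim(n1$null_coef),
               c(length(fit$factors), ncol(fit$coef), 20))
  expect_error(permutation_null(fit, n_perm = 0), "n_perm")
})

test_that("vertex flags follow the two-sided percentile rule", {
  # synthetic fit/null pair with known structure
  fit <- list(coef = matrix(c(0, 10, -10), 1, 3,
                            dimnames = list("f", NULL)))
  null <- list(lower = matrix(-2, 1, 3), upper = matrix(2, 1, 3))
  flags <- significant_vertices(fit, null)
  expect_equal(as.vector(flags), c(FALSE, TRUE, TRUE))
  # observed equal to the null median is never flagged
  fit2 <- list(coef = matrix(0, 1, 1))
  null2 <- list(lower = matrix(-1, 1, 1), upper = matrix(1, 1, 1))
  expect_false(any(significant_vertices(fit2, null2)))
})

test_that("map-level thresholds instantiate the 100 - 5/n rule", {
  set.seed(61)
  counts <- matrix(sample(0:40, 400, replace = TRUE), 1, 400,
                   dimnames = list("f", NULL))
  m1 <- map_level_significance(c(f = 100), counts, n_factors = 1)
  expect_equal(m1$threshold, unname(quantile(counts[1, ], 0.95)))
  m5 <- map_level_significance(c(f = 100), counts, n_factors = 5)
  expect_equal(m5$threshold, unname(quantile(counts[1, ], 0.99)))
  # observed below the null median is not significant
  low <- map_level_significance(c(f = median(counts[1, ]) - 1), counts,
                                n_factors = 1)
  expect_false(low$significant)
})

test_that("planted location-factor coupling raises coefficients in the
           coupled region and is detected at map level", {
  mesh <- fix_mesh()
  parc <- fix_parc()
  ax <- axis_map(mesh)
  hits <- logical(10)
  inside_gt_outside <- logical(10)
  for (r in 1:10) {
    cm <- sample_cohort(mesh, parc,
                        simulation_params(n_patients = 100,
                                          couplings = c(age_at_onset = 1.5),
                                          seed = 300 + r))
    vw <- vertexwise_inference(cm$cohort, cm$masks, null_factor_spec(),
                               n_perm = 60, seed = 400 + r)
    hits[r] <-
      vw$map_level$significant[vw$map_level$factor == "age_at_onset"]
    co <- abs(vw$fit$coef["age_at_onset", ])
    region <- abs(ax[vw$fit$included_vertices]) > 1  # axis extremes
    inside_gt_outside[r] <- mean(co[region], na.rm = TRUE) >
      mean(co[!region], na.rm = TRUE)
  }
  expect_gte(sum(hits), 9)
  expect_gte(sum(inside_gt_outside), 8)
})

test_that("vertex flag rate and map-level family-wise error calibrate on
           null cohorts", {
  mesh <- fix_mesh()
  parc <- fix_parc()
  spec <- null_factor_spec()
  any_sig <- logical(100)
  rate <- numeric(100)
  for (r in 1:100) {
    cm <- sample_cohort(mesh, parc,
                        simulation_params(n_patients = 60,
                                          couplings = NULL,
                                          seed = 5000 + r))
    vw <- vertexwise_inference(cm$cohort, cm$masks, spec, n_perm = 99,
                               seed = 6000 + r)
    any_sig[r] <- any(vw$map_level$significant)
    rate[r] <- mean(rowSums(vw$sig_vertices) /
                      length(vw$fit$included_vertices))
  }
  # per-vertex rule targets 5%; bound reflects Monte Carlo error over
  # 100 cohorts with spatially correlated flags
  expect_gt(mean(rate), 0.033)
  expect_lt(mean(rate), 0.072)
  # map-level rule targets ~5% family-wise; small permutation counts add
  # percentile-estimation graininess
  expect_lte(mean(any_sig), 0.13)
})

test_that("mean-value maps average the variable over covering lesions", {
  mesh <- fix_mesh()
  masks <- list(disc_mask(mesh, 1, 2, "P1"), disc_mask(mesh, 1, 1, "P2"))
  cohort <- toy_cohort(2)
  cohort$age_at_onset <- c(4, 8)
  mv <- mean_value_map(cohort, masks, "age_at_onset")
  overlap <- which(masks[[1]]$indicator & masks[[2]]$indicator)
  only1 <- which(masks[[1]]$indicator & !masks[[2]]$indicator)
  expect_true(all(mv$mean[overlap] == 6))
  expect_true(all(mv$mean[only1] == 4))
  expect_true(all(is.na(mv$mean[mv$coverage == 0])))
  expect_error(mean_value_map(cohort, masks, "sex"), "not numeric")
})
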