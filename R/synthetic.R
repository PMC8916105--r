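#' Icosphere template mesh
#'
#' A unit icosphere: the regular icosahedron subdivided `subdivisions`
#' times, vertices projected to the unit sphere. Vertex count is
#' `10 * 4^s + 2` (162 at s = 2, 642 at s = 3). Serves as a bilaterally
#' symmetric template surface: the same mesh represents both hemispheres,
#' so left/right vertex indices correspond trivially.
#'
#' @param subdivisions refinement level (>= 1).
#' @param hemisphere hemisphere tag for the returned mesh.
#' @return a [triangle_mesh()] with `sphere_coords == vertex_coords`.
#' @export
make_sphere_mesh <- function(subdivisions = 3,
                             hemisphere = c("left", "right")) {
  stopifnot(subdivisions >= 1)
  hemisphere <- match.arg(hemisphere)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    new_v <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      new_v[[length(new_v) + 1L]] <<- m
      idx <- nv + length(new_v)
      midpoint_cache[[key]] <- idx
      idx
    }
    new_f <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      new_f[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                          c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, new_v))
    f <- new_f
  }
  triangle_mesh(v, f, sphere_coords = v, hemisphere = hemisphere)
}

#' Smooth surrogate cortical axis map
#'
#' A deterministic low-order spherical-harmonic gradient over the mesh
#' (degree-1 plus a degree-2 term), standardized to mean 0 and unit
#' variance. Stands in for a principal axis of cortical organization from
#' primary to association areas when testing map-map correlations.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric per-vertex map, mean 0, SD 1.
#' @export
axis_map <- function(mesh) {
  s <- mesh$sphere_coords
  raw <- s[, 3] + 0.6 * s[, 1] + 0.4 * (s[, 1]^2 - s[, 2]^2)
  as.numeric(scale(raw))
}

#' Synthetic Desikan-Killiany-style parcellation
#'
#' Geodesic Voronoi parcels grown from random seed vertices, grouped into
#' six lobes by the spherical sector of each parcel centroid: small polar
#' caps become cingulate (north) and insula (south), the remaining four
#' quadrants of the equatorial band become frontal, temporal, parietal and
#' occipital. Eloquent analogues are designated deterministically: a
#' "precentral" parcel in the frontal lobe, "pericalcarine" and
#' "lateraloccipital" in the occipital lobe (bilateral eloquent), and
#' left-only language analogues "parsopercularis" (frontal) and
#' "transversetemporal" (temporal).
#'
#' @param mesh a [triangle_mesh()].
#' @param n_regions number of parcels (>= 8).
#' @param seed integer RNG seed.
#' @return a [parcellation()].
#' @export
make_parcellation <- function(mesh, n_regions = 24, seed = 1L) {
  stopifnot(n_regions >= 8)
  nv <- n_vertices(mesh)
  if (n_regions > nv) stop("n_regions exceeds vertex count")
  set.seed(seed)
  seeds <- sample.int(nv, n_regions)
  d <- mesh_ring_distance(mesh, seeds)        # n_regions x V
  label <- max.col(-t(d), ties.method = "first")
  s <- mesh$sphere_coords
  centroid <- function(k) {
    m <- colMeans(s[label == k, , drop = FALSE])
    m / sqrt(sum(m^2))
  }
  cents <- t(vapply(seq_len(n_regions), centroid, numeric(3)))
  sector_lobe <- function(cen) {
    if (cen[3] > 0.75) return("cingulate")
    if (cen[3] < -0.75) return("insula")
    if (cen[1] >= 0 && cen[2] >= 0) "frontal"
    else if (cen[1] >= 0 && cen[2] < 0) "temporal"
    else if (cen[1] < 0 && cen[2] >= 0) "parietal"
    else "occipital"
  }
  lobes <- vapply(seq_len(n_regions), function(k) sector_lobe(cents[k, ]),
                  character(1))
  # guarantee the four main lobes are populated (reassign nearest parcel)
  quad_dir <- rbind(frontal = c(1, 1, 0), temporal = c(1, -1, 0),
                    parietal = c(-1, 1, 0), occipital = c(-1, -1, 0))
  quad_dir <- quad_dir / sqrt(2)
  for (lb in rownames(quad_dir)) {
    need <- if (lb %in% c("frontal", "occipital")) 2L else 1L
    while (sum(lobes == lb) < need) {
      cand <- which(lobes != lb &
                      !lobes %in% c("cingulate", "insula"))
      cand <- cand[order(-(cents[cand, ] %*% quad_dir[lb, ]))]
      movable <- cand[vapply(cand, function(k)
        sum(lobes == lobes[k]) > 1, logical(1))]
      if (!length(movable)) break
      lobes[movable[1]] <- lb
    }
  }
  label_names <- paste0("parcel_", seq_len(n_regions))
  # deterministic eloquent designation by centroid direction within lobe
  pick <- function(lobe, n, taken) {
    cand <- setdiff(which(lobes == lobe), taken)
    cand[order(-cents[cand, 1])][seq_len(min(n, length(cand)))]
  }
  taken <- integer(0)
  pre <- pick("frontal", 1, taken); taken <- c(taken, pre)
  vis <- pick("occipital", 2, taken); taken <- c(taken, vis)
  ling_f <- pick("frontal", 1, taken); taken <- c(taken, ling_f)
  ling_t <- pick("temporal", 1, taken); taken <- c(taken, ling_t)
  label_names[pre] <- "precentral"
  if (length(vis) >= 1) label_names[vis[1]] <- "pericalcarine"
  if (length(vis) >= 2) label_names[vis[2]] <- "lateraloccipital"
  label_names[ling_f] <- "parsopercularis"
  label_names[ling_t] <- "transversetemporal"
  lobe_of_label <- setNames(lobes, label_names)
  parcellation(label, label_names, lobe_of_label,
               eloquent_bilateral = intersect(
                 c("precentral", "pericalcarine", "lateraloccipital"),
                 label_names),
               eloquent_left_only = intersect(
                 c("parsopercularis", "transversetemporal"), label_names))
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Defaults emulate the clinical structure of a multicentre FCD cohort:
#' median epilepsy onset around 6 years and median duration around 10
#' years (both right-skewed, log-normal), a 1:1 sex ratio, 32%
#' ever-reported-MRI-negative, about 18% of scans at 1.5 T, histopathology
#' available in 66% of patients with subtype mix approximately
#' 11/31/52/6% (I/IIA/IIB/III), 73% operated, and follow-up with median 2
#' years. Lesion centres are drawn from a smooth nonuniform density over
#' the sphere; `couplings` tilt per-patient placement along a smooth axis
#' map (positive effect: higher variable values push lesions toward the
#' high end of the axis). Outcomes are drawn from a logistic model with
#' planted coefficients (`outcome_betas`); eloquent overlap enters on its
#' raw 0-1 scale, duration as standardized log-duration, lesion size
#' standardized, scanner as an indicator of 3 T versus 1.5 T.
#'
#' @param n_patients cohort size.
#' @param lesion_radius_range integer (min, max) geodesic-disc radius in
#'   rings.
#' @param couplings named numeric vector of axis-coupling effect sizes per
#'   clinical variable (e.g., `c(age_at_onset = 0.8)`); `NULL` for none.
#' @param outcome_betas named numeric vector of planted logistic
#'   coefficients: `intercept`, `eloquent_overlap`, `duration`,
#'   `scanner3`, `lesion_size_pct`, `ever_mri_negative`.
#' @param density_concentration von Mises-Fisher concentration of the
#'   lesion-density bumps (0 gives a uniform density field).
#' @param seed integer RNG seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_patients = 200,
                              lesion_radius_range = c(1, 4),
                              couplings = c(age_at_onset = 0.8),
                              outcome_betas = c(intercept = 0,
                                                eloquent_overlap = -1.39,
                                                duration = -0.35,
                                                scanner3 = 1.04,
                                                lesion_size_pct = -0.2,
                                                ever_mri_negative = -0.32),
                              density_concentration = 3,
                              seed = 1L) {
  stopifnot(n_patients >= 1, lesion_radius_range[1] >= 1,
            lesion_radius_range[2] >= lesion_radius_range[1])
  structure(list(
    n_patients = n_patients,
    lesion_radius_range = as.integer(lesion_radius_range),
    couplings = couplings,
    outcome_betas = outcome_betas,
    density_concentration = density_concentration,
    demographics = list(onset_meanlog = log(6), onset_sdlog = 0.9,
                        duration_meanlog = log(10), duration_sdlog = 0.8,
                        p_female = 0.5, p_mri_negative = 0.32,
                        p_scanner3 = 0.82, p_histo_available = 0.66,
                        histo_probs = c(I = 0.11, IIA = 0.31,
                                        IIB = 0.52, III = 0.06),
                        p_operated = 0.73,
                        followup_meanlog = log(2), followup_sdlog = 0.6),
    seed = as.integer(seed)), class = "simulation_params")
}

# smooth nonuniform lesion-centre density (internal): a mixture of three
# von Mises-Fisher bumps at fixed directions, normalised to sum to 1.
lesion_density_field <- function(mesh, concentration) {
  s <- mesh$sphere_coords
  bumps <- rbind(c(1, 0.3, 0.2), c(0.2, -1, 0.1), c(-0.5, 0.5, -0.6))
  bumps <- bumps / sqrt(rowSums(bumps^2))
  dens <- rowSums(exp(concentration * (s %*% t(bumps))))
  dens / sum(dens)
}

#' Sample a synthetic lesion cohort
#'
#' Generates one patient at a time: demographics from the distributions in
#' `params`, a lesion centre drawn from the smooth density field (tilted
#' along [axis_map()] by any planted couplings), a geodesic-disc lesion of
#' random ring radius, and a seizure-freedom outcome from the planted
#' logistic model applied to the realised covariates. Lesion features
#' (size, lobe, eloquent overlap) are derived with
#' [derive_lesion_features()]. Fully reproducible for a fixed seed.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc the matching [parcellation()].
#' @param params a [simulation_params()] object.
#' @return list with `cohort` (a [cohort_table()]) and `masks` (list of
#'   [lesion_mask()]).
#' @export
sample_cohort <- function(mesh, parc, params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_patients
  dg <- params$demographics
  axis <- axis_map(mesh)
  dens <- lesion_density_field(mesh, params$density_concentration)
  if (all(dens == 0)) stop("lesion density field is all zero")

  sex <- ifelse(runif(n) < dg$p_female, "female", "male")
  age_at_onset <- pmin(rlnorm(n, dg$onset_meanlog, dg$onset_sdlog), 60)
  duration <- pmin(rlnorm(n, dg$duration_meanlog, dg$duration_sdlog), 50)
  age_at_scan <- age_at_onset + duration
  ever_mri_negative <- runif(n) < dg$p_mri_negative
  scanner <- ifelse(runif(n) < dg$p_scanner3, 3, 1.5)
  histo <- ifelse(runif(n) < dg$p_histo_available,
                  sample(names(dg$histo_probs), n, replace = TRUE,
                         prob = dg$histo_probs), NA_character_)
  operated <- runif(n) < dg$p_operated
  follow_up <- ifelse(operated, rlnorm(n, dg$followup_meanlog,
                                       dg$followup_sdlog), NA_real_)
  hemisphere <- ifelse(runif(n) < 0.5, "left", "right")

  clinical <- data.frame(sex = sex, age_at_onset = age_at_onset,
                         duration = duration, age_at_scan = age_at_scan,
                         ever_mri_negative = ever_mri_negative)
  # per-patient lesion-centre density: base field tilted by the couplings
  log_dens <- log(dens)
  radii <- sample(seq(params$lesion_radius_range[1],
                      params$lesion_radius_range[2]), n, replace = TRUE)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    tilt <- 0
    for (v in names(params$couplings)) {
      x <- clinical[[v]]
      if (is.null(x)) stop("unknown coupling variable: ", v)
      z <- (x[i] - mean(x)) / max(sd(x), 1e-12)
      tilt <- tilt + params$couplings[[v]] * z * axis
    }
    w <- exp(log_dens + tilt - max(log_dens + tilt))
    center <- sample.int(length(w), 1, prob = w)
    disc <- geodesic_disc(mesh, center, radii[i])
    ind <- integer(n_vertices(mesh))
    ind[disc] <- 1L
    masks[[i]] <- lesion_mask(paste0("P", sprintf("%04d", i)), ind,
                              hemisphere[i])
  }

  cohort <- data.frame(
    patient_id = paste0("P", sprintf("%04d", seq_len(n))),
    sex = sex, age_at_scan = age_at_scan, age_at_onset = age_at_onset,
    duration = duration, ever_mri_negative = ever_mri_negative,
    scanner = scanner, histopathology = histo, operated = operated,
    seizure_free = NA, follow_up = follow_up,
    lesion_hemisphere = hemisphere, stringsAsFactors = FALSE)
  cohort <- derive_lesion_features(cohort, masks, parc)

  b <- params$outcome_betas
  z <- function(x) (x - mean(x)) / max(sd(x), 1e-12)
  lp <- b[["intercept"]] +
    b[["eloquent_overlap"]] * cohort$eloquent_overlap +
    b[["duration"]] * z(log(cohort$duration)) +
    b[["scanner3"]] * (cohort$scanner == 3) +
    b[["lesion_size_pct"]] * z(cohort$lesion_size_pct) +
    b[["ever_mri_negative"]] * cohort$ever_mri_negative
  outcome_known <- operated & !is.na(follow_up) & follow_up >= 1
  sf <- rep(NA, n)
  sf[outcome_known] <- runif(sum(outcome_known)) < plogis(lp[outcome_known])
  cohort$seizure_free <- sf

  list(cohort = cohort_table(cohort), masks = masks)
}
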