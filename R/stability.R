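#' Bootstrap stability of the lesion frequency map
#'
#' How reproducible is the spatial distribution of lesions at a given sample
#' size? Per repetition, a reference subset of `ref_size` patients and a
#' disjoint test subset of each requested size are drawn at random; the
#' Spearman rank correlation between the two subsets' frequency maps (over
#' all vertices, average ranks for ties) measures map agreement.
#'
#' Reference and test subsets are disjoint by default so a small test subset
#' is never correlated with a map containing its own patients;
#' `disjoint = FALSE` allows the identity sanity check (test == reference
#' gives r = 1).
#'
#' @param masks list of [lesion_mask()] for the full cohort.
#' @param sizes integer vector of test-subset sizes.
#' @param n_reps repetitions per size (>= 1).
#' @param ref_size reference-subset size.
#' @param seed integer RNG seed.
#' @param disjoint draw test subsets disjoint from the reference (default
#'   TRUE).
#' @return data.frame with columns `size`, `rep`, `r_rank`.
#' @export
bootstrap_stability <- function(masks, sizes, n_reps = 100, ref_size,
                                seed = 1L, disjoint = TRUE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  n <- length(masks)
  need <- if (disjoint) ref_size + max(sizes) else max(ref_size, max(sizes))
  if (need > n)
    stop("subset sizes exceed available patients (", n, ")")
  m <- masks_to_matrix(masks)
  set.seed(seed)
  out <- vector("list", n_reps * length(sizes))
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    ref_idx <- sample.int(n, ref_size)
    pool <- if (disjoint) setdiff(seq_len(n), ref_idx) else seq_len(n)
    ref_map <- rowSums(m[, ref_idx, drop = FALSE])
    for (s in sizes) {
      test_idx <- if (!disjoint && s == ref_size) ref_idx
                  else sample(pool, s)
      test_map <- rowSums(m[, test_idx, drop = FALSE])
      k <- k + 1L
      out[[k]] <- data.frame(
        size = s, rep = rep_i,
        r_rank = cor(ref_map, test_map, method = "spearman"))
    }
  }
  do.call(rbind, out)
}

#' Fit a predictive learning curve to map-stability correlations
#'
#' Fits the three-parameter inverse power law
#' `r(n) = r_inf - a * n^(-b)` to the mean rank correlation per subset size
#' by nonlinear least squares, and interpolates/extrapolates the smallest
#' sample size whose predicted correlation reaches `threshold`.
#'
#' @param stability_table data.frame from [bootstrap_stability()].
#' @param threshold stability target in (0, 1\]; default 0.95.
#' @return an object of class `learning_curve_fit`: `sizes`, `mean_r`,
#'   `params` (r_inf, a, b), `threshold` and `required_n` (integer, or `NA`
#'   with `reachable = FALSE` when the fitted asymptote lies below the
#'   threshold).
#' @export
fit_learning_curve <- function(stability_table, threshold = 0.95) {
  agg <- stats::aggregate(r_rank ~ size, stability_table, mean)
  agg <- agg[order(agg$size), ]
  if (nrow(agg) < 3) stop("need >= 3 distinct subset sizes")
  if (sd(agg$r_rank) < 1e-12) {
    # degenerate flat input: asymptote is the observed constant
    r_inf <- agg$r_rank[1]
    fit <- list(sizes = agg$size, mean_r = agg$r_rank,
                params = c(r_inf = r_inf, a = 0, b = 1),
                threshold = threshold,
                reachable = r_inf >= threshold,
                required_n = if (r_inf >= threshold) min(agg$size)
                             else NA_integer_)
    class(fit) <- "learning_curve_fit"
    return(fit)
  }
  start <- list(r_inf = min(1, max(agg$r_rank) + 0.02), a = 1, b = 0.5)
  nls_fit <- minpack.lm::nlsLM(
    r_rank ~ r_inf - a * size^(-b), data = agg, start = start,
    lower = c(r_inf = -1, a = 1e-8, b = 1e-3),
    upper = c(r_inf = 1, a = Inf, b = 5),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- coef(nls_fit)
  predicted <- function(n) p[["r_inf"]] - p[["a"]] * n^(-p[["b"]])
  reachable <- p[["r_inf"]] >= threshold
  required_n <- NA_integer_
  if (reachable) {
    if (predicted(min(agg$size)) >= threshold) {
      required_n <- as.integer(min(agg$size))
    } else {
      # smallest integer n with r(n) >= threshold (monotone for a, b > 0)
      n_star <- (p[["a"]] / (p[["r_inf"]] - threshold))^(1 / p[["b"]])
      required_n <- as.integer(ceiling(n_star - 1e-9))
    }
  }
  structure(list(sizes = agg$size, mean_r = agg$r_rank, params = p,
                 threshold = threshold, reachable = reachable,
                 required_n = required_n),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat("learning_curve_fit: r(n) = ",
      sprintf("%.4f - %.4g * n^(-%.4g)\n", x$params[["r_inf"]],
              x$params[["a"]], x$params[["b"]]))
  if (x$reachable)
    cat("  reaches r >=", x$threshold, "at n =", x$required_n, "\n")
  else
    cat("  threshold", x$threshold, "unreachable (asymptote",
        sprintf("%.4f", x$params[["r_inf"]]), ")\n")
  invisible(x)
}
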