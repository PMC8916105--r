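#' Variable metadata for the pairwise association screen
#'
#' Classifies a cohort variable as continuous, binary or categorical and,
#' for continuous variables, marks it as heavily skewed when the absolute
#' sample skewness exceeds `skew_threshold` (such variables are Box-Cox
#' normalized before parametric testing).
#'
#' @param values the variable's values.
#' @param name variable name.
#' @param skew_threshold absolute-skewness cutoff (default 1).
#' @return object of class `variable_meta`: `name`, `kind`, `skewed`.
#' @export
variable_meta <- function(values, name, skew_threshold = 1) {
  v <- values[!is.na(values)]
  if (is.numeric(v) && length(unique(v)) > 2) {
    kind <- "continuous"
    skewed <- abs(e1071::skewness(v)) > skew_threshold
  } else {
    nlev <- length(unique(as.character(v)))
    kind <- if (nlev <= 2) "binary" else "categorical"
    skewed <- FALSE
  }
  structure(list(name = name, kind = kind, skewed = skewed),
            class = "variable_meta")
}

#' Box-Cox normalization
#'
#' Maximum-likelihood Box-Cox power transform
#' `(x^lambda - 1) / lambda` (log for lambda = 0). Values are shifted by
#' +1 beforehand whenever the minimum is <= 0 (the transform needs
#' positive input). Constant input is returned unchanged with a warning.
#'
#' @param values numeric vector (`NA` passed through).
#' @param lambda optional fixed lambda; estimated by maximum likelihood
#'   (via `car::powerTransform`) when `NULL`.
#' @return list with `transformed`, `lambda`, `shift`.
#' @export
boxcox_normalize <- function(values, lambda = NULL) {
  ok <- !is.na(values)
  x <- values[ok]
  if (sd(x) < 1e-12) {
    warning("constant input; Box-Cox transform skipped")
    return(list(transformed = values, lambda = 1, shift = 0))
  }
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  x <- x + shift
  if (is.null(lambda))
    lambda <- as.numeric(car::powerTransform(x ~ 1)$lambda)
  z <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  list(transformed = out, lambda = lambda, shift = shift)
}

#' Choose the pairwise test for two variable kinds
#'
#' Continuous-continuous pairs are tested by correlation,
#' continuous-binary by a two-sample t test, continuous-categorical (>2
#' levels) by one-way ANOVA (with Tukey HSD post hoc), and
#' categorical/binary pairs by a Pearson chi-square test.
#'
#' @param kind_a,kind_b `"continuous"`, `"binary"` or `"categorical"`.
#' @return test name: `"correlation"`, `"t_test"`, `"anova"` or
#'   `"chi_square"`.
#' @export
select_test <- function(kind_a, kind_b) {
  kinds <- sort(c(kind_a, kind_b))
  if (all(kinds == "continuous")) return("correlation")
  if (identical(kinds, c("binary", "continuous"))) return("t_test")
  if (identical(kinds, c("categorical", "continuous"))) return("anova")
  "chi_square"
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on a contingency table, without continuity
#' correction, df = (rows - 1)(cols - 1).
#'
#' @param table matrix of contingency counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Standard step-up rule at level `alpha`: the k smallest p-values are
#' rejected, where k is the largest i with `p_(i) <= i * alpha / m`.
#'
#' @param p_values numeric vector in \[0, 1\] (`NA` never rejected).
#' @param alpha FDR level (default 0.05).
#' @return logical rejection flags, same order as the input.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  out <- p.adjust(p_values, method = "BH") <= alpha
  out[is.na(out)] <- FALSE
  out
}

#' Post hoc pairwise comparisons within a grouped variable
#'
#' For a continuous outcome across >= 3 groups, Tukey's HSD over all group
#' pairs (following a one-way ANOVA). For a binary outcome across groups,
#' pairwise two-proportion z tests with Holm correction - a pragmatic
#' reading of "post hoc after chi-square", which has no canonical
#' procedure. Groups with fewer than 2 observations are excluded with a
#' warning.
#'
#' @param values outcome values (numeric, or binary/logical).
#' @param groups group labels, same length.
#' @return data.frame with `pair`, `estimate` (mean or proportion
#'   difference), `p_value` (adjusted).
#' @export
posthoc_pairwise <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  if (is.numeric(values) && length(unique(values)) > 2) {
    if (nlevels(g) < 2) stop("Tukey post hoc needs >= 2 groups")
    hsd <- TukeyHSD(aov(values ~ g))$g
    return(data.frame(pair = rownames(hsd), estimate = hsd[, "diff"],
                      p_value = hsd[, "p adj"], row.names = NULL))
  }
  y <- as.integer(as.logical(values))
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- y[g == pr[1]]; b <- y[g == pr[2]]
    pt <- suppressWarnings(stats::prop.test(c(sum(a), sum(b)),
                                            c(length(a), length(b)),
                                            correct = FALSE))
    c(est = mean(a) - mean(b), p = pt$p.value)
  })
  data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
             estimate = res["est", ],
             p_value = p.adjust(res["p", ], method = "holm"),
             row.names = NULL)
}

#' Systematic pairwise association screen
#'
#' Tests every unordered pair of cohort variables with the test selected
#' by [select_test()]. Heavily skewed continuous variables are Box-Cox
#' normalized first. All raw p-values are pooled and passed through the
#' Benjamini-Hochberg procedure at `alpha`; pairs with fewer than 3
#' complete cases (or a degenerate table) are marked untestable.
#'
#' @param cohort a [cohort_table()] (or plain data.frame).
#' @param variables character vector of column names to screen.
#' @param alpha FDR level (default 0.05).
#' @param cor_method `"pearson"` (default) or `"spearman"` for
#'   continuous-continuous pairs.
#' @param skew_threshold passed to [variable_meta()].
#' @return data.frame of class `pairwise_grid`: `var_a`, `var_b`, `test`,
#'   `statistic`, `p_value`, `fdr_significant`, `untestable`.
#' @export
pairwise_grid <- function(cohort, variables, alpha = 0.05,
                          cor_method = c("pearson", "spearman"),
                          skew_threshold = 1) {
  cor_method <- match.arg(cor_method)
  if (length(variables) < 2) stop("need at least 2 variables")
  missing <- setdiff(variables, names(cohort))
  if (length(missing))
    stop("unknown cohort field(s): ", paste(missing, collapse = ", "))
  meta <- lapply(variables, function(v)
    variable_meta(cohort[[v]], v, skew_threshold))
  names(meta) <- variables
  vals <- lapply(variables, function(v) cohort[[v]])
  names(vals) <- variables
  for (v in variables) {
    if (meta[[v]]$kind == "continuous" && meta[[v]]$skewed)
      vals[[v]] <- boxcox_normalize(vals[[v]])$transformed
  }
  pairs <- utils::combn(variables, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    va <- pairs[1, k]; vb <- pairs[2, k]
    test <- select_test(meta[[va]]$kind, meta[[vb]]$kind)
    # orient so a continuous variable is first for t test / ANOVA
    if (meta[[va]]$kind != "continuous" && meta[[vb]]$kind == "continuous") {
      tmp <- va; va <- vb; vb <- tmp
    }
    x <- vals[[va]]; y <- vals[[vb]]
    ok <- !is.na(x) & !is.na(y)
    base <- data.frame(var_a = pairs[1, k], var_b = pairs[2, k],
                       test = test, statistic = NA_real_,
                       p_value = NA_real_, untestable = TRUE)
    if (sum(ok) < 3) return(base)
    x <- x[ok]; y <- y[ok]
    res <- tryCatch(switch(test,
      correlation = {
        ct <- stats::cor.test(x, y, method = cor_method)
        c(ct$estimate, ct$p.value)
      },
      t_test = {
        g <- factor(as.character(y))
        if (nlevels(g) < 2) stop("single level")
        tt <- t.test(x ~ g)
        c(tt$statistic, tt$p.value)
      },
      anova = {
        g <- factor(as.character(y))
        if (nlevels(g) < 2) stop("single level")
        av <- summary(aov(x ~ g))[[1]]
        c(av$`F value`[1], av$`Pr(>F)`[1])
      },
      chi_square = {
        tab <- table(as.character(x), as.character(y))
        cs <- chi_square(tab)
        c(cs$statistic, cs$p_value)
      }), error = function(e) NULL)
    if (is.null(res) || anyNA(res)) return(base)
    base$statistic <- unname(res[1])
    base$p_value <- unname(res[2])
    base$untestable <- FALSE
    base
  })
  grid <- do.call(rbind, rows)
  grid$fdr_significant <- bh_fdr(grid$p_value, alpha)
  class(grid) <- c("pairwise_grid", class(grid))
  grid
}
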