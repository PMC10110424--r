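test_result <- function(method, statistic, df1, df2 = NA_real_, p_value) {
  tibble::tibble(
    method = method, statistic = as.numeric(statistic),
    df1 = as.numeric(df1), df2 = as.numeric(df2),
    p_value = as.numeric(p_value)
  )
}

check_grouped <- function(values, group, min_per_group = 2L) {
  if (length(values) != length(group)) {
    stop("`values` and `group` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  n <- table(droplevels(group))
  if (any(n < min_per_group)) {
    stop("every group needs >= ", min_per_group, " values; too small: ",
         paste(names(n)[n < min_per_group], collapse = ", "),
         call. = FALSE)
  }
  droplevels(group)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances, the
#' appropriate omnibus test when homoscedasticity fails (as judged by
#' [levene_test()]). For exactly two groups the statistic equals the
#' squared Welch two-sample t statistic and the p-values coincide.
#' Computed via [stats::oneway.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite denominator degrees of freedom). Despite sometimes
#' being described as non-parametric in the applied literature, Welch's
#' ANOVA is a parametric test; no rank transform is applied here.
#'
#' @param values Numeric measurements.
#' @param group Parallel vector of group labels.
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`
#'   (fractional), `p_value`.
#' @export
welch_anova <- function(values, group) {
  group <- check_grouped(values, group)
  v <- tapply(values, group, stats::var)
  if (all(v == 0)) {
    m <- tapply(values, group, mean)
    if (max(m) - min(m) == 0) {
      return(test_result("Welch's ANOVA", 0, nlevels(group) - 1,
                         NA_real_, 1))
    }
    stop("degenerate variance: all groups constant with unequal means",
         call. = FALSE)
  }
  if (any(v == 0)) {
    stop("degenerate variance: group(s) with zero variance: ",
         paste(levels(group)[v == 0], collapse = ", "), call. = FALSE)
  }
  ht <- stats::oneway.test(values ~ group, var.equal = FALSE)
  test_result("Welch's ANOVA", ht$statistic, ht$parameter[1],
              ht$parameter[2], ht$p.value)
}

#' Two-sample variance-ratio F-test
#'
#' Compares the variances of two samples with `F = var(a) / var(b)` on
#' `(n_a - 1, n_b - 1)` degrees of freedom; the two-sided p-value doubles
#' the smaller tail (via [stats::var.test()]). This is the test used to ask
#' whether one genotype is more variable than the other.
#'
#' @param a,b Numeric samples with >= 2 values each.
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
variance_ratio_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(b) == 0) {
    stop("zero variance in the denominator sample", call. = FALSE)
  }
  ht <- stats::var.test(a, b)
  test_result("F test to compare two variances", ht$statistic,
              ht$parameter[1], ht$parameter[2], ht$p.value)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group centres. The
#' default centre is the group median (the Brown-Forsythe variant, robust
#' to non-normality); `center = "mean"` gives the classical Levene test.
#' Computed via [car::leveneTest()].
#'
#' @param values Numeric measurements.
#' @param group Parallel vector of group labels.
#' @param center `"median"` (default) or `"mean"`.
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
levene_test <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  group <- check_grouped(values, group)
  v <- tapply(values, group, stats::var)
  if (all(v == 0)) {
    stop("degenerate groups: all values constant within every group",
         call. = FALSE)
  }
  ht <- car::leveneTest(values ~ group,
                        center = if (center == "median") stats::median
                                 else mean)
  test_result(paste0("Levene's test (center = ", center, ")"),
              ht$`F value`[1], ht$Df[1], ht$Df[2], ht$`Pr(>F)`[1])
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' All pairwise mean comparisons after a heteroscedastic omnibus test; the
#' unequal-variance alternative to Tukey's HSD. For each pair the
#' statistic is the Welch t on the two groups and the p-value comes from
#' the studentized-range distribution with `k` means and Welch-
#' Satterthwaite degrees of freedom, which adjusts internally for the
#' number of comparisons.
#'
#' @param values Numeric measurements.
#' @param group Parallel vector of group labels (>= 2 groups).
#' @return A tibble with one row per pair: `group1`, `group2`,
#'   `mean_diff` (group2 - group1), `statistic` (Welch t), `df`,
#'   `p_value`, and `flagged` (`TRUE` where a degenerate pair -- both
#'   variances zero -- made the comparison impossible; other pairs are
#'   still returned).
#' @export
games_howell <- function(values, group) {
  group <- check_grouped(values, group)
  k <- nlevels(group)
  m <- tapply(values, group, mean)
  v <- tapply(values, group, stats::var)
  n <- tapply(values, group, length)
  pairs <- utils::combn(levels(group), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se2 <- v[g1] / n[g1] + v[g2] / n[g2]
    if (se2 == 0) {
      return(tibble::tibble(
        group1 = g1, group2 = g2, mean_diff = unname(m[g2] - m[g1]),
        statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        flagged = TRUE
      ))
    }
    t_stat <- unname((m[g2] - m[g1]) / sqrt(se2))
    df <- unname(se2^2 / ((v[g1] / n[g1])^2 / (n[g1] - 1) +
                            (v[g2] / n[g2])^2 / (n[g2] - 1)))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble::tibble(
      group1 = g1, group2 = g2, mean_diff = unname(m[g2] - m[g1]),
      statistic = t_stat, df = df, p_value = p, flagged = FALSE
    )
  })
  dplyr::bind_rows(res)
}

#' Cliff's delta dominance effect size
#'
#' The probability that a value from `a` exceeds one from `b` minus the
#' reverse: `delta = (#[a_i > b_j] - #[a_i < b_j]) / (n_a * n_b)`, on
#' `[-1, 1]`; positive when `a` stochastically dominates `b`. Being purely
#' rank-based it is invariant under strictly monotone transforms.
#' Magnitude bands follow the conventional thresholds: |delta| < 0.147
#' negligible, < 0.33 small, < 0.474 medium, otherwise large.
#'
#' @param a,b Non-empty numeric samples.
#' @return A list of class `effect_size`: `name`, `value`, `band`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))$value # -0.5556
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  cmp <- sign(outer(a, b, `-`))
  delta <- sum(cmp) / (length(a) * length(b))
  structure(
    list(name = "cliffs_delta", value = delta, band = effect_band(delta)),
    class = "effect_size"
  )
}

effect_band <- function(x) {
  ax <- abs(x)
  if (ax < 0.147) "negligible"
  else if (ax < 0.33) "small"
  else if (ax < 0.474) "medium"
  else "large"
}

#' Omega-squared effect size for a one-way ANOVA
#'
#' Variance explained by the group factor, corrected for its expectation
#' under the null:
#' \deqn{\omega^2 = (SS_b - df_b MS_w) / (SS_t + MS_w).}
#' Less biased than eta-squared; small-sample estimates may be slightly
#' negative. Magnitude bands: < 0.01 negligible, < 0.06 small, < 0.14
#' medium, otherwise large.
#'
#' @param x Either a fitted [stats::aov()] / [stats::lm()] one-way model,
#'   or a list with fields `ss_between`, `df_between`, `ss_within`,
#'   `df_within`.
#' @return A list of class `effect_size`: `name`, `value`, `band`.
#' @export
omega_squared <- function(x) {
  if (inherits(x, c("aov", "lm"))) {
    tab <- stats::anova(x)
    dec <- list(ss_between = tab$`Sum Sq`[1], df_between = tab$Df[1],
                ss_within = tab$`Sum Sq`[2], df_within = tab$Df[2])
  } else {
    dec <- x
    req <- c("ss_between", "df_between", "ss_within", "df_within")
    if (!all(req %in% names(dec))) {
      stop("`x` must be an aov/lm fit or a list with fields ",
           paste(req, collapse = ", "), call. = FALSE)
    }
  }
  ss_total <- dec$ss_between + dec$ss_within
  if (!is.finite(ss_total) || ss_total <= 0) {
    stop("non-positive total sum of squares", call. = FALSE)
  }
  ms_within <- dec$ss_within / dec$df_within
  value <- (dec$ss_between - dec$df_between * ms_within) /
    (ss_total + ms_within)
  band <- {
    av <- abs(value)
    if (av < 0.01) "negligible"
    else if (av < 0.06) "small"
    else if (av < 0.14) "medium"
    else "large"
  }
  structure(list(name = "omega_squared", value = value, band = band),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.4f (%s)\n", x$name, x$value, x$band))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. The p-value uses the t approximation
#' (`exact = FALSE` in [stats::cor.test()]), which handles ties and
#' matches common practice for organoid-sized samples.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho is undefined for a constant vector", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       method = "Spearman rank correlation (t approximation)")
}

#' Principal component analysis of an organoid-by-variable matrix
#'
#' Centred (and by default unit-variance scaled) PCA via
#' [stats::prcomp()]. Standardisation is the default because flow and
#' kinetics variables live on heterogeneous scales (counts, hours,
#' fractions). Missing values are an error: no silent imputation.
#'
#' @param x A numeric matrix or data frame, organoids in rows, variables
#'   in columns (>= 2 of each).
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @return A list: `scores` (organoids x components), `loadings`
#'   (orthonormal, variables x components), `explained_variance`
#'   (eigenvalues; sums to the number of variables when standardised),
#'   `explained_fraction`.
#' @export
run_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("PCA needs >= 2 rows and >= 2 columns", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("missing values in the input; impute or drop before PCA",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("zero-variance column(s) cannot be standardised: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- fit$sdev^2
  list(
    scores = fit$x,
    loadings = fit$rotation,
    explained_variance = ev,
    explained_fraction = ev / sum(ev)
  )
}

#' Batch-aware mixed-effects genotype contrast
#'
#' Fits `response ~ genotype` with batch as a random effect, the model
#' used to separate a genotype effect from batch-to-batch baseline
#' differences. The default random structure is a random intercept and
#' genotype slope by batch (batches may differ both in baseline and in how
#' strongly genotype manifests); if that fit is singular it falls back to
#' a random intercept only, recorded in `singular_fallback`. The genotype
#' test is a type III F test with Satterthwaite denominator degrees of
#' freedom ([lmerTest]).
#'
#' @param data A data frame with the response column, a `genotype` column
#'   and a `batch` column.
#' @param response Name of the response column.
#' @param random `"intercept_and_slope_by_batch"` (default) or
#'   `"intercept_by_batch"`.
#' @return A list: `estimate` (fixed-effect genotype contrast),
#'   `statistic` (F), `df1`, `df2` (Satterthwaite), `p_value`,
#'   `random_structure` (the structure actually fitted),
#'   `singular_fallback`, `method`, and `model` (the `lmerModLmerTest`
#'   fit).
#' @export
fit_genotype_lme <- function(data, response,
                             random = c("intercept_and_slope_by_batch",
                                        "intercept_by_batch")) {
  random <- match.arg(random)
  req <- c(response, "genotype", "batch")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("data are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$batch <- as.factor(data$batch)
  data$genotype <- as.factor(data$genotype)
  if (nlevels(droplevels(data$batch)) < 2L) {
    stop("only one batch present: there is no batch variance to model; ",
         "use welch_anova() instead", call. = FALSE)
  }
  if (nlevels(droplevels(data$genotype)) < 2L) {
    stop("genotype does not vary in the data", call. = FALSE)
  }
  forms <- list(
    intercept_and_slope_by_batch =
      stats::as.formula(paste0("`", response, "` ~ genotype + ",
                               "(1 + genotype | batch)")),
    intercept_by_batch =
      stats::as.formula(paste0("`", response, "` ~ genotype + (1 | batch)"))
  )
  fit_one <- function(structure_name) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(forms[[structure_name]], data = data,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
    ))
  }
  used <- random
  fit <- fit_one(used)
  fallback <- FALSE
  if (used == "intercept_and_slope_by_batch" && lme4::isSingular(fit)) {
    used <- "intercept_by_batch"
    fit <- fit_one(used)
    fallback <- TRUE
  }
  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  fe <- lme4::fixef(fit)
  est <- unname(fe[grep("^genotype", names(fe))][1])
  list(
    estimate = est,
    statistic = an[["F value"]][1],
    df1 = an[["NumDF"]][1],
    df2 = an[["DenDF"]][1],
    p_value = an[["Pr(>F)"]][1],
    random_structure = used,
    singular_fallback = fallback,
    method = "LME genotype contrast, type III F (Satterthwaite)",
    model = fit
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalises a target gene's Ct to the arithmetic mean Ct of two
#' housekeeping genes per sample (equivalent to the geometric mean of
#' their expression), references the result to the mean delta-Ct of a
#' calibrator group, and reports fold change `2^(-ddCt)`.
#'
#' @param data Long-format qPCR table with columns `sample_id`, `group`,
#'   `gene`, `ct` (finite, positive).
#' @param target Target gene name.
#' @param housekeeping Character vector of exactly two housekeeping gene
#'   names.
#' @param calibrator_group Group whose mean delta-Ct is the reference
#'   (default `"control"`).
#' @return A tibble with one row per sample: `sample_id`, `group`,
#'   `delta_ct`, `ddct`, `fold_change`.
#' @export
ddct <- function(data, target, housekeeping,
                 calibrator_group = "control") {
  req <- c("sample_id", "group", "gene", "ct")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("data are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(housekeeping) != 2L) {
    stop("exactly two housekeeping genes are required", call. = FALSE)
  }
  if (any(!is.finite(data$ct) | data$ct <= 0)) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  needed <- c(target, housekeeping)
  for (sid in unique(data$sample_id)) {
    genes <- data$gene[data$sample_id == sid]
    absent <- setdiff(needed, genes)
    if (length(absent)) {
      stop("sample ", sid, " is missing gene(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  per_sample <- data |>
    dplyr::filter(.data$gene %in% needed) |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(
      delta_ct = .data$ct[.data$gene == target][1] -
        mean(.data$ct[.data$gene %in% housekeeping]),
      .groups = "drop"
    )
  cal <- per_sample$delta_ct[per_sample$group == calibrator_group]
  if (length(cal) == 0L) {
    stop("calibrator group '", calibrator_group, "' is empty",
         call. = FALSE)
  }
  per_sample |>
    dplyr::mutate(
      ddct = .data$delta_ct - mean(cal),
      fold_change = 2^(-.data$ddct)
    )
}
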