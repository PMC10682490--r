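#' Covariate-adjusted omnibus group test for one metric
#'
#' Fits an ordinary least-squares model of the metric on group indicators
#' plus covariates (the ANCOVA reading of a Gaussian GLM) and tests the
#' omnibus group effect with a partial F against the covariates-only
#' model. With no covariates this reduces exactly to one-way ANOVA.
#'
#' @param data Data frame holding metric, group and covariate columns.
#' @param value Name of the metric column.
#' @param group Name of the grouping column (>= 2 levels, each n >= 3).
#' @param covariates Character vector of covariate column names (default
#'   age, sex, education, site when present); categorical covariates are
#'   expanded to indicators by the model formula.
#' @return One-row tibble: `statistic` (partial F), `df1`, `df2`,
#'   `p_value`, `n`, `covariates`.
#' @export
metric_group_test <- function(data, value = "value", group = "group",
                              covariates = intersect(c("age", "sex", "education", "site"),
                                                     names(data))) {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  if (!all(covariates %in% names(data))) {
    stop_sg("missing covariate column(s): ",
            paste(setdiff(covariates, names(data)), collapse = ", "))
  }
  df <- data[stats::complete.cases(data[c(value, group, covariates)]), , drop = FALSE]
  g <- droplevels(factor(df[[group]]))
  if (nlevels(g) < 2L) stop_sg("need at least 2 groups")
  if (any(table(g) < 3L)) stop_sg("every group needs n >= 3")
  df[[group]] <- g

  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::reformulate(c(covariates, group), response = value)
  f_red <- stats::reformulate(rhs0, response = value)
  mm <- stats::model.matrix(f_full, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop_sg("rank-deficient design; collinear column(s): ",
            paste(aliased, collapse = ", "))
  }
  fit_full <- stats::lm(f_full, df)
  fit_red <- stats::lm(f_red, df)
  an <- stats::anova(fit_red, fit_full)
  tibble::tibble(statistic = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                 p_value = an$`Pr(>F)`[2], n = nrow(df),
                 covariates = paste(covariates, collapse = ","))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' adjusted values are monotone in the raw p-values and never smaller
#' than them.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_sg("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group tests over the full network-metric family
#'
#' Runs [metric_group_test()] for every network metric (for a K-network
#' partition: K WNC + K OVO + K(K-1)/2 BNC, i.e. 65 metrics when K = 10)
#' and adjusts the whole family with Benjamini-Hochberg FDR. The family
#' size is computed from the networks present, never hard-coded.
#'
#' @param summaries Long per-subject summary tibble from
#'   [summarize_cohort()].
#' @param subjects Phenotype table with `subject_id`, `group` and the
#'   covariate columns.
#' @param covariates Covariate names passed to [metric_group_test()].
#' @param groups Optional subset of group labels to contrast (default all
#'   present); e.g. `c("HC", "MDDSB")` for one pairwise contrast.
#' @return Tibble of class `sg_metric_tests`, one row per metric:
#'   `metric_type`, `name`, `statistic`, `df1`, `df2`, `p_value`,
#'   `p_adjusted`, `n`, `covariates`.
#' @export
metric_test_table <- function(summaries, subjects,
                              covariates = c("age", "sex", "education", "site"),
                              groups = NULL) {
  stopifnot(all(c("subject_id", "metric_type", "name", "value") %in% names(summaries)))
  subj <- subjects
  if (!is.null(groups)) subj <- subj[subj$group %in% groups, , drop = FALSE]
  merged <- dplyr::inner_join(summaries,
                              dplyr::select(subj, "subject_id", "group",
                                            dplyr::all_of(covariates)),
                              by = "subject_id")
  nets <- unique(merged$net_a[merged$metric_type == "wnc"])
  k <- length(nets)
  expected <- k + k + choose(k, 2)
  out <- merged |>
    dplyr::group_by(.data$metric_type, .data$name) |>
    dplyr::group_modify(~ metric_group_test(.x, value = "value", group = "group",
                                            covariates = covariates)) |>
    dplyr::ungroup()
  if (nrow(out) != expected) {
    stop_sg("expected ", expected, " metrics for ", k, " networks, got ", nrow(out))
  }
  out$p_adjusted <- fdr_adjust(out$p_value)
  class(out) <- c("sg_metric_tests", class(out))
  out
}

#' Demographic and clinical comparison table
#'
#' Group comparisons of phenotype variables the way cohort tables are
#' built: one-way ANOVA with least-significant-difference (LSD) post-hoc
#' pairwise tests for continuous variables, chi-squared tests for
#' categorical ones (no Yates continuity correction by default; it only
#' ever applies to 2x2 tables).
#'
#' @param subjects Phenotype data frame with a `group` column.
#' @param continuous,categorical Variable names to test.
#' @param correct Continuity correction for 2x2 chi-squared (default
#'   `FALSE`).
#' @return Tibble, one row per variable: `variable`, `test` ("anova" or
#'   "chi_squared"), `statistic`, `df`, `p_value`, `posthoc` (list column
#'   of LSD pairwise tibbles for continuous variables).
#' @export
demographic_table <- function(subjects,
                              continuous = intersect(c("age", "education", "hamd_total",
                                                       "hamd_anxiety", "hamd_weight",
                                                       "hamd_retardation", "hamd_sleep"),
                                                     names(subjects)),
                              categorical = intersect("sex", names(subjects)),
                              correct = FALSE) {
  g_all <- droplevels(factor(subjects$group))
  if (nlevels(g_all) < 2L) stop_sg("need at least 2 groups")
  rows <- list()
  for (v in continuous) {
    ok <- !is.na(subjects[[v]]) & !is.na(g_all)
    y <- subjects[[v]][ok]; g <- droplevels(g_all[ok])
    if (nlevels(g) < 2L) next
    if (any(table(g) < 2L)) stop_sg("ANOVA for '", v, "' has a group with n < 2")
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    rows[[v]] <- tibble::tibble(variable = v, test = "anova",
                                statistic = an$`F value`[1], df = an$Df[1],
                                p_value = an$`Pr(>F)`[1],
                                posthoc = list(lsd_posthoc(y, g)))
  }
  for (v in categorical) {
    ok <- !is.na(subjects[[v]]) & !is.na(g_all)
    tab <- table(subjects[[v]][ok], droplevels(g_all[ok]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    rows[[v]] <- tibble::tibble(variable = v, test = "chi_squared",
                                statistic = unname(ct$statistic),
                                df = unname(ct$parameter),
                                p_value = ct$p.value, posthoc = list(NULL))
  }
  dplyr::bind_rows(rows)
}

#' Least-significant-difference pairwise tests
#'
#' Pairwise t-tests using the pooled ANOVA error term and its residual
#' degrees of freedom, with no multiplicity correction -- that is what LSD
#' means, so interpret the p-values accordingly.
#'
#' @param y Numeric response.
#' @param g Grouping factor.
#' @return Tibble `group1`, `group2`, `diff`, `statistic`, `p_value`
#'   (uncorrected).
#' @export
lsd_posthoc <- function(y, g) {
  g <- droplevels(factor(g))
  fit <- stats::aov(y ~ g)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  means <- tapply(y, g, mean); ns <- table(g)
  levs <- levels(g)
  cmb <- utils::combn(levs, 2L)
  purrr::map_dfr(seq_len(ncol(cmb)), function(q) {
    a <- cmb[1, q]; b <- cmb[2, q]
    d <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tt <- d / se
    tibble::tibble(group1 = a, group2 = b, diff = d, statistic = tt,
                   p_value = 2 * stats::pt(-abs(tt), fit$df.residual))
  })
}

#' Covariate-controlled Pearson correlation
#'
#' Partial correlation between two variables after residualizing both on
#' the covariates (with intercept): the Pearson correlation of the
#' residuals, with a t-based p-value on n - k - 2 degrees of freedom
#' (k = number of covariate design columns beyond the intercept). With no
#' covariates this is the plain Pearson correlation and its usual test.
#'
#' @param data Data frame.
#' @param x,y Column names of the two variables.
#' @param covariates Covariate column names (categorical allowed).
#' @return One-row tibble `r`, `df`, `p_value`, `n`.
#' @export
partial_pearson <- function(data, x, y, covariates = character(0)) {
  cols <- c(x, y, covariates)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(df)
  if (length(covariates)) {
    # model matrix built from the covariates alone so metric names need not
    # be syntactic R names
    mm <- stats::model.matrix(stats::reformulate(covariates),
                              df[covariates])
    if (qr(mm)$rank < ncol(mm)) stop_sg("rank-deficient covariate design")
    k <- ncol(mm) - 1L
    rx <- stats::lm.fit(mm, df[[x]])$residuals
    ry <- stats::lm.fit(mm, df[[y]])$residuals
  } else {
    k <- 0L
    rx <- df[[x]]; ry <- df[[y]]
  }
  dfree <- n - k - 2L
  if (dfree < 1L) stop_sg("too few observations for ", k, " covariate columns")
  if (stats::sd(rx) < 1e-10 || stats::sd(ry) < 1e-10) {
    # a variable fully explained by the covariates carries no residual
    # association
    return(tibble::tibble(r = 0, df = dfree, p_value = 1, n = n))
  }
  r <- stats::cor(rx, ry)
  tt <- r * sqrt(dfree / (1 - r^2))
  tibble::tibble(r = r, df = dfree, p_value = 2 * stats::pt(-abs(tt), dfree), n = n)
}

# Wilcoxon rank-sum p-value policy: exact enumeration for small tie-free
# samples (both n <= 10), tie-corrected normal approximation without
# continuity correction otherwise.
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop_sg("empty stratum in rank-sum test")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 10L && length(b) <= 10L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact, n1 = length(a), n2 = length(b))
}

#' Sex / age heterogeneity screen
#'
#' Two-sided Wilcoxon rank-sum tests of each variable between the two
#' strata of a demographic split: `"sex"` (female vs male) or `"age"`
#' (younger, 18-37, vs older, 38-65; 37 is the last "younger" year).
#' P-values are reported on the log10 scale with the conventional
#' significance line at log10(0.05), about -1.301.
#'
#' @param data Data frame containing the variables plus `sex` and/or
#'   `age`.
#' @param variables Column names to screen.
#' @param split `"sex"` or `"age"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble `variable`, `split`, `statistic` (rank-sum W), `p_value`,
#'   `log10_p`, `exact`, `significant`.
#' @export
heterogeneity_screen <- function(data, variables, split = c("sex", "age"),
                                 alpha = 0.05) {
  split <- match.arg(split)
  stopifnot(all(variables %in% names(data)))
  strata <- if (split == "sex") {
    factor(data$sex, levels = c("female", "male"))
  } else {
    factor(ifelse(data$age <= 37, "younger", "older"),
           levels = c("younger", "older"))
  }
  if (any(table(strata) < 2L)) stop_sg("both strata need n >= 2 for split '", split, "'")
  purrr::map_dfr(variables, function(v) {
    res <- rank_sum_test(data[[v]][strata == levels(strata)[1]],
                         data[[v]][strata == levels(strata)[2]])
    dplyr::mutate(res, variable = v, split = split,
                  log10_p = log10(.data$p_value),
                  significant = .data$p_value < alpha, .before = 1L)
  })
}
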