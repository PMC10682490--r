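test_that("covariate-free group test equals classical one-way ANOVA", {
  withr::local_seed(1)
  d <- tibble::tibble(value = rnorm(60), group = rep(c("a", "b", "c"), each = 20))
  res <- metric_group_test(d, covariates = character(0))
  oracle <- summary(aov(value ~ group, data = d))[[1]]
  expect_equal(res$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("group test is calibrated under the null and powered under signal", {
  withr::local_seed(2)
  pvals <- vapply(1:200, function(i) {
    d <- tibble::tibble(value = rnorm(40), group = rep(c("a", "b"), each = 20),
                        age = rnorm(40), sex = sample(c("f", "m"), 40, TRUE))
    metric_group_test(d)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01); expect_lte(rate, 0.09)

  hits <- vapply(1:100, function(i) {
    d <- tibble::tibble(value = c(rnorm(30), rnorm(30, 1.5)),
                        group = rep(c("a", "b"), each = 30))
    metric_group_test(d, covariates = character(0))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("confounded designs fail naming the collinear columns", {
  d <- tibble::tibble(value = rnorm(20), group = rep(c("a", "b"), each = 10),
                      site = rep(c("s1", "s2"), each = 10), age = rnorm(20))
  expect_error(metric_group_test(d, covariates = c("age", "site")),
               "collinear.*group")
})

test_that("BH adjustment matches hand arithmetic and a brute-force oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bh_oracle <- function(p) {  # literal step-up definition
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  withr::local_seed(3)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("the metric family for 10 networks has exactly 65 rows with valid FDR", {
  coh <- test_cohort()
  tt <- metric_test_table(test_summaries(), coh$subjects)
  k <- length(network_names(coh$partition))
  expect_equal(nrow(tt), k + k + choose(k, 2))
  expect_equal(nrow(tt), 65)
  expect_true(all(tt$p_adjusted >= tt$p_value - 1e-15))
  expect_true(all(tt$p_adjusted > 0 & tt$p_adjusted <= 1))
  expect_equal(sum(tt$metric_type == "bnc"), choose(k, 2))
})

test_that("demographic table uses ANOVA + LSD and chi-squared as designed", {
  withr::local_seed(4)
  subj <- tibble::tibble(group = rep(c("a", "b", "c"), each = 15),
                         age = rnorm(45, 30), sex = sample(c("f", "m"), 45, TRUE))
  tab <- demographic_table(subj, continuous = "age", categorical = "sex")
  expect_equal(tab$test, c("anova", "chi_squared"))
  oracle <- summary(aov(age ~ group, data = subj))[[1]]
  expect_equal(tab$statistic[1], oracle$`F value`[1])
  lsd <- tab$posthoc[[1]]
  expect_equal(nrow(lsd), 3)  # all pairs
  # LSD uses the pooled error term: compare one pair against the formula
  fit <- aov(age ~ group, data = subj)
  mse <- sum(residuals(fit)^2) / fit$df.residual
  d <- mean(subj$age[subj$group == "a"]) - mean(subj$age[subj$group == "b"])
  expect_equal(lsd$statistic[lsd$group1 == "a" & lsd$group2 == "b"],
               d / sqrt(mse * (2 / 15)), tolerance = 1e-12)

  # 2x2 chi-squared without continuity correction: expected counts all 5
  perfect <- tibble::tibble(group = rep(c("g1", "g2"), each = 10),
                            sex = rep(c("f", "m"), each = 10))
  t2 <- demographic_table(perfect, continuous = character(0), categorical = "sex")
  expect_equal(t2$statistic, 20)

  expect_error(demographic_table(tibble::tibble(group = "a", age = 1)),
               "at least 2 groups")
})

test_that("partial correlation reduces to Pearson and matches the closed form", {
  withr::local_seed(5)
  d <- tibble::tibble(x = rnorm(50), y = rnorm(50), z = rnorm(50))
  plain <- partial_pearson(d, "x", "y")
  ct <- cor.test(d$x, d$y)
  expect_equal(plain$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(plain$p_value, ct$p.value, tolerance = 1e-12)

  # first-order partial correlation closed form r_xy.z
  d2 <- tibble::tibble(z = rnorm(80)) |>
    dplyr::mutate(x = 0.7 * z + rnorm(80), y = -0.5 * z + rnorm(80))
  got <- partial_pearson(d2, "x", "y", covariates = "z")
  rxy <- cor(d2$x, d2$y); rxz <- cor(d2$x, d2$z); ryz <- cor(d2$y, d2$z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got$r, closed, tolerance = 1e-10)
  expect_equal(got$df, 80 - 1 - 2)

  # a variable that is a copy of a covariate has ~zero residual correlation
  d3 <- dplyr::mutate(d2, y2 = z)
  expect_lt(abs(partial_pearson(d3, "x", "y2", covariates = "z")$r), 1e-8)
})

test_that("rank-sum screen: exact enumeration, ties, and the log10 cut", {
  d <- tibble::tibble(v = c(1, 2, 3, 4), sex = c("female", "female", "male", "male"))
  res <- heterogeneity_screen(d, "v", split = "sex")
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)  # 2/6 orderings as extreme
  expect_true(res$exact)
  expect_equal(res$log10_p, log10(1 / 3))

  tied <- tibble::tibble(v = rep(c(1, 1, 2, 2), 6),
                         sex = rep(c("female", "male"), 12))
  res2 <- heterogeneity_screen(tied, "v", split = "sex")
  expect_false(res2$exact)
  expect_gt(res2$p_value, 0.8)

  # significance threshold on the log scale
  expect_equal(log10(0.05), -1.301, tolerance = 5e-4)
  # age split: 37 is younger, 38 older
  da <- tibble::tibble(v = c(1, 2, 10, 11, 3, 12), age = c(20, 37, 38, 65, 30, 50))
  res3 <- heterogeneity_screen(da, "v", split = "age")
  expect_equal(res3$n1, 3)  # ages 20, 37, 30
  expect_equal(res3$n2, 3)

  expect_error(heterogeneity_screen(tibble::tibble(v = 1:3, age = c(20, 21, 22)),
                                    "v", split = "age"),
               "strata")
})
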