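gauss_features <- function(n_per_class, d = 5, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = sep / sqrt(d)), ncol = d))
    tibble::tibble(subject_id = sprintf("s%03d", seq_len(2 * n_per_class))) |>
      dplyr::bind_cols(tibble::as_tibble(x, .name_repair = ~ paste0("f", 1:d)))
  })
}

test_that("feature construction: per-edge count, FCI reduction, stable order", {
  withr::local_seed(1)
  p <- tiny_partition()
  conns <- lapply(1:6, function(i) random_connectome(4)) |>
    stats::setNames(paste0("s", 1:6))
  ed <- as_edge_set(c(1, 1, 2), c(2, 3, 4))
  fe <- build_features(conns, ed, mode = "per_edge")
  expect_equal(ncol(fe) - 1, nrow(ed))
  expect_equal(names(fe)[-1], c("e1_2", "e1_3", "e2_4"))
  expect_equal(fe$e1_2, vapply(conns, function(m) m[1, 2], numeric(1)),
               ignore_attr = TRUE)

  # all edges in one within-block -> single feature equal to fci()
  ed_a <- as_edge_set(1, 2)
  ff <- build_features(conns, ed_a, mode = "fci", partition = p)
  expect_equal(ncol(ff) - 1, 1)
  expect_equal(ff[[2]], vapply(conns, fci, numeric(1), edges = ed_a),
               ignore_attr = TRUE)
  expect_error(build_features(conns, as_edge_set(1, 9)), "beyond")
  expect_error(build_features(conns, ed, mode = "fci"), "partition")
})

test_that("separable classes reach high AUC; a label feature is near-perfect", {
  fx <- gauss_features(30, sep = 4, seed = 2)
  y <- factor(rep(c("ctrl", "case"), each = 30), levels = c("ctrl", "case"))
  rep <- evaluate_classifier(fx, y, n_splits = 4, cv_folds = 4,
                             n_permutations = 0, seed = 3)
  g <- glance(rep)
  expect_gt(g$auc, 0.9)
  expect_gt(g$accuracy, 0.85)
})

test_that("shuffled labels sit at chance and permutation p is honest", {
  fx <- gauss_features(25, sep = 0, seed = 4)
  aucs <- vapply(1:8, function(r) {
    y <- withr::with_seed(100 + r,
                          factor(sample(rep(c("a", "b"), each = 25))))
    glance(evaluate_classifier(fx, y, n_splits = 3, cv_folds = 3,
                               cost_grid = 1, n_permutations = 0,
                               seed = r))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  # permutation p with signal present is small; floor respected
  fx2 <- gauss_features(20, sep = 4, seed = 5)
  y2 <- factor(rep(c("a", "b"), each = 20))
  rep2 <- evaluate_classifier(fx2, y2, n_splits = 3, cv_folds = 3,
                              cost_grid = 1, n_permutations = 60, seed = 6)
  expect_gte(rep2$permutation_p, 1 / 61)
  expect_lte(rep2$permutation_p, 0.1)
})

test_that("reports are deterministic and internally consistent", {
  fx <- gauss_features(15, sep = 2, seed = 7)
  y <- factor(rep(c("a", "b"), each = 15))
  r1 <- evaluate_classifier(fx, y, n_splits = 3, cv_folds = 3, cost_grid = c(0.1, 1),
                            n_permutations = 30, seed = 11)
  r2 <- evaluate_classifier(fx, y, n_splits = 3, cv_folds = 3, cost_grid = c(0.1, 1),
                            n_permutations = 30, seed = 11)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$permutation_p, r2$permutation_p)

  # confusion-matrix identities on every split
  s <- r1$splits
  expect_equal(s$accuracy, (s$tp + s$tn) / s$n_test)
  expect_equal(s$sensitivity, s$tp / (s$tp + s$fn))
  expect_equal(s$specificity, s$tn / (s$tn + s$fp))
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  expect_true(all(s$auc >= 0 & s$auc <= 1))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(8)
  score <- rnorm(40); lab <- score + rnorm(40) > 0
  got <- suigrad:::rank_auc(score, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("single-class and undersized inputs are rejected", {
  fx <- gauss_features(10, seed = 9)
  expect_error(evaluate_classifier(fx, rep("a", 20)), "2 classes")
  expect_error(evaluate_classifier(fx, c(rep("a", 17), rep("b", 3))),
               "at least 4")
})

test_that("the contrast families enumerate 15 reports, fewer with missing groups", {
  withr::local_seed(10)
  groups <- rep(suicidality_groups(), each = 10)
  fx <- tibble::tibble(subject_id = sprintf("s%03d", seq_along(groups)),
                       f1 = rnorm(length(groups)), f2 = rnorm(length(groups)))
  subj <- tibble::tibble(subject_id = fx$subject_id, group = groups)
  res <- run_all_contrasts(fx, subj, n_splits = 2, cv_folds = 2, cost_grid = 1,
                           n_permutations = 0, seed = 1)
  expect_length(res$reports, 15)
  expect_equal(nrow(res$skipped), 0)
  expect_true("MDDSB vs HC" %in% names(res$reports))
  expect_true("MDDSB vs MDDNSI" %in% names(res$reports))
  expect_true("MDDmoSI vs MDDmSI" %in% names(res$reports))

  no_sb <- subj$group != "MDDSB"
  res2 <- run_all_contrasts(fx[no_sb, ], subj[no_sb, ], n_splits = 2, cv_folds = 2,
                            cost_grid = 1, n_permutations = 0, seed = 1)
  expect_length(res2$reports, 10)
  expect_equal(nrow(res2$skipped), 5)
  expect_true(all(grepl("MDDSB", res2$skipped$contrast)))
})
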