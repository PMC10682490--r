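random_cohort_conns <- function(n_subj, n_nodes, shift_edges = NULL, shift = 0,
                                first = 0) {
  # iid N(0,1) edge weights; optional mean shift on chosen edges of the
  # first `first` subjects
  lapply(seq_len(n_subj), function(s) {
    m <- matrix(0, n_nodes, n_nodes)
    v <- rnorm(n_nodes * (n_nodes - 1) / 2)
    m[upper.tri(m)] <- v
    m <- m + t(m); diag(m) <- 1
    if (!is.null(shift_edges) && s <= first) {
      ix <- cbind(shift_edges$node_i, shift_edges$node_j)
      m[ix] <- m[ix] + shift
      m[ix[, 2:1]] <- m[ix[, 2:1]] + shift
    }
    as_connectome(m / max(1.01, max(abs(m[upper.tri(m)]))))
  }) |> stats::setNames(sprintf("s%03d", seq_len(n_subj)))
}

test_that("covariate-free edge statistics equal the pooled two-sample t", {
  withr::local_seed(1)
  conns <- random_cohort_conns(14, 5)
  g <- factor(rep(c("A", "B"), each = 7), levels = c("A", "B"))
  es <- edge_stats(conns, g)
  vals <- sapply(conns, function(m) unclass(m)[upper.tri(m)])
  for (e in seq_len(nrow(es))) {
    tt <- t.test(vals[e, g == "A"], vals[e, g == "B"], var.equal = TRUE)
    expect_equal(es$statistic[e], unname(tt$statistic), tolerance = 1e-10)
  }
  # sign convention: first level's mean higher -> positive
  shifted <- random_cohort_conns(14, 5, shift_edges = as_edge_set(1, 2),
                                shift = 3, first = 7)
  es2 <- edge_stats(shifted, g)
  expect_gt(es2$statistic[es2$node_i == 1 & es2$node_j == 2], 0)
})

test_that("degenerate edges yield statistic zero, not NaN", {
  conns <- random_cohort_conns(10, 4)
  conns <- lapply(conns, function(m) {
    m[1, 2] <- m[2, 1] <- 0.5  # identical across subjects
    as_connectome(unclass(m))
  })
  es <- edge_stats(conns, rep(c("A", "B"), each = 5))
  expect_equal(es$statistic[es$node_i == 1 & es$node_j == 2], 0)
})

test_that("component extraction matches a breadth-first-search oracle", {
  # toy graph: edges (1,2), (2,3), (5,6) -> two components
  stats_tbl <- tibble::tibble(node_i = c(1, 2, 5, 1), node_j = c(2, 3, 6, 4),
                              statistic = c(4, 4, 4, 1))
  comps <- extract_components(stats_tbl, threshold = 3)
  expect_length(comps, 2)
  expect_equal(nrow(comps[[1]]), 2)
  expect_equal(nrow(comps[[2]]), 1)
  expect_length(extract_components(stats_tbl, threshold = 10), 0)

  # triangle is one component of 3 edges
  tri <- tibble::tibble(node_i = c(1, 1, 2), node_j = c(2, 3, 3), statistic = 5)
  expect_equal(nrow(extract_components(tri, 3)[[1]]), 3)

  bfs_components <- function(edges) {  # independent oracle
    nodes <- unique(c(edges$node_i, edges$node_j))
    seen <- character(0); sizes <- integer(0)
    adj <- split(c(edges$node_j, edges$node_i), c(edges$node_i, edges$node_j))
    for (start in nodes) {
      if (as.character(start) %in% seen) next
      queue <- start; comp <- character(0)
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (as.character(v) %in% comp) next
        comp <- c(comp, as.character(v))
        queue <- c(queue, adj[[as.character(v)]])
      }
      seen <- c(seen, comp)
      sizes <- c(sizes, sum(as.character(edges$node_i) %in% comp))
    }
    sort(sizes[sizes > 0], decreasing = TRUE)
  }
  withr::local_seed(2)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    ep <- upper_tri_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    st <- tibble::tibble(node_i = ep[, 1], node_j = ep[, 2],
                         statistic = rnorm(nrow(ep), sd = 2))
    comps <- extract_components(st, threshold = 2.5)
    kept <- st[st$statistic >= 2.5, ]
    if (nrow(kept) == 0) { expect_length(comps, 0); next }
    expect_equal(unname(sort(vapply(comps, nrow, integer(1)), decreasing = TRUE)),
                 as.integer(bfs_components(kept)))
  }
})

test_that("NBS p-values respect the permutation floor and the seed", {
  withr::local_seed(3)
  conns <- random_cohort_conns(20, 8, shift_edges = networks_edge_set(
    as_partition(data.frame(node_id = 1:8, network = rep(c("A", "B"), each = 4))), "A"),
    shift = 2, first = 10)
  g <- rep(c("A", "B"), each = 10)
  cov <- data.frame(age = rnorm(20))
  r1 <- nbs_test(conns, g, covariates = cov, n_permutations = 100, seed = 7)
  r2 <- nbs_test(conns, g, covariates = cov, n_permutations = 100, seed = 7)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_max, r2$null_max)
  if (nrow(r1$components)) {
    expect_true(all(r1$components$p_raw >= 1 / 101))
    # monotone: larger components never have larger raw p within a direction
    for (d in unique(r1$components$direction)) {
      cc <- r1$components[r1$components$direction == d, ]
      cc <- cc[order(-cc$n_edges), ]
      expect_true(all(diff(cc$p_raw) >= -1e-15))
    }
  }
})

test_that("observed NBS components are invariant to subject order", {
  withr::local_seed(4)
  conns <- random_cohort_conns(16, 6, shift_edges = as_edge_set(c(1, 1, 2), c(2, 3, 3)),
                               shift = 2, first = 8)
  g <- rep(c("A", "B"), each = 8)
  cov <- data.frame(age = rnorm(16))
  perm <- sample(16)
  r1 <- nbs_test(conns, g, covariates = cov, n_permutations = 100, seed = 1)
  r2 <- nbs_test(conns[perm], g[perm], covariates = cov[perm, , drop = FALSE],
                 n_permutations = 100, seed = 1)
  norm_comps <- function(r) {
    lapply(r$components$edges, function(e)
      dplyr::arrange(dplyr::select(e, "node_i", "node_j"), node_i, node_j))
  }
  expect_equal(r1$threshold, r2$threshold)
  expect_equal(norm_comps(r1), norm_comps(r2))
})

test_that("stratified and Freedman-Lane permutation schemes run and agree on the observed stats", {
  withr::local_seed(5)
  conns <- random_cohort_conns(24, 6)
  g <- rep(c("A", "B"), each = 12)
  site <- rep(c("s1", "s2"), 12)
  cov <- data.frame(site = site)
  r_lab <- nbs_test(conns, g, covariates = cov, n_permutations = 100,
                    strata = site, seed = 2)
  r_fl <- nbs_test(conns, g, covariates = cov, n_permutations = 100,
                   permute = "freedman_lane", seed = 2)
  expect_equal(r_lab$threshold, r_fl$threshold)
  expect_equal(nrow(r_lab$components), nrow(r_fl$components))
})

test_that("conjunction is order-independent set intersection", {
  a <- as_edge_set(c(1, 3), c(2, 4))
  b <- as_edge_set(c(3, 5), c(4, 6))
  expect_equal(nrow(conjunction(a, b)), 1)
  expect_equal(conjunction(a, b)$node_i, 3L)
  expect_equal(conjunction(b, a), conjunction(a, b))
  expect_equal(conjunction(a, a), as_edge_set(a$node_i, a$node_j))
  disj <- conjunction(a, as_edge_set(7, 8))
  expect_equal(nrow(disj), 0)
  expect_error(conjunction(a), "at least 2")
})
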