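# Stack a cohort of connectomes into a subjects x edges matrix over the
# upper triangle; all NBS computation runs on this layout.
stack_connectomes <- function(connectomes) {
  stopifnot(is.list(connectomes), length(connectomes) >= 1L)
  n_nodes <- nrow(connectomes[[1]])
  edges <- upper_tri_pairs(n_nodes)
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  values <- t(vapply(connectomes, function(m) {
    if (nrow(m) != n_nodes) stop_sg("connectomes differ in size")
    unclass(m)[ut]
  }, numeric(nrow(edges))))
  rownames(values) <- names(connectomes)
  list(values = values, edges = edges, n_nodes = n_nodes)
}

# Vectorized edge-wise OLS t-statistics for a binary group indicator with
# covariates: one shared design matrix, all edges solved at once. Sign
# convention: positive when the first factor level's adjusted mean exceeds
# the second's. Zero-variance (degenerate) edges get statistic 0.
edge_t_stats <- function(Y, groups, covariate_mm = NULL) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2L) stop_sg("edge statistics need exactly 2 groups")
  ind <- as.numeric(g == levels(g)[1])
  X <- cbind(covariate_mm %||% matrix(1, length(ind), 1,
                                      dimnames = list(NULL, "(Intercept)")),
             group = ind)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_sg("rank-deficient edge-model design; collinear column(s): ",
            paste(bad, collapse = ", "))
  }
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cgg <- XtX_inv[ncol(X), ncol(X)]
  tt <- B[ncol(X), ] / sqrt(sigma2 * cgg)
  tt[sigma2 <= .Machine$double.eps * 100] <- 0
  list(t = unname(tt), df = df)
}

#' Edge-wise covariate-adjusted group statistics
#'
#' For every upper-triangle edge, the t-statistic of the group indicator
#' in a linear model of edge FC on group plus covariates, computed with a
#' single shared design across all edges. Positive statistics mean the
#' first group's adjusted mean is larger.
#'
#' @param connectomes Named list of `sg_connectome` (same node count).
#' @param groups Two-level factor/vector aligned with `connectomes`.
#' @param covariates Optional data frame of covariates (rows aligned with
#'   `connectomes`); categorical columns are expanded to indicators.
#' @return Tibble `node_i`, `node_j`, `statistic` with attribute `df`
#'   (residual degrees of freedom).
#' @export
edge_stats <- function(connectomes, groups, covariates = NULL) {
  stk <- stack_connectomes(connectomes)
  mm <- covariate_model_matrix(covariates, length(groups))
  res <- edge_t_stats(stk$values, groups, mm)
  out <- tibble::tibble(node_i = stk$edges[, 1], node_j = stk$edges[, 2],
                        statistic = res$t)
  attr(out, "df") <- res$df
  attr(out, "n_nodes") <- stk$n_nodes
  out
}

covariate_model_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  stopifnot(is.data.frame(covariates), nrow(covariates) == n)
  if (anyNA(covariates)) stop_sg("covariates must be complete")
  stats::model.matrix(~ ., data = as.data.frame(covariates))
}

#' Suprathreshold connected components
#'
#' Thresholds an edge-statistic map and returns the connected components
#' of the surviving graph as edge sets -- the NBS "extent" construction.
#' Direction `"positive"` keeps edges with statistic `>= threshold`,
#' `"negative"` those `<= -threshold`.
#'
#' @param stats Either a symmetric statistic matrix or a tibble from
#'   [edge_stats()].
#' @param threshold Positive edge-forming cutoff on the statistic.
#' @param direction `"positive"` or `"negative"`.
#' @return List of edge tibbles (`node_i`, `node_j`, `statistic`), one per
#'   component, ordered by decreasing edge count; empty list when no edge
#'   survives.
#' @export
extract_components <- function(stats, threshold, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (threshold <= 0) stop_sg("threshold must be positive")
  if (is.matrix(stats)) {
    n <- nrow(stats)
    ep <- upper_tri_pairs(n)
    stats <- tibble::tibble(node_i = ep[, 1], node_j = ep[, 2],
                            statistic = stats[upper.tri(stats)])
  }
  keep <- if (direction == "positive") stats$statistic >= threshold else stats$statistic <= -threshold
  sel <- stats[keep, , drop = FALSE]
  if (nrow(sel) == 0L) return(list())
  comp_id <- edge_components(cbind(sel$node_i, sel$node_j))
  out <- lapply(split(seq_len(nrow(sel)), comp_id), function(ix) {
    tibble::as_tibble(sel[ix, , drop = FALSE])
  })
  out[order(-vapply(out, nrow, integer(1)))]
}

# component id per edge, via igraph connected components on the
# suprathreshold graph
edge_components <- function(edge_mat) {
  verts <- sort(unique(as.vector(edge_mat)))
  g <- igraph::graph_from_edgelist(matrix(match(edge_mat, verts), ncol = 2),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[match(edge_mat[, 1], verts)]
}

# Largest component size in edges via union-find; called once per
# permutation and direction, where igraph's per-call overhead would
# dominate, so this stays plain R with path halving.
max_component_edges <- function(t_vec, edge_mat, threshold, direction) {
  keep <- if (direction == "positive") t_vec >= threshold else t_vec <= -threshold
  if (!any(keep)) return(0L)
  em <- edge_mat[keep, , drop = FALSE]
  parent <- seq_len(max(em))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (q in seq_len(nrow(em))) {
    ra <- find(em[q, 1]); rb <- find(em[q, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(em[, 1], find, integer(1))
  max(tabulate(factor(roots)))
}

#' Network-based statistic permutation test
#'
#' Edge-wise covariate-adjusted group statistics, suprathreshold component
#' extraction, and family-wise component inference by max-component-size
#' permutation: group labels are permuted (optionally within site strata,
#' or via Freedman-Lane residual permutation under the covariate model),
#' the edge statistics recomputed, and the largest surviving component
#' size recorded to build the null. Component p-values are
#' `(1 + #[null >= observed]) / (1 + n_permutations)`, never below
#' `1 / (n_permutations + 1)`. Positive and negative directions are tested
#' separately; with `direction = "both"` each component p-value is
#' Bonferroni-doubled for the two directions.
#'
#' The edge-forming threshold defaults to the two-sided p = 0.001 t
#' quantile at the model's residual degrees of freedom; it is always
#' recorded in the result.
#'
#' @inheritParams edge_stats
#' @param threshold Edge-forming statistic cutoff; default
#'   `qt(1 - threshold_p / 2, df)`.
#' @param threshold_p Two-sided edge-forming p when `threshold` is `NULL`.
#' @param n_permutations Number of label permutations (>= 100).
#' @param direction `"both"`, `"positive"` or `"negative"`.
#' @param permute `"labels"` (permute group labels) or `"freedman_lane"`
#'   (permute covariate-model residuals).
#' @param strata Optional factor; label permutations are restricted to
#'   within its levels (e.g. site).
#' @param seed Integer seed; the result is reproducible from it.
#' @return Object of class `sg_nbs`: list with `components` tibble
#'   (`component`, `direction`, `n_edges`, `n_nodes`, `p_raw`, `p_value`,
#'   `edges` list-column), `null_max` tibble of per-permutation max
#'   component sizes per direction, `threshold`, `df`, `n_permutations`,
#'   `permute`, `seed`.
#' @export
nbs_test <- function(connectomes, groups, covariates = NULL, threshold = NULL,
                     threshold_p = 0.001, n_permutations = 1000,
                     direction = c("both", "positive", "negative"),
                     permute = c("labels", "freedman_lane"), strata = NULL,
                     seed = 1L) {
  direction <- match.arg(direction)
  permute <- match.arg(permute)
  if (n_permutations < 100) stop_sg("n_permutations must be at least 100")
  stk <- stack_connectomes(connectomes)
  n <- nrow(stk$values)
  stopifnot(length(groups) == n)
  g <- droplevels(factor(groups))
  if (any(table(g) < 3L)) stop_sg("both groups need n >= 3")
  mm <- covariate_model_matrix(covariates, n)

  obs <- edge_t_stats(stk$values, g, mm)
  thr <- threshold %||% stats::qt(1 - threshold_p / 2, obs$df)
  dirs <- if (direction == "both") c("positive", "negative") else direction
  n_dir <- length(dirs)

  stats_tbl <- tibble::tibble(node_i = stk$edges[, 1], node_j = stk$edges[, 2],
                              statistic = obs$t)
  obs_comps <- purrr::map(dirs, ~ extract_components(stats_tbl, thr, .x))
  names(obs_comps) <- dirs

  if (permute == "freedman_lane") {
    qz <- qr(mm)
    fitted_z <- qr.fitted(qz, stk$values)
    resid_z <- qr.resid(qz, stk$values)
  }
  perm_index <- make_strata_permuter(n, strata)
  null_max <- matrix(0L, n_permutations, n_dir, dimnames = list(NULL, dirs))
  withr::with_seed(substream_seed(seed, stream = 77L), {
    for (b in seq_len(n_permutations)) {
      idx <- perm_index()
      tb <- if (permute == "labels") {
        edge_t_stats(stk$values, g[idx], mm)$t
      } else {
        edge_t_stats(fitted_z + resid_z[idx, , drop = FALSE], g, mm)$t
      }
      for (d in seq_len(n_dir)) {
        null_max[b, d] <- max_component_edges(tb, stk$edges, thr, dirs[d])
      }
    }
  })

  comp_rows <- purrr::map_dfr(dirs, function(d) {
    comps <- obs_comps[[d]]
    if (!length(comps)) return(tibble::tibble())
    purrr::imap_dfr(comps, function(ed, i) {
      sz <- nrow(ed)
      p_raw <- (1 + sum(null_max[, d] >= sz)) / (1 + n_permutations)
      tibble::tibble(direction = d, n_edges = sz,
                     n_nodes = length(unique(c(ed$node_i, ed$node_j))),
                     p_raw = p_raw,
                     p_value = min(1, p_raw * n_dir),
                     edges = list(ed))
    })
  })
  if (nrow(comp_rows)) {
    comp_rows <- dplyr::arrange(comp_rows, .data$p_value, -.data$n_edges)
    comp_rows <- dplyr::mutate(comp_rows, component = dplyr::row_number(), .before = 1L)
  }
  structure(list(components = comp_rows,
                 null_max = tibble::as_tibble(cbind(perm = seq_len(n_permutations),
                                                    as.data.frame(null_max))),
                 threshold = thr, df = obs$df, n_permutations = n_permutations,
                 direction = direction, permute = permute, seed = seed,
                 groups = levels(g)),
            class = "sg_nbs")
}

make_strata_permuter <- function(n, strata) {
  if (is.null(strata)) {
    function() sample.int(n)
  } else {
    stopifnot(length(strata) == n)
    sidx <- split(seq_len(n), strata)
    function() {
      idx <- seq_len(n)
      for (s in sidx) idx[s] <- s[sample.int(length(s))]
      idx
    }
  }
}

#' Significant NBS edges
#'
#' Union of the edges of all components at or below a component-level
#' alpha, as an [as_edge_set()].
#'
#' @param x An `sg_nbs` result.
#' @param alpha Component-level significance cutoff (default 0.05).
#' @return An `sg_edge_set` (possibly empty tibble).
#' @export
significant_edges <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "sg_nbs"))
  comps <- x$components
  if (!nrow(comps)) return(as_edge_set(integer(0), integer(0)))
  keep <- comps$p_value <= alpha
  if (!any(keep)) return(as_edge_set(integer(0), integer(0)))
  ed <- dplyr::bind_rows(comps$edges[keep])
  as_edge_set(ed$node_i, ed$node_j)
}

#' Conjunction of differential edge sets
#'
#' Edges present in every input set (set intersection over unordered node
#' pairs), used to find connections shared across contrasts.
#'
#' @param ... Two or more edge sets (or one list of them).
#' @return An `sg_edge_set` of the common edges (possibly empty).
#' @export
conjunction <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !is.data.frame(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2L) stop_sg("conjunction needs at least 2 edge sets")
  keys <- lapply(sets, function(s) {
    if (nrow(s) == 0L) return(character(0))
    paste(pmin(s$node_i, s$node_j), pmax(s$node_i, s$node_j))
  })
  common <- Reduce(intersect, keys)
  if (!length(common)) return(as_edge_set(integer(0), integer(0)))
  ij <- do.call(rbind, strsplit(common, " "))
  as_edge_set(as.integer(ij[, 1]), as.integer(ij[, 2]))
}

#' @export
print.sg_nbs <- function(x, ...) {
  cat("<sg_nbs> ", x$groups[1], " vs ", x$groups[2],
      "; threshold |t| >= ", signif(x$threshold, 4),
      " (df = ", x$df, "), ", x$n_permutations, " permutations (",
      x$permute, ")\n", sep = "")
  if (nrow(x$components)) {
    print(dplyr::select(x$components, -"edges"))
  } else {
    cat("  no suprathreshold components\n")
  }
  invisible(x)
}
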