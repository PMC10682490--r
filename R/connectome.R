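#' Functional connectivity matrices
#'
#' A connectome is an N x N symmetric matrix of functional connectivity
#' (FC) values between node pairs, either raw Pearson correlations
#' (`scale = "pearson_r"`) or Fisher z-transformed (`scale = "fisher_z"`).
#' The diagonal carries no information and is stored as `NA` so that no
#' self-connection can silently leak into a mean.
#'
#' @param values Square numeric matrix.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param tol Maximum tolerated absolute asymmetry before erroring;
#'   sub-tolerance asymmetry is removed by averaging with the transpose.
#' @return Matrix of class `sg_connectome` with a `scale` attribute and an
#'   `NA` diagonal.
#' @export
as_connectome <- function(values, scale = c("pearson_r", "fisher_z"), tol = 1e-6) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) != ncol(values)) stop_sg("connectome must be square")
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (asym > tol) stop_sg("matrix asymmetry ", signif(asym, 3), " exceeds tolerance ", tol)
  m <- (values + t(values)) / 2
  diag(m) <- NA_real_
  off <- m[upper.tri(m)]
  if (anyNA(off)) stop_sg("missing off-diagonal values in connectome")
  if (scale == "pearson_r" && any(abs(off) > 1 + 1e-12)) {
    stop_sg("pearson_r connectome has off-diagonal entries outside [-1, 1]")
  }
  structure(m, scale = scale, class = "sg_connectome")
}

#' @rdname as_connectome
#' @param conn Object to test / query.
#' @export
fc_scale <- function(conn) attr(conn, "scale")

#' @export
print.sg_connectome <- function(x, ...) {
  cat("<sg_connectome> ", nrow(x), " x ", ncol(x), " (", attr(x, "scale"), ")\n", sep = "")
  off <- x[upper.tri(x)]
  cat("  off-diagonal FC: mean ", signif(mean(off), 3),
      ", range [", signif(min(off), 3), ", ", signif(max(off), 3), "]\n", sep = "")
  invisible(x)
}

#' Pearson functional connectivity from ROI time series
#'
#' Computes the Pearson correlation between every pair of node time series.
#' A constant column has no defined correlation and fails loudly, naming
#' the offending node, rather than propagating `NaN`.
#'
#' @param ts T x N numeric matrix, T >= 3 timepoints.
#' @return An [as_connectome()] matrix on the `pearson_r` scale.
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' compute_fc(ts)
#' @export
compute_fc <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (nrow(ts) < 3L) stop_sg("need at least 3 timepoints, got ", nrow(ts))
  if (anyNA(ts)) stop_sg("time series contains missing values")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_sg("constant time series at node(s): ",
            paste(which(sds == 0), collapse = ", "))
  }
  as_connectome(stats::cor(ts), scale = "pearson_r")
}

#' Fisher z-transform of a correlation connectome
#'
#' Applies `atanh` entrywise to a `pearson_r` connectome. Entries with
#' |r| = 1 would map to infinity and are an error.
#'
#' @param conn An `sg_connectome` on the `pearson_r` scale.
#' @return An `sg_connectome` on the `fisher_z` scale.
#' @export
fisher_z <- function(conn) {
  if (!identical(fc_scale(conn), "pearson_r")) {
    stop_sg("fisher_z() expects a pearson_r connectome")
  }
  m <- unclass(conn)
  off <- m[upper.tri(m)]
  if (any(abs(off) >= 1)) stop_sg("|r| = 1 entries cannot be Fisher-transformed")
  z <- atanh(m)
  diag(z) <- 0
  as_connectome(z, scale = "fisher_z")
}

#' Network-level connectivity summaries
#'
#' For a K-network partition, computes the three standard block summaries
#' of a connectome: within-network connectivity (WNC, the mean FC over the
#' node pairs inside each network; K values), pairwise between-network
#' connectivity (BNC, the mean FC over node pairs spanning each unordered
#' network pair; K(K-1)/2 values), and one-versus-others connectivity
#' (OVO, the mean FC over all node pairs linking a network to the other
#' K-1 networks; K values). OVO pools node pairs, so it equals the
#' pair-count-weighted mean of the K-1 corresponding BNC values.
#' Negative correlations enter the means as-is; the diagonal never does.
#'
#' @param conn An [as_connectome()] matrix.
#' @param partition An [as_partition()] whose size matches `conn`.
#' @return A tibble of class `sg_network_summary` with columns
#'   `metric_type` (`"wnc"`, `"bnc"`, `"ovo"`), `name` (e.g. `"WNC_DMN"`,
#'   `"BNC_AUD-CON"`), `net_a`, `net_b` (`net_b` is `NA` for WNC and
#'   `"OTHERS"` for OVO), `value` and `n_pairs`.
#' @examples
#' p <- as_partition(data.frame(node_id = 1:4, network = c("A", "A", "B", "B")))
#' m <- diag(4); m[upper.tri(m)] <- c(.5, .2, .2, .4, 0, .1); m <- m + t(m) - diag(4)
#' summarize_networks(as_connectome(m), p)
#' @export
summarize_networks <- function(conn, partition) {
  stopifnot(inherits(conn, "sg_connectome"), inherits(partition, "sg_partition"))
  n <- nrow(conn)
  if (n != nrow(partition)) {
    stop_sg("connectome has ", n, " nodes but partition has ", nrow(partition))
  }
  idx <- network_index(partition)
  nets <- names(idx)
  singleton <- nets[lengths(idx) < 2L]
  if (length(singleton)) {
    stop_sg("within-network connectivity undefined for singleton network(s): ",
            paste(singleton, collapse = ", "))
  }
  m <- unclass(conn)
  diag(m) <- 0
  # all block sums at once: S = G' m G with G the node-by-network indicator
  sizes <- lengths(idx)
  g_ind <- matrix(0, n, length(nets))
  for (k in seq_along(nets)) g_ind[idx[[k]], k] <- 1
  S <- crossprod(g_ind, m %*% g_ind)

  wnc_pairs <- sizes * (sizes - 1) / 2
  wnc <- tibble::tibble(metric_type = "wnc", name = paste0("WNC_", nets),
                        net_a = nets, net_b = NA_character_,
                        value = unname(diag(S) / 2 / wnc_pairs),
                        n_pairs = as.integer(unname(wnc_pairs)))

  ovo_pairs <- sizes * (n - sizes)
  ovo <- tibble::tibble(metric_type = "ovo", name = paste0("OVO_", nets),
                        net_a = nets, net_b = "OTHERS",
                        value = unname((rowSums(S) - diag(S)) / ovo_pairs),
                        n_pairs = as.integer(unname(ovo_pairs)))

  pairs <- utils::combn(nets, 2L)
  a <- pairs[1, ]; b <- pairs[2, ]
  bnc_pairs <- sizes[a] * sizes[b]
  bnc <- tibble::tibble(metric_type = "bnc", name = paste0("BNC_", a, "-", b),
                        net_a = a, net_b = b,
                        value = unname(S[cbind(match(a, nets), match(b, nets))] / bnc_pairs),
                        n_pairs = as.integer(unname(bnc_pairs)))

  out <- dplyr::bind_rows(wnc, ovo, bnc)
  attr(out, "scale") <- fc_scale(conn)
  class(out) <- c("sg_network_summary", class(out))
  out
}

#' Summarize a cohort of connectomes
#'
#' Applies [summarize_networks()] to each subject's connectome and stacks
#' the results into one long tibble keyed by `subject_id`.
#'
#' @param connectomes Named list of `sg_connectome` (names = subject ids).
#' @param partition An `sg_partition`.
#' @return Long tibble with columns `subject_id`, `metric_type`, `name`,
#'   `net_a`, `net_b`, `value`, `n_pairs`.
#' @export
summarize_cohort <- function(connectomes, partition) {
  stopifnot(is.list(connectomes), !is.null(names(connectomes)))
  purrr::imap_dfr(connectomes, function(conn, id) {
    dplyr::mutate(summarize_networks(conn, partition),
                  subject_id = id, .before = 1L)
  })
}

#' Group-mean network summaries
#'
#' Joins per-subject summaries to group labels and averages each metric
#' within group, the aggregation used for network-role assignment and the
#' gradient trajectory displays.
#'
#' @param summaries Long tibble from [summarize_cohort()].
#' @param subjects Data frame with `subject_id` and `group`.
#' @return Tibble with columns `group`, `metric_type`, `name`, `net_a`,
#'   `net_b`, `value` (group mean) and `n_subjects`.
#' @export
summarize_groups <- function(summaries, subjects) {
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  summaries |>
    dplyr::inner_join(dplyr::select(subjects, "subject_id", "group"),
                      by = "subject_id") |>
    dplyr::group_by(.data$group, .data$metric_type, .data$name,
                    .data$net_a, .data$net_b) |>
    dplyr::summarise(n_subjects = dplyr::n(), value = mean(.data$value),
                     .groups = "drop")
}

#' Functional connectivity index (FCI)
#'
#' The FCI of an edge set is the arithmetic mean of the connectome values
#' over its edges: a single composite number summarising the FC strength of
#' a designated set of connections, used as a subject-level feature.
#'
#' @param conn An `sg_connectome`.
#' @param edges An [as_edge_set()] (or data frame with `node_i`, `node_j`).
#' @return Scalar mean FC over the edges.
#' @export
fci <- function(conn, edges) {
  stopifnot(inherits(conn, "sg_connectome"))
  if (is.data.frame(edges) && !inherits(edges, "sg_edge_set")) {
    edges <- as_edge_set(edges)
  }
  if (nrow(edges) == 0L) stop_sg("empty edge set")
  n <- nrow(conn)
  if (any(pmax(edges$node_i, edges$node_j) > n)) {
    stop_sg("edge references node beyond matrix size ", n)
  }
  mean(unclass(conn)[cbind(edges$node_i, edges$node_j)])
}
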