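#' Read and write ROI time series, connectomes and edge lists
#'
#' All on-disk formats are plain delimited text: time series are T x N
#' numeric matrices (rows = timepoints, columns = nodes in partition order),
#' connectomes are N x N numeric matrices, and edge lists are three-column
#' TSV (`node_i`, `node_j`, `value`) with 1-based node ids and `i < j`.
#' Node indexing is 1-based in every file; in memory, matrix positions are
#' used directly.
#'
#' @param path File path.
#' @param n_nodes Expected number of nodes (optional check).
#' @return `read_time_series()`: a numeric T x N matrix.
#' @export
read_time_series <- function(path, n_nodes = NULL) {
  m <- read_numeric_matrix(path)
  if (nrow(m) < 3L) stop_sg("time series needs at least 3 timepoints: ", path)
  if (!is.null(n_nodes) && ncol(m) != n_nodes) {
    stop_sg("time series has ", ncol(m), " columns, expected ", n_nodes, ": ", path)
  }
  m
}

#' @rdname read_time_series
#' @param x Matrix to write.
#' @export
write_time_series <- function(x, path) {
  write_numeric_matrix(x, path)
}

#' @rdname read_time_series
#' @param scale Correlation scale of the stored matrix, `"pearson_r"` or
#'   `"fisher_z"`.
#' @param tol Maximum tolerated absolute asymmetry; the matrix is
#'   symmetrized by averaging if the asymmetry is below `tol`, otherwise
#'   reading fails.
#' @return `read_connectome()`: an N x N connectome matrix (class
#'   `sg_connectome`) with `NA` on the diagonal and a `scale` attribute.
#' @export
read_connectome <- function(path, scale = "pearson_r", tol = 1e-6) {
  m <- read_numeric_matrix(path)
  if (nrow(m) != ncol(m)) {
    stop_sg("connectome must be square, got ", nrow(m), " x ", ncol(m), ": ", path)
  }
  as_connectome(m, scale = scale, tol = tol)
}

#' @rdname read_time_series
#' @param conn An `sg_connectome`.
#' @export
write_connectome <- function(conn, path) {
  m <- unclass(conn)
  diag(m) <- 0
  write_numeric_matrix(m, path)
}

#' @rdname read_time_series
#' @return `read_edge_list()`: an edge tibble with integer columns `node_i`
#'   `< node_j` and a numeric `value` column.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 3L) stop_sg("edge list must have 3 columns: ", path)
  if (is.na(suppressWarnings(as.numeric(raw[1, 1])))) raw <- raw[-1, , drop = FALSE]
  i <- as.integer(raw[[1]]); j <- as.integer(raw[[2]]); v <- as.numeric(raw[[3]])
  if (anyNA(i) || anyNA(j) || anyNA(v)) stop_sg("non-numeric entries in edge list: ", path)
  as_edge_set(i, j, value = v, n_nodes = n_nodes)
}

#' @rdname read_time_series
#' @param edges Edge tibble as returned by [as_edge_set()].
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Edge sets
#'
#' An edge set is a tibble of unique unordered node pairs, stored with
#' `node_i < node_j` (pairs given in the other order are flipped), 1-based.
#' Self-loops and duplicated pairs are errors.
#'
#' @param node_i,node_j Integer node ids.
#' @param value Optional numeric value per edge.
#' @param n_nodes Optional bound check on node ids.
#' @return Tibble of class `sg_edge_set`.
#' @export
as_edge_set <- function(node_i, node_j, value = NULL, n_nodes = NULL) {
  if (is.data.frame(node_i)) {
    df <- node_i
    value <- df[["value"]]
    node_j <- df[["node_j"]]
    node_i <- df[["node_i"]]
  }
  i <- as.integer(node_i); j <- as.integer(node_j)
  if (length(i) != length(j)) stop_sg("node_i and node_j lengths differ")
  if (anyNA(i) || anyNA(j) || any(i < 1L) || any(j < 1L)) stop_sg("invalid node id in edge set")
  if (any(i == j)) stop_sg("self-loop in edge set at node ", i[which(i == j)[1]])
  if (!is.null(n_nodes) && any(pmax(i, j) > n_nodes)) {
    stop_sg("edge references node beyond ", n_nodes)
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) stop_sg("duplicate edge(s): ", key[duplicated(key)][1])
  out <- tibble::tibble(node_i = lo, node_j = hi)
  if (!is.null(value)) out$value <- as.numeric(value)
  class(out) <- c("sg_edge_set", class(out))
  out
}

#' @rdname as_edge_set
#' @param edges Edge tibble with a `value` column.
#' @export
edge_list_to_matrix <- function(edges, n_nodes) {
  stopifnot(is.data.frame(edges), !is.null(edges$value))
  m <- matrix(0, n_nodes, n_nodes)
  if (any(pmax(edges$node_i, edges$node_j) > n_nodes)) {
    stop_sg("edge references node beyond ", n_nodes)
  }
  m[cbind(edges$node_i, edges$node_j)] <- edges$value
  m[cbind(edges$node_j, edges$node_i)] <- edges$value
  m
}

#' Read and write subject phenotype tables
#'
#' CSV with one row per subject; expected columns are `subject_id`, `site`,
#' `group`, `age`, `sex`, `education`, `mean_fd`, `hamd_total`,
#' `hamd_suicide` and the HAMD subfactors (`hamd_anxiety`, `hamd_weight`,
#' `hamd_retardation`, `hamd_sleep`). Missing clinical values are allowed;
#' each analysis stage validates the columns it actually needs.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_subjects
#' @param subjects Data frame of subjects.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(path)
}

read_numeric_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_sg("empty matrix file: ", path)
  rows <- strsplit(trimws(lines), "[ \t,]+")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop_sg("ragged rows in matrix file (", paste(unique(lens), collapse = "/"),
            " columns): ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop_sg("non-numeric or missing entries in matrix file: ", path)
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

write_numeric_matrix <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
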