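#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Deterministic substream seeds: one global seed fans out to per-stage /
# per-subject streams so subject-level draws are stable when group sizes
# change. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  as.integer((abs(seed) %% 1e5) * 20011 + stream * 1000003 + index * 7919) %% 2147483647L
}

# All unordered node pairs i < j of an n-node graph, as a 2-column matrix.
upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(node_i = idx[, "row"], node_j = idx[, "col"])
}

stop_sg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
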