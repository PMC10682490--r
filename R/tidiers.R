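#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NBS result
#'
#' One row per suprathreshold component with its size, node count and
#' permutation p-values (edge list retained as a list column).
#'
#' @param x An `sg_nbs` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.sg_nbs <- function(x, ...) {
  if (!nrow(x$components)) {
    return(tibble::tibble(component = integer(0), direction = character(0),
                          n_edges = integer(0), n_nodes = integer(0),
                          p_raw = numeric(0), p_value = numeric(0)))
  }
  dplyr::select(x$components, -"edges")
}

#' @rdname tidy.sg_nbs
#' @exportS3Method generics::glance
#' @export
glance.sg_nbs <- function(x, ...) {
  tibble::tibble(contrast = paste(x$groups, collapse = " vs "),
                 threshold = x$threshold, df = x$df,
                 n_components = nrow(x$components),
                 n_significant = sum(x$components$p_value <= 0.05),
                 min_p = if (nrow(x$components)) min(x$components$p_value) else NA_real_,
                 n_permutations = x$n_permutations, permute = x$permute,
                 seed = x$seed)
}

#' Tidy a classification report
#'
#' `tidy()` returns per-split test metrics; `glance()` one row with the
#' mean and sd of each metric plus the permutation p-value for accuracy.
#'
#' @param x An `sg_classification` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.sg_classification <- function(x, ...) {
  dplyr::mutate(x$splits, contrast = x$contrast, .before = 1L)
}

#' @rdname tidy.sg_classification
#' @exportS3Method generics::glance
#' @export
glance.sg_classification <- function(x, ...) {
  s <- x$summary
  grab <- function(m, what) s[[what]][s$metric == m]
  tibble::tibble(contrast = x$contrast,
                 accuracy = grab("accuracy", "mean"),
                 accuracy_sd = grab("accuracy", "sd"),
                 sensitivity = grab("sensitivity", "mean"),
                 specificity = grab("specificity", "mean"),
                 auc = grab("auc", "mean"), auc_sd = grab("auc", "sd"),
                 permutation_p = x$permutation_p,
                 n_splits = nrow(x$splits),
                 n_permutations = x$n_permutations, seed = x$seed)
}
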