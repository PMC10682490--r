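#' Build classification features from connectomes
#'
#' Per-edge mode yields one feature per edge of the edge set; FCI mode
#' groups the edges by the network pair (or within-network block) each
#' edge belongs to and averages FC within each block, yielding one
#' composite FCI feature per block -- the representation used when mean
#' FCIs of differential connections feed a classifier.
#'
#' @param connectomes Named list of `sg_connectome`.
#' @param edges Non-empty [as_edge_set()].
#' @param mode `"per_edge"` or `"fci"`.
#' @param partition Required for `mode = "fci"`.
#' @return Tibble with `subject_id` plus one numeric column per feature
#'   (deterministic column order).
#' @export
build_features <- function(connectomes, edges, mode = c("per_edge", "fci"),
                           partition = NULL) {
  mode <- match.arg(mode)
  if (nrow(edges) == 0L) stop_sg("empty edge set")
  n_nodes <- nrow(connectomes[[1]])
  if (any(pmax(edges$node_i, edges$node_j) > n_nodes)) {
    stop_sg("edge references node beyond matrix size ", n_nodes)
  }
  ix <- cbind(edges$node_i, edges$node_j)
  vals <- do.call(rbind, lapply(connectomes, function(m) unclass(m)[ix]))
  if (mode == "per_edge") {
    colnames(vals) <- paste0("e", edges$node_i, "_", edges$node_j)
  } else {
    if (is.null(partition)) stop_sg("mode 'fci' needs a partition")
    net <- partition$network
    a <- net[edges$node_i]; b <- net[edges$node_j]
    block <- ifelse(a <= b, paste0(a, "-", b), paste0(b, "-", a))
    blocks <- sort(unique(block))
    vals <- vapply(blocks, function(bl) rowMeans(vals[, block == bl, drop = FALSE]),
                   numeric(nrow(vals)))
    colnames(vals) <- paste0("fci_", blocks)
  }
  dplyr::bind_cols(tibble::tibble(subject_id = names(connectomes)),
                   tibble::as_tibble(vals))
}

# Stratified indices: test split and cross-validation folds.
stratified_split <- function(labels, test_prop) {
  test <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    n_test <- max(1L, round(length(ix) * test_prop))
    ix[sample.int(length(ix), n_test)]
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (ix in split(seq_along(labels), labels)) {
    fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# Mann-Whitney AUC of scores for the positive class.
rank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Linear SVM fit plus hand-rolled decision values (w'x - rho): equivalent
# to stats::predict(..., decision.values = TRUE) but without its per-call
# overhead, which matters inside the permutation loop. libsvm's decision
# sign is positive for the class appearing first in the training data;
# scores are re-oriented so larger means the positive (second) level.
svm_fit_predict <- function(x_train, y_train, x_test, cost) {
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                    scale = FALSE, probability = FALSE, fitted = FALSE)
  w <- crossprod(fit$SV, fit$coefs)
  dec_raw <- as.numeric(x_test %*% w) - fit$rho
  first <- as.character(y_train[1L])
  second <- setdiff(levels(y_train), first)
  cls <- factor(ifelse(dec_raw > 0, first, second), levels = levels(y_train))
  pos <- levels(y_train)[2]
  list(class = cls, score = if (identical(first, pos)) dec_raw else -dec_raw)
}

# one full repeated-split evaluation; returns per-split metric tibble
evaluate_splits <- function(x, y, n_splits, cv_folds, cost_grid, test_prop) {
  purrr::map_dfr(seq_len(n_splits), function(s) {
    sp <- stratified_split(y, test_prop)
    x_tr <- x[sp$train, , drop = FALSE]; y_tr <- droplevels(y[sp$train])
    x_te <- x[sp$test, , drop = FALSE]; y_te <- y[sp$test]
    # standardize with training statistics only
    mu <- colMeans(x_tr); sdv <- apply(x_tr, 2, stats::sd); sdv[sdv == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sdv, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sdv, "/")

    k <- min(cv_folds, min(table(y_tr)))
    if (k < cv_folds) {
      warning("reducing cv folds to ", k, " (smallest training class)", call. = FALSE)
    }
    cost <- cost_grid[1]
    if (length(cost_grid) > 1L && k >= 2L) {
      fold <- stratified_folds(y_tr, k)
      cv_acc <- vapply(cost_grid, function(cc) {
        hits <- 0L
        for (f in seq_len(k)) {
          tr <- fold != f
          if (nlevels(droplevels(y_tr[tr])) < 2L) next
          pr <- svm_fit_predict(x_tr[tr, , drop = FALSE], droplevels(y_tr[tr]),
                                x_tr[!tr, , drop = FALSE], cc)
          hits <- hits + sum(pr$class == y_tr[!tr])
        }
        hits / length(y_tr)
      }, numeric(1))
      cost <- cost_grid[which.max(cv_acc)]
    }
    pr <- svm_fit_predict(x_tr, y_tr, x_te, cost)
    pos <- levels(y)[2]
    tp <- sum(pr$class == pos & y_te == pos)
    tn <- sum(pr$class != pos & y_te != pos)
    fp <- sum(pr$class == pos & y_te != pos)
    fn <- sum(pr$class != pos & y_te == pos)
    tibble::tibble(split = s,
                   accuracy = (tp + tn) / length(y_te),
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   auc = rank_auc(pr$score, y_te == pos),
                   cost = cost, tp = tp, tn = tn, fp = fp, fn = fn,
                   n_test = length(y_te))
  })
}

#' Linear SVM evaluation with repeated splits and a permutation test
#'
#' The classification protocol: the data are split `n_splits` times into
#' stratified training and test sets (default 80/20); within each
#' training set, features are standardized using training statistics
#' only, the soft-margin cost C of a linear SVM is chosen by stratified
#' `cv_folds`-fold cross-validation over `cost_grid`, and accuracy,
#' sensitivity, specificity and AUC (from decision values, by the
#' rank/Mann-Whitney formula) are computed on the held-out test set.
#' The permutation test permutes the labels *before* the whole
#' split-and-tune procedure and compares mean permuted test accuracy with
#' the observed mean: p = (1 + #[permuted >= observed]) / (1 + B).
#'
#' The second factor level is the positive class (sensitivity = its true
#' positive rate).
#'
#' @param features Tibble/data frame of numeric features (a `subject_id`
#'   column is carried but not used as a feature) or numeric matrix.
#' @param labels Two-level factor (or coercible) aligned with rows.
#' @param n_splits Number of random train/test splits (default 10).
#' @param cv_folds Inner cross-validation folds (default 10; reduced with
#'   a warning if a training class is smaller).
#' @param cost_grid Candidate C values (default 0.01, 0.1, 1, 10, 100).
#' @param n_permutations Label permutations for the accuracy test
#'   (default 1000; 0 skips the test).
#' @param test_prop Held-out fraction per split (default 0.2).
#' @param seed Integer seed; the full report is reproducible from it.
#' @param contrast Optional label stored in the report.
#' @return Object of class `sg_classification`: list with `splits`
#'   (per-split metrics), `summary` (mean and sd of each metric),
#'   `permutation_p`, `n_permutations`, settings and `seed`.
#' @export
evaluate_classifier <- function(features, labels, n_splits = 10, cv_folds = 10,
                                cost_grid = c(0.01, 0.1, 1, 10, 100),
                                n_permutations = 1000, test_prop = 0.2,
                                seed = 1L, contrast = NULL) {
  x <- features
  if (is.data.frame(x)) {
    x <- as.matrix(x[setdiff(names(x), "subject_id")])
  }
  stopifnot(is.numeric(x))
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2L) stop_sg("labels must have exactly 2 classes, got ", nlevels(y))
  if (any(table(y) < 4L)) stop_sg("each class needs at least 4 subjects")
  if (nrow(x) != length(y)) stop_sg("features and labels disagree in length")

  splits <- withr::with_seed(substream_seed(seed, stream = 11L),
                             evaluate_splits(x, y, n_splits, cv_folds, cost_grid, test_prop))
  obs_acc <- mean(splits$accuracy)

  perm_acc <- numeric(0)
  if (n_permutations > 0) {
    perm_acc <- vapply(seq_len(n_permutations), function(b) {
      withr::with_seed(substream_seed(seed, stream = 13L, index = b), {
        yp <- y[sample.int(length(y))]
        mean(suppressWarnings(
          evaluate_splits(x, yp, n_splits, cv_folds, cost_grid, test_prop))$accuracy)
      })
    }, numeric(1))
  }
  perm_p <- if (n_permutations > 0) {
    (1 + sum(perm_acc >= obs_acc)) / (1 + n_permutations)
  } else NA_real_

  summary_tbl <- splits |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity", "auc"),
                        names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")

  structure(list(contrast = contrast %||% paste(levels(y), collapse = " vs "),
                 classes = levels(y), splits = splits, summary = summary_tbl,
                 permutation_p = perm_p, n_permutations = n_permutations,
                 null_accuracy = perm_acc,
                 settings = list(n_splits = n_splits, cv_folds = cv_folds,
                                 cost_grid = cost_grid, test_prop = test_prop),
                 seed = seed),
            class = "sg_classification")
}

#' Run the full set of pairwise group contrasts
#'
#' Evaluates the classifier on the three contrast families of the study
#' design: (A) each MDD subgroup versus HC, (B) each suicidal-ideation
#' subgroup and MDDSB versus MDDNSI, and (C) all pairs among the
#' suicidal-ideation subgroups and MDDSB -- 5 + 4 + 6 = 15 binary
#' contrasts when all six groups are present. Missing groups cause their
#' contrasts to be skipped with a logged reason. In every contrast the
#' less severe group is the first (negative) class.
#'
#' @param features Feature tibble from [build_features()] with
#'   `subject_id`.
#' @param subjects Phenotype table with `subject_id` and `group`.
#' @param ... Passed to [evaluate_classifier()].
#' @param seed Master seed; each contrast uses a derived substream.
#' @return List with `reports` (named list of `sg_classification`) and
#'   `skipped` (tibble `contrast`, `reason`).
#' @export
run_all_contrasts <- function(features, subjects, ..., seed = 1L) {
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  groups <- suicidality_groups()
  si <- groups[3:6]  # MDDmSI .. MDDSB
  contrasts <- rbind(
    data.frame(a = "HC", b = groups[-1]),
    data.frame(a = "MDDNSI", b = si),
    as.data.frame(t(utils::combn(si, 2)), col.names = c("a", "b")) |>
      stats::setNames(c("a", "b"))
  )
  present <- unique(as.character(subjects$group))
  merged <- dplyr::inner_join(features,
                              dplyr::select(subjects, "subject_id", "group"),
                              by = "subject_id")
  reports <- list(); skipped <- list()
  for (q in seq_len(nrow(contrasts))) {
    a <- contrasts$a[q]; b <- contrasts$b[q]
    nm <- paste(b, "vs", a)
    if (!all(c(a, b) %in% present)) {
      skipped[[nm]] <- tibble::tibble(
        contrast = nm,
        reason = paste("missing group(s):",
                       paste(setdiff(c(a, b), present), collapse = ", ")))
      next
    }
    sub <- merged[merged$group %in% c(a, b), , drop = FALSE]
    y <- factor(as.character(sub$group), levels = c(a, b))
    reports[[nm]] <- evaluate_classifier(
      dplyr::select(sub, -"group"), y, ...,
      seed = substream_seed(seed, stream = 29L, index = q), contrast = nm)
  }
  list(reports = reports, skipped = dplyr::bind_rows(skipped))
}

#' @export
print.sg_classification <- function(x, ...) {
  cat("<sg_classification> ", x$contrast, " (positive class: ", x$classes[2],
      ")\n", sep = "")
  s <- x$summary
  for (m in c("accuracy", "sensitivity", "specificity", "auc")) {
    row <- s[s$metric == m, ]
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, row$mean, row$sd))
  }
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p (accuracy) = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  }
  invisible(x)
}
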