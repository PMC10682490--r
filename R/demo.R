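with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_sg("stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' End-to-end pipeline demonstration on a synthetic cohort
#'
#' Runs the whole analysis in the order of the study design --
#' simulate -> QC -> connectomes -> network summaries -> roles ->
#' covariate-adjusted metric tests with FDR -> NBS -> conjunction -> FCI
#' features -> SVM contrasts -> behaviour correlations -> heterogeneity
#' screens -- on the default synthetic cohort, and writes a full output
#' tree (tidy CSV/TSV tables, a JSON run manifest with per-file digests,
#' and a human-readable report). Every stage derives its randomness from
#' `seed`, so two runs with the same seed produce identical outputs.
#'
#' The analysis parameters are scaled for a quick single-CPU run: 200 NBS
#' permutations, and 5 splits / 5 folds / 50 label permutations per
#' classifier contrast.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [cohort_config()]; default uses `seed`.
#' @param nbs_permutations Permutations per NBS contrast.
#' @param clf_splits,clf_folds,clf_permutations Classifier protocol sizes.
#' @param fd_threshold Head-motion QC threshold in millimetres.
#' @param verbose Print stage progress.
#' @return (Invisibly) a list with every intermediate result and the
#'   manifest.
#' @export
run_demo <- function(seed = 1L, out_dir = file.path(tempdir(), "suigrad_demo"),
                     config = NULL, nbs_permutations = 200,
                     clf_splits = 5, clf_folds = 5, clf_permutations = 50,
                     fd_threshold = 0.2, verbose = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[suigrad] ", ...)
  config <- config %||% cohort_config(seed = seed)

  say("simulate: generating synthetic cohort")
  cohort <- with_stage("simulate", generate_cohort(config, output = "connectome"))

  say("qc: head-motion filter at ", fd_threshold, " mm")
  qc <- with_stage("qc", qc_filter(cohort$subjects, fd_threshold))
  subjects <- qc$retained
  connectomes <- cohort$data[subjects$subject_id]

  say("summarize: network summaries for ", nrow(subjects), " subjects")
  summaries <- with_stage("summarize", summarize_cohort(connectomes, cohort$partition))
  group_summary <- with_stage("summarize", summarize_groups(summaries, subjects))

  say("roles: network role taxonomy and trajectory")
  roles <- with_stage("roles", assign_roles(group_summary))
  traj <- with_stage("roles", role_trajectory(roles))

  say("stats: covariate-adjusted metric tests with FDR")
  contrast_list <- c(list(omnibus = NULL),
                     stats::setNames(lapply(suicidality_groups()[-1],
                                            function(g) c("HC", g)),
                                     paste0(suicidality_groups()[-1], "_vs_HC")))
  metric_tests <- with_stage("stats", purrr::imap_dfr(contrast_list, function(gr, nm) {
    dplyr::mutate(metric_test_table(summaries, subjects, groups = gr),
                  contrast = nm, .before = 1L)
  }))

  say("nbs: permutation inference (", nbs_permutations, " permutations)")
  nbs_contrasts <- list(MDDSSI_vs_HC = "MDDSSI", MDDSB_vs_HC = "MDDSB")
  nbs_results <- with_stage("nbs", purrr::imap(nbs_contrasts, function(g, nm) {
    keep <- subjects$group %in% c("HC", g)
    sub <- subjects[keep, , drop = FALSE]
    nbs_test(connectomes[sub$subject_id],
             factor(as.character(sub$group), levels = c(g, "HC")),
             covariates = sub[c("age", "sex", "education", "site")],
             n_permutations = nbs_permutations,
             seed = substream_seed(seed, stream = 41L,
                                   index = match(nm, names(nbs_contrasts))))
  }))

  say("conjunction: overlap of differential edge sets")
  sig_sets <- purrr::map(nbs_results, significant_edges)
  conj <- with_stage("conjunction", {
    if (all(vapply(sig_sets, nrow, integer(1)) > 0)) conjunction(sig_sets)
    else as_edge_set(integer(0), integer(0))
  })
  feature_edges <- conj
  feature_source <- "conjunction"
  if (nrow(feature_edges) == 0L) {
    un <- dplyr::bind_rows(purrr::map(sig_sets, ~ dplyr::select(.x, "node_i", "node_j")))
    un <- dplyr::distinct(un)
    if (nrow(un) > 0L) {
      feature_edges <- as_edge_set(un)
      feature_source <- "union of significant components"
    } else {
      # final fallback: strongest edges of the severest contrast
      es <- edge_stats(connectomes[subjects$group %in% c("HC", "MDDSB")][
        order(names(connectomes[subjects$group %in% c("HC", "MDDSB")]))],
        factor(as.character(subjects$group[subjects$group %in% c("HC", "MDDSB")]),
               levels = c("MDDSB", "HC")))
      top <- es[order(-abs(es$statistic)), ][seq_len(31), ]
      feature_edges <- as_edge_set(top$node_i, top$node_j)
      feature_source <- "top 31 |t| edges (no significant component)"
    }
  }

  say("classify: FCI features over ", nrow(feature_edges), " edges (",
      feature_source, "); 15 contrasts")
  features <- with_stage("classify",
                         build_features(connectomes, feature_edges, mode = "fci",
                                        partition = cohort$partition))
  clf <- with_stage("classify", run_all_contrasts(
    features, subjects, n_splits = clf_splits, cv_folds = clf_folds,
    n_permutations = clf_permutations,
    seed = substream_seed(seed, stream = 43L)))
  clf_glance <- purrr::map_dfr(clf$reports, glance)

  say("correlate: covariate-controlled behaviour correlations")
  mdd <- subjects[subjects$group != "HC", , drop = FALSE]
  metric_wide <- summaries |>
    dplyr::select("subject_id", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value") |>
    dplyr::inner_join(mdd, by = "subject_id")
  metric_names <- unique(summaries$name)
  correlations <- with_stage("correlate", purrr::map_dfr(metric_names, function(mname) {
    purrr::map_dfr(c("hamd_anxiety", "hamd_weight"), function(cv) {
      dplyr::mutate(partial_pearson(metric_wide, mname, cv,
                                    covariates = c("age", "sex", "education", "site")),
                    metric = mname, clinical = cv, .before = 1L)
    })
  }))

  say("heterogeneity: sex and age rank-sum screens")
  heterogeneity <- with_stage("heterogeneity", dplyr::bind_rows(
    heterogeneity_screen(metric_wide, metric_names, split = "sex"),
    heterogeneity_screen(metric_wide, metric_names, split = "age")))

  say("writing outputs to ", out_dir)
  fp <- function(f) file.path(out_dir, f)
  readr::write_csv(subjects, fp("subjects.csv"))
  readr::write_csv(qc$exclusions, fp("qc_exclusions.csv"))
  readr::write_csv(summaries, fp("network_summaries.csv"))
  readr::write_csv(group_summary, fp("group_summary.csv"))
  readr::write_csv(roles, fp("network_roles.csv"))
  readr::write_csv(traj$stability, fp("role_stability.csv"))
  readr::write_csv(metric_tests, fp("metric_tests.csv"))
  purrr::iwalk(nbs_results, function(res, nm) {
    readr::write_csv(tidy(res), fp(paste0("nbs_", nm, "_components.csv")))
  })
  nbs_glance <- purrr::map_dfr(nbs_results, glance)
  readr::write_csv(nbs_glance, fp("nbs_summary.csv"))
  write_edge_list(feature_edges, fp("conjunction_edges.tsv"))
  readr::write_csv(features, fp("fci_features.csv"))
  readr::write_csv(clf_glance, fp("classification_summary.csv"))
  readr::write_csv(purrr::map_dfr(clf$reports, tidy), fp("classification_splits.csv"))
  readr::write_csv(correlations, fp("behaviour_correlations.csv"))
  readr::write_csv(heterogeneity, fp("heterogeneity_screen.csv"))

  report <- c(
    "suigrad end-to-end demonstration",
    sprintf("seed %d; %d subjects retained (%d excluded by FD > %.2g mm)",
            seed, nrow(subjects), nrow(qc$exclusions), fd_threshold),
    sprintf("metric tests: %d contrasts x %d metrics",
            length(contrast_list), nrow(metric_tests) / length(contrast_list)),
    sprintf("FDR-significant metrics (omnibus, q <= 0.05): %d",
            sum(metric_tests$p_adjusted[metric_tests$contrast == "omnibus"] <= 0.05)),
    sprintf("network roles: %d networks x %d groups; %d divergent across gradient",
            dplyr::n_distinct(roles$network), dplyr::n_distinct(roles$group),
            sum(!traj$stability$stable)),
    sprintf("NBS: %s", paste(sprintf("%s: %d component(s), min p %.4g",
                                     names(nbs_results),
                                     vapply(nbs_results, function(r) nrow(r$components), integer(1)),
                                     vapply(nbs_results, function(r)
                                       if (nrow(r$components)) min(r$components$p_value) else NA_real_,
                                       numeric(1))),
                             collapse = "; ")),
    sprintf("feature edges: %d (%s)", nrow(feature_edges), feature_source),
    sprintf("classification: %d reports, %d skipped; AUC range %.3f-%.3f",
            length(clf$reports), nrow(clf$skipped),
            min(clf_glance$auc), max(clf_glance$auc)),
    sprintf("heterogeneity: %d/%d sex-significant, %d/%d age-significant metrics",
            sum(heterogeneity$significant[heterogeneity$split == "sex"]),
            sum(heterogeneity$split == "sex"),
            sum(heterogeneity$significant[heterogeneity$split == "age"]),
            sum(heterogeneity$split == "age")),
    sprintf("elapsed: %.1f min", as.numeric(difftime(Sys.time(), t0, units = "mins")))
  )
  writeLines(report, fp("report.txt"))

  files <- setdiff(list.files(out_dir, full.names = TRUE), fp("manifest.json"))
  manifest <- list(
    package = "suigrad",
    version = as.character(utils::packageVersion("suigrad")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = list(n_per_group = as.list(config$n_per_group),
                  t_len = config$t_len, sites = config$sites,
                  noise_sd = config$noise_sd,
                  nbs_permutations = nbs_permutations,
                  clf_splits = clf_splits, clf_folds = clf_folds,
                  clf_permutations = clf_permutations,
                  fd_threshold = fd_threshold,
                  feature_source = feature_source),
    files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  say("done: ", paste(report[2], collapse = ""))

  invisible(list(cohort = cohort, subjects = subjects, qc = qc,
                 summaries = summaries, group_summary = group_summary,
                 roles = roles, trajectory = traj, metric_tests = metric_tests,
                 nbs = nbs_results, conjunction = conj,
                 feature_edges = feature_edges, feature_source = feature_source,
                 features = features, classification = clf,
                 classification_summary = clf_glance,
                 correlations = correlations, heterogeneity = heterogeneity,
                 manifest = manifest, out_dir = out_dir))
}
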