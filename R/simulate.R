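#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated multi-site resting-state
#' cohort spanning the six suicidality groups. Each subject's node time
#' series are drawn from a zero-mean multivariate normal whose correlation
#' matrix is block-constant over the partition's networks: within-network
#' blocks take `base_within[net] + shift`, between-network blocks take
#' `(base_between[a] + base_between[b]) / 2 + shift`, where the shifts come
#' from `effect_map` (per group) and `site_shift` (per acquisition site,
#' applied to every off-diagonal block as a nuisance offset).
#'
#' The default `effect_map` plants the non-monotone gradient the analysis
#' is designed to detect: within-network connectivity of AUD, SAN and SUB
#' first rises and then falls across HC -> MDDNSI -> ... -> MDDSB
#' (inverted-U), while the one-versus-others connectivity of DMN and VAN
#' first falls and then rises (U-shape), together with baseline values that
#' make the AUD/SAN/SUB trio straddle the within-network median so their
#' network roles diverge across groups while the other seven stay stable.
#'
#' @param seed Integer master seed; every subject draws from a substream
#'   derived from it, so subject data are stable under group-size changes.
#' @param n_per_group Named counts for the six groups (scaled-down default
#'   50/30/30/25/20/15).
#' @param partition An [as_partition()]; default 226-node, 10-network
#'   fixture.
#' @param t_len Timepoints per subject (default 200).
#' @param base_within,base_between Named per-network baselines (see above);
#'   defaults cover the fixture's 10 networks.
#' @param effect_map Tibble `group`, `net_a`, `net_b`, `delta` of additive
#'   shifts on block correlations. `net_b == net_a` targets the within
#'   block; `net_b == "OTHERS"` targets every between block touching
#'   `net_a` (overlapping shifts add).
#' @param sites Character vector of site labels; subjects are assigned
#'   round-robin within group.
#' @param site_shift Named additive offset per site on all off-diagonal
#'   correlations.
#' @param noise_sd Standard deviation of optional iid measurement noise
#'   added to the time series (default 0; positive values attenuate all
#'   observed correlations by 1 / (1 + noise_sd^2)).
#' @param clinical_model List of linear models linking HAMD subfactor
#'   scores to the planted FCI (see [generate_clinical()]): each element
#'   `c(base, slope, sd)` with slope per SD of planted FCI, plus
#'   `hamd_total_base` per MDD group and integer clipping ranges.
#' @return List of class `sg_cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_per_group = c(HC = 50L, MDDNSI = 30L, MDDmSI = 30L,
                                          MDDmoSI = 25L, MDDSSI = 20L, MDDSB = 15L),
                          partition = default_partition(),
                          t_len = 200L,
                          base_within = NULL,
                          base_between = NULL,
                          effect_map = default_effect_map(),
                          sites = c("siteA", "siteB"),
                          site_shift = c(siteA = 0, siteB = 0.02),
                          noise_sd = 0,
                          clinical_model = default_clinical_model()) {
  groups <- suicidality_groups()
  if (!all(groups %in% names(n_per_group))) {
    stop_sg("n_per_group must name all groups: ", paste(groups, collapse = ", "))
  }
  nets <- network_names(partition)
  base_within <- base_within %||% default_base_within()[nets]
  base_between <- base_between %||% default_base_between()[nets]
  if (anyNA(base_within) || anyNA(base_between)) {
    stop_sg("base_within/base_between must cover every partition network")
  }
  if (t_len < 3L) stop_sg("t_len must be at least 3")
  if (!all(names(site_shift) == sites)) stop_sg("site_shift must be named by sites")
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group[groups],
              partition = partition, t_len = as.integer(t_len),
              base_within = base_within, base_between = base_between,
              effect_map = effect_map, sites = sites, site_shift = site_shift,
              noise_sd = noise_sd, clinical_model = clinical_model)
  class(cfg) <- "sg_cohort_config"
  cfg
}

# Baseline within-network correlations. Four networks sit well below the
# within-network median (stable incohesive), three well above (stable
# cohesive), and AUD/SAN/SUB straddle it so the planted gradient moves them
# across. Levels are on the high side of typical resting-state values so
# planted shifts stay comfortably clear of sampling noise at T = 200.
default_base_within <- function() {
  c(DAN = 0.24, SMN = 0.26, DMN = 0.28, VAN = 0.30,
    AUD = 0.38, SAN = 0.42, SUB = 0.34,
    FPN = 0.53, CON = 0.56, VIS = 0.60)
}

# Per-network between-block levels b; block (a, b) baseline is the mean
# (b_a + b_b) / 2. The top five define the stable connector set, the
# bottom five the stable province set, with a wide SAN/SUB gap so the
# one-versus-others median boundary never moves.
default_base_between <- function() {
  c(DAN = 0.24, SMN = 0.21, CON = 0.18, AUD = 0.15, SAN = 0.12,
    SUB = 0.02, VIS = -0.01, FPN = -0.04, VAN = -0.07, DMN = -0.10)
}

#' @rdname cohort_config
#' @export
default_effect_map <- function() {
  mdd <- suicidality_groups()[-1]
  w <- function(net, deltas) tibble::tibble(group = mdd, net_a = net, net_b = net,
                                            delta = deltas)
  o <- function(net, deltas) tibble::tibble(group = mdd, net_a = net, net_b = "OTHERS",
                                            delta = deltas)
  dplyr::bind_rows(
    # within-network inverted-U (up from HC, peak at MDDmoSI, down into MDDSB)
    w("AUD", c(0.02, 0.04, 0.05, 0.02, 0.01)),
    w("SAN", c(0.02, 0.04, 0.05, 0.02, -0.07)),
    w("SUB", c(0.14, 0.16, 0.17, 0.14, 0.09)),
    # one-versus-others U-shape (down from HC, valley at MDDmoSI, up into MDDSB)
    o("DMN", c(-0.03, -0.05, -0.06, -0.03, 0.03)),
    o("VAN", c(-0.02, -0.035, -0.05, -0.02, 0.02))
  )
}

#' @rdname cohort_config
#' @export
default_clinical_model <- function() {
  list(
    hamd_total_base = c(MDDNSI = 16, MDDmSI = 22, MDDmoSI = 24,
                        MDDSSI = 26, MDDSB = 27),
    hamd_total_sd = 4, hamd_total_range = c(8, 52),
    # c(base, slope per SD of planted FCI, residual sd)
    anxiety = c(base = 5.5, slope = -1.4, sd = 1.8),
    weight = c(base = 0.8, slope = 0.45, sd = 0.6),
    retardation = c(base = 7.0, slope = 0.6, sd = 2.0),
    sleep = c(base = 3.9, slope = 0.3, sd = 1.6),
    ranges = list(anxiety = c(0, 12), weight = c(0, 3),
                  retardation = c(0, 15), sleep = c(0, 6)),
    # networks whose pooled within-network FC defines the planted FCI
    fci_networks = c("AUD", "SAN", "SUB")
  )
}

# 10 x 10 block-value matrix (diag = within, off-diag = between) for one
# group at one site, before positive-definiteness repair.
block_value_matrix <- function(config, group, site) {
  nets <- network_names(config$partition)
  k <- length(nets)
  bw <- config$base_within[nets]
  bb <- config$base_between[nets]
  m <- (outer(bb, rep(1, k)) + outer(rep(1, k), bb)) / 2
  diag(m) <- bw
  dimnames(m) <- list(nets, nets)
  em <- config$effect_map
  em <- em[em$group == group, , drop = FALSE]
  if (nrow(em)) {
    for (q in seq_len(nrow(em))) {
      a <- em$net_a[q]; b <- em$net_b[q]; d <- em$delta[q]
      if (!a %in% nets) stop_sg("effect_map network not in partition: ", a)
      if (identical(b, "OTHERS")) {
        m[a, nets != a] <- m[a, nets != a] + d
        m[nets != a, a] <- m[nets != a, a] + d
      } else if (a == b) {
        m[a, a] <- m[a, a] + d
      } else {
        m[a, b] <- m[a, b] + d
        m[b, a] <- m[b, a] + d
      }
    }
  }
  off <- config$site_shift[[site]]
  shift <- matrix(off, k, k); diag(shift) <- off
  m <- m + shift
  if (any(abs(m) >= 1)) {
    stop_sg("planted shifts push block correlations to |r| >= 1 for group ",
            group, "; reduce effect sizes or baselines")
  }
  m
}

# Expand a block-value matrix to the full node-level correlation target and
# repair to positive definite by eigenvalue clipping + renormalization to
# unit diagonal. Returns the repaired matrix, its upper Cholesky factor and
# the block means of the repaired matrix (what the data actually follow).
target_correlation <- function(config, group, site, eps = 1e-4) {
  bm <- block_value_matrix(config, group, site)
  net <- factor(config$partition$network, levels = network_names(config$partition))
  C <- bm[as.integer(net), as.integer(net)]
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  clipped <- any(ev$values < eps)
  if (clipped) {
    C_raw <- C
    vals <- pmax(ev$values, eps)
    C2 <- ev$vectors %*% (vals * t(ev$vectors))
    C <- stats::cov2cor(C2)
    # mild indefiniteness is repaired silently; a repair that visibly moves
    # the planted block structure means the config is inconsistent
    drift <- max(abs(block_means_of(C, config$partition) -
                       block_means_of(C_raw, config$partition)))
    if (drift > 0.05) {
      stop_sg("target correlation for group ", group, " is far from positive ",
              "definite (block drift ", signif(drift, 2), " after repair); ",
              "reduce base_between or the planted shifts")
    }
  }
  if (config$noise_sd > 0) {
    # iid measurement noise attenuates every observed correlation
    C_obs <- C / (1 + config$noise_sd^2)
    diag(C_obs) <- 1
  } else C_obs <- C
  list(corr = C, chol = chol(C), clipped = clipped,
       block_means = block_means_of(C_obs, config$partition))
}

# Block summary (10 x 10: diag = mean within off-diagonal, off = mean
# between) of a node-level matrix.
block_means_of <- function(C, partition) {
  idx <- network_index(partition)
  nets <- names(idx)
  k <- length(nets)
  out <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      sub <- C[idx[[a]], idx[[b]], drop = FALSE]
      out[a, b] <- if (a == b) mean(sub[upper.tri(sub)]) else mean(sub)
    }
  }
  out
}

#' Generate a synthetic multi-site cohort
#'
#' Draws the full cohort defined by a [cohort_config()]: per-subject node
#' time series (or connectomes), a phenotype table with demographics and
#' HAMD clinical scores, and a ground-truth record sufficient to re-derive
#' every planted effect. Fully reproducible from `config$seed`; each
#' subject uses a seed substream keyed by (group, position), so adding
#' subjects to one group leaves existing subjects' data unchanged.
#'
#' @param config A [cohort_config()].
#' @param output `"time_series"` (default) or `"connectome"`.
#' @return List of class `sg_cohort` with elements `subjects` (tibble),
#'   `data` (named list of T x N time-series matrices or `sg_connectome`s),
#'   `partition`, `config` and `ground_truth`. The ground truth records,
#'   per group, the site-weighted block means of the repaired target
#'   correlation matrices (`block_means`), the subject-level planted FCI
#'   values, the clinical generating model and the effect map.
#' @export
generate_cohort <- function(config = cohort_config(), output = c("time_series", "connectome")) {
  output <- match.arg(output)
  stopifnot(inherits(config, "sg_cohort_config"))
  partition <- config$partition
  n_nodes <- nrow(partition)
  groups <- suicidality_groups()
  sites <- config$sites

  targets <- list()
  for (g in groups) for (s in sites) {
    targets[[paste(g, s, sep = ".")]] <- target_correlation(config, g, s)
  }

  fci_edges <- networks_edge_set(partition, config$clinical_model$fci_networks)
  subj_rows <- list(); data <- list(); fci_vals <- numeric(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_g <- config$n_per_group[[g]]
    for (i in seq_len(n_g)) {
      site <- sites[1L + (i - 1L) %% length(sites)]
      id <- sprintf("%s_%03d", g, i)
      s_data <- substream_seed(config$seed, stream = gi, index = i)
      tgt <- targets[[paste(g, site, sep = ".")]]
      res <- withr::with_seed(s_data, {
        z <- matrix(stats::rnorm(config$t_len * n_nodes), config$t_len, n_nodes)
        ts <- z %*% tgt$chol
        if (config$noise_sd > 0) {
          ts <- ts + matrix(stats::rnorm(length(ts), sd = config$noise_sd),
                            nrow(ts), ncol(ts))
        }
        list(ts = ts,
             age = sample(18:65, 1L),
             sex = ifelse(stats::runif(1) < 0.55, "female", "male"),
             education = max(5L, min(22L, round(stats::rnorm(1, 13, 3)))),
             mean_fd = round(stats::rgamma(1, shape = 4, scale = 0.025), 4))
      })
      conn <- compute_fc(res$ts)
      fci_vals[[id]] <- fci(conn, fci_edges)
      data[[id]] <- if (output == "connectome") conn else res$ts
      subj_rows[[id]] <- tibble::tibble(
        subject_id = id, site = site, group = g, age = res$age, sex = res$sex,
        education = res$education, mean_fd = res$mean_fd)
    }
  }
  subjects <- dplyr::bind_rows(subj_rows)
  subjects$group <- factor(subjects$group, levels = groups)

  gt <- list(
    effect_map = config$effect_map,
    block_means = group_block_means(targets, config),
    clipped = any(vapply(targets, `[[`, logical(1), "clipped")),
    subject_fci = fci_vals,
    fci_edges = fci_edges,
    clinical_model = config$clinical_model
  )
  subjects <- generate_clinical(subjects, fci_vals, config)
  gt$fci_ref <- attr(subjects, "fci_ref")

  structure(list(subjects = subjects, data = data, partition = partition,
                 config = config, ground_truth = gt),
            class = "sg_cohort")
}

# site-weighted (by round-robin site proportions) block means per group
group_block_means <- function(targets, config) {
  groups <- suicidality_groups()
  sites <- config$sites
  out <- list()
  for (g in groups) {
    n_g <- config$n_per_group[[g]]
    site_n <- table(sites[1L + (seq_len(n_g) - 1L) %% length(sites)])
    acc <- 0
    for (s in sites) {
      wgt <- as.numeric(site_n[s]) / n_g
      acc <- acc + wgt * targets[[paste(g, s, sep = ".")]]$block_means
    }
    out[[g]] <- acc
  }
  out
}

#' All within-network edges of selected networks
#'
#' @param partition An `sg_partition`.
#' @param nets Network names; default all.
#' @return An [as_edge_set()] with every node pair inside each named
#'   network (no cross-network pairs).
#' @export
networks_edge_set <- function(partition, nets = network_names(partition)) {
  idx <- network_index(partition)[nets]
  pairs <- purrr::map_dfr(idx, function(nodes) {
    if (length(nodes) < 2L) return(tibble::tibble())
    cmb <- utils::combn(nodes, 2L)
    tibble::tibble(node_i = cmb[1, ], node_j = cmb[2, ])
  })
  as_edge_set(pairs$node_i, pairs$node_j)
}

#' Generate HAMD clinical scores coupled to planted connectivity
#'
#' HAMD subfactor scores (anxiety, weight, retardation, sleep) are linear
#' in the subject's planted FCI (standardized over MDD subjects) plus
#' Gaussian noise, with the signs set by the clinical model (default:
#' anxiety negative, weight positive), then rounded and clipped to
#' plausible integer ranges. The HAMD total increases with the suicide-item
#' score on average, and `hamd_suicide` is derived from the group so it is
#' consistent with [assign_suicidality_group()]. Healthy controls get `NA`
#' clinical scores.
#'
#' @param subjects Phenotype tibble with `subject_id` and `group`.
#' @param fci Named numeric of planted FCI per subject.
#' @param config The [cohort_config()].
#' @return `subjects` with clinical columns appended; the standardization
#'   reference (mean, sd of FCI over MDD subjects) is attached as attribute
#'   `fci_ref`.
#' @export
generate_clinical <- function(subjects, fci, config) {
  cm <- config$clinical_model
  groups <- suicidality_groups()
  is_mdd <- subjects$group != "HC"
  ref <- c(mean = mean(fci[is_mdd]), sd = stats::sd(fci[is_mdd]))
  z <- (fci - ref[["mean"]]) / ref[["sd"]]

  n <- nrow(subjects)
  suicide <- ifelse(is_mdd, match(as.character(subjects$group), groups) - 2L, NA_integer_)
  total <- anx <- wgt <- ret <- slp <- rep(NA_real_, n)
  draw <- function(par, zi) par[["base"]] + par[["slope"]] * zi + stats::rnorm(1, sd = par[["sd"]])
  clip <- function(x, rng) pmin(pmax(round(x), rng[1]), rng[2])
  for (q in seq_len(n)) {
    if (!is_mdd[q]) next
    s_cli <- substream_seed(config$seed, stream = 600L + match(as.character(subjects$group[q]), groups),
                            index = match(subjects$subject_id[q], subjects$subject_id))
    withr::with_seed(s_cli, {
      total[q] <- clip(cm$hamd_total_base[[as.character(subjects$group[q])]] +
                         stats::rnorm(1, sd = cm$hamd_total_sd), cm$hamd_total_range)
      anx[q] <- clip(draw(cm$anxiety, z[q]), cm$ranges$anxiety)
      wgt[q] <- clip(draw(cm$weight, z[q]), cm$ranges$weight)
      ret[q] <- clip(draw(cm$retardation, z[q]), cm$ranges$retardation)
      slp[q] <- clip(draw(cm$sleep, z[q]), cm$ranges$sleep)
    })
  }
  out <- dplyr::mutate(subjects,
                       hamd_total = total, hamd_suicide = suicide,
                       hamd_anxiety = anx, hamd_weight = wgt,
                       hamd_retardation = ret, hamd_sleep = slp)
  attr(out, "fci_ref") <- ref
  out
}

#' Expected group-level network summaries under the generator
#'
#' Derives, from a cohort's ground truth alone, the network summaries the
#' sample estimates converge to: block means of the repaired target
#' correlation matrices, site-weighted per group, pooled with the
#' partition's pair counts for the one-versus-others values. Used by
#' recovery tests as the closure property of the ground-truth record.
#'
#' @param cohort An `sg_cohort`.
#' @return Tibble `group`, `metric_type`, `name`, `value` matching the
#'   layout of [summarize_groups()].
#' @export
expected_group_summary <- function(cohort) {
  stopifnot(inherits(cohort, "sg_cohort"))
  partition <- cohort$partition
  idx <- network_index(partition)
  nets <- names(idx)
  sizes <- lengths(idx)
  n <- nrow(partition)
  purrr::imap_dfr(cohort$ground_truth$block_means, function(bm, g) {
    wnc <- tibble::tibble(group = g, metric_type = "wnc",
                          name = paste0("WNC_", nets), value = diag(bm))
    cmb <- utils::combn(nets, 2L)
    bnc <- tibble::tibble(group = g, metric_type = "bnc",
                          name = paste0("BNC_", cmb[1, ], "-", cmb[2, ]),
                          value = bm[cbind(cmb[1, ], cmb[2, ])])
    ovo_val <- vapply(nets, function(k) {
      others <- setdiff(nets, k)
      wts <- sizes[k] * sizes[others]
      sum(bm[k, others] * wts) / sum(wts)
    }, numeric(1))
    ovo <- tibble::tibble(group = g, metric_type = "ovo",
                          name = paste0("OVO_", nets), value = ovo_val)
    dplyr::bind_rows(wnc, ovo, bnc)
  })
}

#' @export
print.sg_cohort <- function(x, ...) {
  cat("<sg_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$partition), " nodes, ", length(network_names(x$partition)),
      " networks\n", sep = "")
  print(table(x$subjects$group))
  invisible(x)
}
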