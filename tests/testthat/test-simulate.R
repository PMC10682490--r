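test_that("same seed reproduces the cohort byte for byte", {
  cfg <- small_config(seed = 9, t_len = 60)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$data, b$data)
  expect_identical(a$ground_truth$subject_fci, b$ground_truth$subject_fci)
})

test_that("subject draws are stable when another group grows", {
  cfg1 <- small_config(seed = 3, t_len = 60)
  n2 <- cfg1$n_per_group; n2[["MDDSB"]] <- n2[["MDDSB"]] + 3
  cfg2 <- small_config(seed = 3, t_len = 60, n_per_group = n2)
  a <- generate_cohort(cfg1); b <- generate_cohort(cfg2)
  expect_identical(a$data[["HC_001"]], b$data[["HC_001"]])
  expect_identical(a$data[["MDDSB_002"]], b$data[["MDDSB_002"]])
})

test_that("with no planted effects the sample FC concentrates on the baselines", {
  cfg <- small_config(seed = 5,
                      n_per_group = c(HC = 10, MDDNSI = 2, MDDmSI = 2,
                                      MDDmoSI = 2, MDDSSI = 2, MDDSB = 2),
                      t_len = 1500, site_shift = c(siteA = 0, siteB = 0))
  coh <- generate_cohort(cfg, output = "connectome")
  s <- summarize_cohort(coh$data[coh$subjects$subject_id[coh$subjects$group == "HC"]],
                        coh$partition)
  b <- small_bases(coh$partition)
  for (k in network_names(coh$partition)) {
    est <- mean(s$value[s$name == paste0("WNC_", k)])
    expect_lt(abs(est - b$within[[k]]), 0.02)
  }
})

test_that("a planted within-network shift is recovered by group-mean WNC", {
  # oracle: empirical mean of the estimated shift over independent replicates
  diffs <- vapply(1:20, function(r) {
    em <- tibble::tibble(group = "MDDSSI", net_a = "NetB", net_b = "NetB",
                         delta = 0.15)
    cfg <- small_config(seed = 100 + r, t_len = 200,
                        n_per_group = c(HC = 25, MDDNSI = 2, MDDmSI = 2,
                                        MDDmoSI = 2, MDDSSI = 25, MDDSB = 2),
                        effect_map = em)
    coh <- generate_cohort(cfg, output = "connectome")
    s <- summarize_cohort(coh$data, coh$partition)
    gs <- summarize_groups(s, coh$subjects)
    w <- gs[gs$name == "WNC_NetB", ]
    w$value[w$group == "MDDSSI"] - w$value[w$group == "HC"]
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.15), 0.03)
})

test_that("ground-truth block means re-derive every planted effect", {
  # clip-free config: closure is tight
  em <- tibble::tibble(group = c("MDDSB", "MDDmSI"), net_a = c("NetA", "NetC"),
                       net_b = c("NetA", "NetC"), delta = c(0.1, -0.05))
  cfg <- small_config(seed = 2, t_len = 50,
                      n_per_group = c(HC = 4, MDDNSI = 2, MDDmSI = 2,
                                      MDDmoSI = 2, MDDSSI = 2, MDDSB = 2),
                      effect_map = em)
  coh <- generate_cohort(cfg)
  eg <- expected_group_summary(coh)
  site_avg <- mean(cfg$site_shift)
  for (q in seq_len(nrow(em))) {
    expected <- cfg$base_within[[em$net_a[q]]] + em$delta[q] + site_avg
    got <- eg$value[eg$group == em$group[q] & eg$name == paste0("WNC_", em$net_a[q])]
    expect_lt(abs(got - expected), 1e-6)
  }

  # default design: positive-definiteness repair may move block means a
  # little, but planted within-network effects survive to ~0.03
  coh2 <- test_cohort()
  eg2 <- expected_group_summary(coh2)
  em2 <- coh2$config$effect_map
  site_avg2 <- mean(coh2$config$site_shift)
  for (q in which(em2$net_a == em2$net_b)) {
    expected <- coh2$config$base_within[[em2$net_a[q]]] + em2$delta[q] + site_avg2
    got <- eg2$value[eg2$group == em2$group[q] & eg2$name == paste0("WNC_", em2$net_a[q])]
    expect_lt(abs(got - expected), 0.04)
  }
})

test_that("invalid targets fail with actionable messages", {
  em <- tibble::tibble(group = "MDDSB", net_a = "NetA", net_b = "NetA", delta = 0.8)
  expect_error(generate_cohort(small_config(effect_map = em)), "\\|r\\| >= 1")
  p <- small_partition()
  b <- small_bases(p)
  b$between[] <- 0.6  # between blocks far beyond what the within blocks allow
  cfg <- small_config()
  cfg$base_between <- b$between
  expect_error(generate_cohort(cfg), "positive")
})

test_that("clinical scores follow the planted FCI coupling", {
  coh <- test_cohort()
  subj <- coh$subjects
  fci_v <- coh$ground_truth$subject_fci[subj$subject_id]
  mdd <- subj$group != "HC"
  # anxiety slope is negative, weight positive (defaults)
  expect_lt(cor(fci_v[mdd], subj$hamd_anxiety[mdd]), 0)
  expect_gt(cor(fci_v[mdd], subj$hamd_weight[mdd]), 0)
  # HAMD total increases with the suicide item on average
  fit <- lm(hamd_total ~ hamd_suicide, data = subj[mdd, ])
  expect_gt(coef(fit)[["hamd_suicide"]], 0)
  # HC rows carry no clinical scores
  expect_true(all(is.na(subj$hamd_total[!mdd])))
  # suicide item consistent with the group mapping
  regen <- assign_suicidality_group(subj$hamd_suicide, mdd)
  expect_equal(as.character(regen), as.character(subj$group))
})

test_that("zero clinical coupling leaves scores independent of connectivity", {
  cm <- default_clinical_model()
  cm$fci_networks <- c("NetA", "NetB")
  for (v in c("anxiety", "weight", "retardation", "sleep")) cm[[v]][["slope"]] <- 0
  cfg <- small_config(seed = 8, t_len = 80,
                      n_per_group = c(HC = 2, MDDNSI = 20, MDDmSI = 20,
                                      MDDmoSI = 20, MDDSSI = 20, MDDSB = 20))
  cfg$clinical_model <- cm
  coh <- generate_cohort(cfg, output = "connectome")
  mdd <- coh$subjects$group != "HC"
  fci_v <- coh$ground_truth$subject_fci[coh$subjects$subject_id][mdd]
  expect_lt(abs(cor(fci_v, coh$subjects$hamd_anxiety[mdd])), 0.2)
})

test_that("negative anxiety coupling is recovered at n = 150", {
  hits <- vapply(1:20, function(r) {
    cfg <- small_config(seed = 2000 + r, t_len = 80,
                        n_per_group = c(HC = 2, MDDNSI = 30, MDDmSI = 30,
                                        MDDmoSI = 30, MDDSSI = 30, MDDSB = 30))
    coh <- generate_cohort(cfg, output = "connectome")
    mdd <- coh$subjects$group != "HC"
    fci_v <- coh$ground_truth$subject_fci[coh$subjects$subject_id][mdd]
    ct <- cor.test(fci_v, coh$subjects$hamd_anxiety[mdd])
    ct$estimate < 0 && ct$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
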