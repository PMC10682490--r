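# Shared fixtures, built in code at test time.

# tiny 2-network partition
tiny_partition <- function() {
  as_partition(data.frame(node_id = 1:4, network = c("A", "A", "B", "B")))
}

# small 4-network partition for simulation-heavy tests (40 nodes)
small_partition <- function(sizes = c(NetA = 12, NetB = 10, NetC = 10, NetD = 8)) {
  as_partition(data.frame(node_id = seq_len(sum(sizes)),
                          network = rep(names(sizes), sizes)))
}

small_bases <- function(partition) {
  nets <- network_names(partition)
  list(within = stats::setNames(seq(0.25, 0.45, length.out = length(nets)), nets),
       between = stats::setNames(seq(0.12, 0.02, length.out = length(nets)), nets))
}

# a no-effect config on the small partition (overridable)
small_config <- function(seed = 1, n_per_group = c(HC = 6, MDDNSI = 4, MDDmSI = 4,
                                                   MDDmoSI = 4, MDDSSI = 4, MDDSB = 4),
                         t_len = 120, effect_map = NULL, ...) {
  p <- small_partition()
  b <- small_bases(p)
  em <- effect_map %||% tibble::tibble(group = character(0), net_a = character(0),
                                       net_b = character(0), delta = numeric(0))
  cm <- default_clinical_model()
  cm$fci_networks <- c("NetA", "NetB")
  cohort_config(seed = seed, n_per_group = n_per_group, partition = p,
                t_len = t_len, base_within = b$within, base_between = b$between,
                effect_map = em, clinical_model = cm, ...)
}

# symmetric pearson-scale connectome from upper-triangle values
toy_connectome <- function(upper, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- upper
  m <- m + t(m)
  diag(m) <- 1
  as_connectome(m)
}

random_connectome <- function(n, sd = 0.3) {
  toy_connectome(pmax(pmin(stats::rnorm(n * (n - 1) / 2, 0, sd), 0.99), -0.99), n)
}

# cached default-design cohort, scaled down, shared across test files
test_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- cohort_config(seed = 42,
                           n_per_group = c(HC = 20, MDDNSI = 12, MDDmSI = 12,
                                           MDDmoSI = 12, MDDSSI = 12, MDDSB = 12),
                           t_len = 150)
      memo <<- generate_cohort(cfg, output = "connectome")
    }
    memo
  }
})

test_summaries <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      coh <- test_cohort()
      memo <<- summarize_cohort(coh$data, coh$partition)
    }
    memo
  }
})

`%||%` <- function(x, y) if (is.null(x)) y else x
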