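# shared fixture builders; everything is generated in code at test time

# small planted-effect cohort for pipeline-level tests
small_cohort <- function(seed = 1, n_subjects = 16, n_nodes = 20,
                         frames_per_run = 84, effect_size = 0.3,
                         n_planted = 6, fd_spike_rate = 0.05) {
  pe <- plant_edges(n_nodes, n_planted, n_planted, seed = seed)
  spec <- cohort_spec(
    n_subjects = n_subjects, n_nodes = n_nodes, frames_per_run = frames_per_run,
    positive_edges = pe$positive, negative_edges = pe$negative,
    effect_size = effect_size, fd_spike_rate = fd_spike_rate,
    seed = seed + 1000)
  generate_cohort(spec)
}

# subjects x edges matrix from raw frames (no censoring/GSR): isolates the
# planted coupling for engine-level tests
raw_edges <- function(cohort) {
  t(vapply(cohort$subjects, function(s) {
    to_edge_vector(stats::cor(do.call(rbind, s$runs)))
  }, numeric(n_edges(cohort$truth$n_nodes))))
}

# random symmetric correlation-like matrix (unit diagonal, entries in [-1,1])
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
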