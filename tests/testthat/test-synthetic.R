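test_that("cohort has the contracted shape: runs, frames, nodes, FD traces", {
  pe <- plant_edges(10, 2, 2, seed = 3)
  spec <- cohort_spec(n_subjects = 8, n_nodes = 10, n_runs = 2,
                      frames_per_run = 120, dummy_frames = 4,
                      positive_edges = pe$positive,
                      negative_edges = pe$negative, seed = 9)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 8)
  expect_length(coh$phenotypes, 8)
  for (s in coh$subjects) {
    expect_length(s$runs, 2)
    for (r in s$runs) expect_equal(dim(r), c(120, 10))
    for (fd in s$fd) expect_length(fd, 120)
    expect_true(all(is.na(vapply(s$fd, `[`, numeric(1), 1)))) # frame 1 FD is NA
  }
})

test_that("generation is bit-for-bit reproducible from the seed", {
  spec <- function() {
    pe <- plant_edges(12, 3, 3, seed = 2)
    cohort_spec(n_subjects = 4, n_nodes = 12, frames_per_run = 40,
                positive_edges = pe$positive, negative_edges = pe$negative,
                seed = 77)
  }
  a <- generate_cohort(spec())
  b <- generate_cohort(spec())
  expect_identical(a$phenotypes, b$phenotypes)
  for (s in 1:4) {
    expect_identical(a$subjects[[s]]$runs, b$subjects[[s]]$runs)
    expect_identical(a$subjects[[s]]$fd, b$subjects[[s]]$fd)
  }
})

test_that("truth_mask maps planted pairs to canonical indices", {
  spec <- cohort_spec(n_subjects = 4, n_nodes = 3,
                      positive_edges = data.frame(i = 0L, j = 1L),
                      effect_size = 0.2, seed = 1)
  tm <- truth_mask(spec)
  expect_equal(tm$positive$indices, 1L) # (0,1) is the first canonical edge
  expect_length(tm$negative$indices, 0)

  spec2 <- cohort_spec(n_subjects = 4, n_nodes = 10, seed = 1)
  tm2 <- truth_mask(spec2)
  expect_length(tm2$positive$indices, 0)
  expect_length(tm2$negative$indices, 0)

  pe <- plant_edges(15, 4, 6, seed = 5)
  spec3 <- cohort_spec(n_subjects = 4, n_nodes = 15,
                       positive_edges = pe$positive,
                       negative_edges = pe$negative, seed = 1)
  tm3 <- truth_mask(spec3)
  expect_length(tm3$positive$indices, 4)
  expect_length(tm3$negative$indices, 6)
})

test_that("spec invariants are enforced", {
  shared <- data.frame(i = 0L, j = 1L)
  expect_error(cohort_spec(4, n_nodes = 5, positive_edges = shared,
                           negative_edges = shared, seed = 1),
               "disjoint")
  expect_error(cohort_spec(4, n_nodes = 5, effect_size = 0.4,
                           baseline_correlation = 0.3, seed = 1),
               "< 1")
  expect_error(cohort_spec(4, n_nodes = 5, frames_per_run = 4,
                           dummy_frames = 4, seed = 1))
  expect_error(cohort_spec(4, n_nodes = 5, fd_spike_magnitude_mm = 0.1,
                           seed = 1))
  expect_error(plant_edges(40, 30, 30), "degree cap")
})

test_that("a jointly unsatisfiable planted triangle is flagged infeasible", {
  # (0,1) and (0,2) strongly positive with (1,2) strongly negative cannot
  # be completed to a PSD correlation matrix for extreme phenotypes
  spec <- cohort_spec(
    n_subjects = 12, n_nodes = 6, frames_per_run = 20,
    positive_edges = data.frame(i = c(0L, 0L), j = c(1L, 2L)),
    negative_edges = data.frame(i = 1L, j = 2L),
    effect_size = 0.45, baseline_correlation = 0, seed = 4)
  expect_error(generate_cohort(spec), "infeasible")
})

test_that("with no planted effect, edge-phenotype associations are null-distributed", {
  # 210 edges, 64 subjects: fraction of Spearman p < 0.05 stays inside a
  # wide binomial band around 0.05
  coh <- small_cohort(seed = 21, n_subjects = 64, n_nodes = 21,
                      frames_per_run = 64, effect_size = 0,
                      n_planted = 0, fd_spike_rate = 0)
  edges <- raw_edges(coh)
  pvals <- apply(edges, 2, function(e) {
    stats::cor.test(e, coh$phenotypes, method = "spearman",
                    exact = FALSE)$p.value
  })
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 210))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 210))
})

test_that("planted positive edges separate phenotype quartiles in raw FC", {
  pe <- plant_edges(40, 30, 0, seed = 8)
  spec <- cohort_spec(n_subjects = 64, n_nodes = 40, frames_per_run = 200,
                      dummy_frames = 0, fd_spike_rate = 0,
                      positive_edges = pe$positive, effect_size = 0.3,
                      seed = 88)
  coh <- generate_cohort(spec)
  edges <- raw_edges(coh)
  idx <- truth_mask(spec)$positive$indices
  q <- stats::quantile(coh$phenotypes, c(0.25, 0.75))
  top <- coh$phenotypes >= q[2]
  bottom <- coh$phenotypes <= q[1]
  expect_gt(mean(edges[top, idx]), mean(edges[bottom, idx]))
})

test_that("sampled correlations converge to the subject's target matrix", {
  pe <- plant_edges(12, 3, 3, seed = 6)
  spec <- cohort_spec(n_subjects = 2, n_nodes = 12, frames_per_run = 4000,
                      dummy_frames = 0, n_runs = 1, fd_spike_rate = 0,
                      positive_edges = pe$positive,
                      negative_edges = pe$negative, seed = 66)
  coh <- generate_cohort(spec)
  for (s in 1:2) {
    emp <- stats::cor(coh$subjects[[s]]$runs[[1]])
    expect_lt(max(abs(emp - coh$target_matrices[[s]])), 0.08)
  }
})

test_that("cohort on-disk layout round-trips", {
  coh <- small_cohort(seed = 14, n_subjects = 3, n_nodes = 8,
                      frames_per_run = 30, n_planted = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sub-001_run-1_timeseries.tsv")))
  expect_true(file.exists(file.path(dir, "sub-001_run-2_confounds.tsv")))
  # confounds dialect: framewise_displacement header, first frame n/a
  cf <- readLines(file.path(dir, "sub-001_run-1_confounds.tsv"), n = 2)
  expect_equal(cf[1], "framewise_displacement")
  expect_equal(cf[2], "n/a")
  back <- read_cohort(dir)
  expect_equal(names(back$phenotypes), names(coh$phenotypes))
  expect_equal(unname(back$phenotypes), unname(coh$phenotypes),
               tolerance = 1e-12)
  expect_equal(back$subjects[[1]]$runs[[1]], coh$subjects[[1]]$runs[[1]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(is.na(back$subjects[[2]]$fd[[1]][1]), TRUE)
  expect_equal(back$parcellation, coh$parcellation)
})
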