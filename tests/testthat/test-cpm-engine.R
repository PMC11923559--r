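test_that("a strictly monotone edge is selected with rho = 1", {
  set.seed(1)
  targets <- sort(rnorm(28)) + seq_len(28) * 1e-6 # no ties
  edges <- cbind(exp(targets),          # strictly increasing in target
                 rep(0.5, 28),          # constant: must be excluded
                 matrix(rnorm(28 * 10), 28, 10))
  sel <- edge_select(edges, targets, 0.01)
  expect_true(1 %in% sel$positive$indices)
  expect_equal(sel$positive$rho[match(1, sel$positive$indices)], 1)
  expect_false(2 %in% sel$positive$indices)
  expect_false(2 %in% sel$negative$indices)
})

test_that("selection boundary matches the t-approximation critical rho", {
  n <- 28
  t_c <- qt(1 - 0.01 / 2, df = n - 2)
  rho_crit <- t_c / sqrt(t_c^2 + (n - 2))
  expect_equal(rho_crit, 0.4785, tolerance = 1e-4) # frozen closed form
  set.seed(42)
  targets <- rnorm(n)
  edges <- matrix(rnorm(n * 400), n, 400)
  sel <- edge_select(edges, targets, 0.01)
  rho <- cpmr:::spearman_rho_cols(edges, targets)
  in_mask <- seq_len(400) %in% c(sel$positive$indices, sel$negative$indices)
  expect_equal(in_mask, abs(rho) > rho_crit)
})

test_that("rho and p agree with stats::cor.test per edge, including ties", {
  set.seed(5)
  n <- 12
  targets <- rnorm(n)
  edges <- matrix(round(rnorm(n * 30), 1), n, 30) # rounding induces ties
  rho <- cpmr:::spearman_rho_cols(edges, targets)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  for (e in seq_len(30)) {
    ct <- suppressWarnings(
      cor.test(edges[, e], targets, method = "spearman", exact = FALSE))
    expect_equal(rho[e], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(p[e], ct$p.value, tolerance = 1e-10)
  }
})

test_that("t-approximate p tracks the exact permutation p at small n", {
  # brute-force oracle: enumerate all permutations of the targets and count
  # |rho_perm| >= |rho_obs|
  set.seed(9)
  n <- 6
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ]
  targets <- rnorm(n)
  for (rep in 1:5) {
    edge <- rnorm(n)
    obs <- abs(cor(rank(edge), rank(targets)))
    null <- abs(apply(perms, 1, function(pm) {
      cor(rank(edge), rank(targets[pm]))
    }))
    p_exact <- mean(null >= obs - 1e-12)
    rho <- cpmr:::spearman_rho_cols(cbind(edge), targets)
    p_t <- 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
    expect_lt(abs(p_t - p_exact), 0.08)
  }
})

test_that("edge selection rejects degenerate training sets", {
  edges <- matrix(rnorm(12), 3, 4)
  expect_error(edge_select(edges, rnorm(3), 0.01), "at least 4")
  expect_error(edge_select(matrix(rnorm(20), 5, 4), rep(1, 5), 0.01),
               "all training targets equal")
})

test_that("selection is invariant to subject row order", {
  set.seed(13)
  edges <- matrix(rnorm(20 * 50), 20, 50)
  targets <- rnorm(20)
  perm <- sample(20)
  a <- edge_select(edges, targets, 0.05)
  b <- edge_select(edges[perm, ], targets[perm], 0.05)
  expect_equal(a$positive$indices, b$positive$indices)
  expect_equal(a$negative$indices, b$negative$indices)
})

test_that("network strength sums masked FC and matches the double-loop oracle", {
  mask <- edge_mask("positive", c(1L, 3L, 6L))
  ev <- c(0.2, 9, 0.5, 9, 9, -0.1, 9, 9, 9, 9)
  expect_equal(network_strength(ev, mask), 0.6)
  expect_equal(network_strength(ev, edge_mask("positive", integer(0))), 0)

  for (seed in 1:5) {
    n <- 9
    m <- random_symmetric(n, seed + 40)
    ev <- to_edge_vector(m)
    set.seed(seed)
    idx <- sort(sample(n_edges(n), 12))
    mask <- edge_mask("positive", idx)
    # oracle: loop over the full matrix restricted to masked (i, j) pairs
    pairs <- edge_pairs(n)[idx, ]
    acc <- 0
    for (e in seq_len(nrow(pairs))) {
      acc <- acc + m[pairs$i[e] + 1, pairs$j[e] + 1]
    }
    expect_identical(network_strength(ev, mask), acc)
  }
})

test_that("OLS fit recovers exact coefficients and matches normal equations", {
  # single-edge mask so strengths are the edge values themselves
  edges <- matrix(0, 3, 5)
  edges[, 2] <- c(1, 2, 3)
  mask <- edge_mask("positive", 2L)
  model <- fit_cpm(edges, c(2, 4, 6), mask)
  expect_equal(model$slope, 2)
  expect_equal(model$intercept, 0, tolerance = 1e-12)

  set.seed(31)
  edges <- matrix(rnorm(20 * 30), 20, 30)
  targets <- rnorm(20)
  mask <- edge_mask("negative", sort(sample(30, 7)))
  model <- fit_cpm(edges, targets, mask)
  s <- network_strength(edges, mask)
  X <- cbind(1, s)
  beta <- solve(t(X) %*% X, t(X) %*% targets) # normal-equations oracle
  expect_equal(model$intercept, beta[1], tolerance = 1e-10)
  expect_equal(model$slope, beta[2], tolerance = 1e-10)
})

test_that("degenerate models fall back to the training mean everywhere", {
  edges <- matrix(rnorm(5 * 4), 5, 4)
  targets <- c(1, 2, 3, 4, 10)
  model <- fit_cpm(edges, targets, edge_mask("positive", integer(0)))
  expect_true(model$degenerate)
  expect_equal(predict_cpm(model, edges[1, ]), 4)
  expect_equal(predict_cpm(model, edges), rep(4, 5))
})

test_that("prediction is local to the mask and monotone in masked positive edges", {
  set.seed(17)
  edges <- matrix(rnorm(10 * 20), 10, 20)
  targets <- 3 * rowSums(edges[, c(2, 5)]) + rnorm(10, sd = 0.01)
  mask <- edge_mask("positive", c(2L, 5L))
  model <- fit_cpm(edges, targets, mask)
  ev <- edges[1, ]
  base_pred <- predict_cpm(model, ev)
  ev_other <- ev; ev_other[10] <- ev_other[10] + 100 # non-masked edge
  expect_equal(predict_cpm(model, ev_other), base_pred)
  expect_gt(model$slope, 0)
  ev_up <- ev; ev_up[2] <- ev_up[2] + 1
  expect_gt(predict_cpm(model, ev_up), base_pred)
})

test_that("planted edges are recovered with few false selections", {
  # engine-level selection consistency on unregressed connectomes, where the
  # only phenotype coupling is the planted one
  stats <- vapply(1:20, function(seed) {
    coh <- small_cohort(seed = seed + 200, n_subjects = 64, n_nodes = 30,
                        frames_per_run = 200, effect_size = 0.3,
                        n_planted = 8, fd_spike_rate = 0)
    edges <- raw_edges(coh)
    sel <- edge_select(edges, coh$phenotypes, 0.01)
    tm <- truth_mask(coh$truth)
    planted <- c(tm$positive$indices, tm$negative$indices)
    chosen <- c(sel$positive$indices, sel$negative$indices)
    c(recall_pos = mean(tm$positive$indices %in% sel$positive$indices),
      recall_neg = mean(tm$negative$indices %in% sel$negative$indices),
      fp = length(setdiff(chosen, planted)) /
           (n_edges(30) - length(planted)))
  }, numeric(3))
  expect_gt(mean(stats["recall_pos", ]), 0.8)
  expect_gt(mean(stats["recall_neg", ]), 0.8)
  expect_lt(mean(stats["fp", ]), 2 * 0.01)
})
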