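#' Random balanced fold assignment
#'
#' Partitions subjects into k folds whose sizes differ by at most one,
#' uniformly at random, reproducibly from the seed.
#'
#' @param subject_ids character or integer ids
#' @param k number of folds (<= number of subjects)
#' @param seed RNG seed
#' @return list of class `fold_assignment`: k, `folds` (integer fold index
#'   per subject, named), seed
#' @export
assign_folds <- function(subject_ids, k, seed = 1L) {
  n <- length(subject_ids)
  if (k > n) stop("k = ", k, " exceeds the ", n, " subjects")
  if (k < 2) stop("k must be >= 2")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- withr_seed(seed, sample(rep.int(seq_len(k), sizes)))
  names(folds) <- subject_ids
  structure(list(k = k, folds = folds, seed = seed),
            class = "fold_assignment")
}

# Pearson r of pooled predictions; 0 (flagged) when either side is constant.
pooled_r <- function(actual, predicted) {
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(actual, predicted)
}

#' One k-fold cross-validated CPM run
#'
#' For every fold, edges are selected and the OLS model fit on the
#' out-of-fold training subjects only, then applied to the held-out fold, so
#' no subject ever contributes to both training and testing. Positive- and
#' negative-tail models are built and evaluated separately. Pooled accuracy
#' is the Pearson correlation between actual and predicted values over all
#' subjects, per tail.
#'
#' @param edges n_subjects x n_edges matrix of edge vectors
#' @param targets phenotype vector, length n_subjects
#' @param k number of folds
#' @param p_threshold edge-selection significance level (default 0.01)
#' @param seed seed for the fold assignment
#' @param collect_masks keep each fold's edge masks (for consensus maps)
#' @return list: `predictions` (per tail), `r` (named vector, per tail),
#'   `fold_assignment`, `masks` (per tail, list over folds, if collected),
#'   `n_degenerate` fold-models
#' @export
run_kfold <- function(edges, targets, k, p_threshold = 0.01, seed = 1L,
                      collect_masks = FALSE) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  stopifnot(length(targets) == n)
  fa <- assign_folds(seq_len(n), k, seed)
  pred <- list(positive = numeric(n), negative = numeric(n))
  masks <- list(positive = vector("list", k), negative = vector("list", k))
  n_degenerate <- 0L
  for (f in seq_len(k)) {
    test <- which(fa$folds == f)
    train <- which(fa$folds != f)
    tr_targets <- targets[train]
    if (length(unique(tr_targets)) == 1 || length(train) < 4) {
      # constant or tiny training targets: both tails fall back to the mean
      for (tail in c("positive", "negative")) {
        pred[[tail]][test] <- mean(tr_targets)
        masks[[tail]][[f]] <- edge_mask(tail, integer(0), p_threshold)
      }
      n_degenerate <- n_degenerate + 2L
      next
    }
    sel <- edge_select(edges[train, , drop = FALSE], tr_targets, p_threshold)
    for (tail in c("positive", "negative")) {
      model <- fit_cpm(edges[train, , drop = FALSE], tr_targets, sel[[tail]])
      if (model$degenerate) n_degenerate <- n_degenerate + 1L
      pred[[tail]][test] <- predict_cpm(model, edges[test, , drop = FALSE])
      masks[[tail]][[f]] <- sel[[tail]]
    }
  }
  r <- c(positive = as.numeric(pooled_r(targets, pred$positive)),
         negative = as.numeric(pooled_r(targets, pred$negative)))
  list(predictions = pred, r = r, fold_assignment = fa,
       masks = if (collect_masks) masks else NULL,
       n_degenerate = n_degenerate)
}

#' Iterated k-fold cross-validation with accuracy averaging
#'
#' Fold assignment is inherently random, so the k-fold run is repeated
#' `n_iterations` times with re-randomized folds (child seeds derived
#' deterministically from `master_seed`) and the pooled accuracies are
#' averaged arithmetically per tail. Per-edge selection counts over all
#' fold-models are accumulated for consensus mapping.
#'
#' @inheritParams run_kfold
#' @param n_iterations number of re-randomized k-fold runs (default 50)
#' @param master_seed seed from which per-iteration seeds are derived
#' @return object of class `prediction_result`: `actual`, `predictions`
#'   (per-subject mean over iterations, per tail), `per_iteration_r`
#'   (n_iterations x 2 matrix), `mean_r` (named), `selection` (per-tail
#'   selection counts and the number of fold-models), `n_iterations`, `k`,
#'   `p_threshold`, `n_degenerate`
#' @export
repeat_cv <- function(edges, targets, k, p_threshold = 0.01,
                      n_iterations = 50L, master_seed = 1L) {
  stopifnot(n_iterations >= 1)
  edges <- as.matrix(edges)
  seeds <- derive_seeds(master_seed, n_iterations)
  m <- ncol(edges)
  counts <- list(positive = numeric(m), negative = numeric(m))
  pred_sum <- list(positive = numeric(nrow(edges)),
                   negative = numeric(nrow(edges)))
  per_r <- matrix(NA_real_, n_iterations, 2,
                  dimnames = list(NULL, c("positive", "negative")))
  n_degenerate <- 0L
  for (it in seq_len(n_iterations)) {
    res <- run_kfold(edges, targets, k, p_threshold, seed = seeds[it],
                     collect_masks = TRUE)
    per_r[it, ] <- res$r[c("positive", "negative")]
    for (tail in c("positive", "negative")) {
      pred_sum[[tail]] <- pred_sum[[tail]] + res$predictions[[tail]]
      for (msk in res$masks[[tail]]) {
        counts[[tail]][msk$indices] <- counts[[tail]][msk$indices] + 1
      }
    }
    n_degenerate <- n_degenerate + res$n_degenerate
  }
  structure(list(
    actual = targets,
    predictions = lapply(pred_sum, function(x) x / n_iterations),
    per_iteration_r = per_r,
    mean_r = colMeans(per_r),
    selection = list(positive = counts$positive, negative = counts$negative,
                     n_models = n_iterations * k),
    n_iterations = n_iterations, k = k, p_threshold = p_threshold,
    n_degenerate = n_degenerate),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> n = %d, k = %d, %d iteration(s)\n  mean r: positive %.3f, negative %.3f\n",
    length(x$actual), x$k, x$n_iterations,
    x$mean_r["positive"], x$mean_r["negative"]))
  invisible(x)
}

# deterministic child seeds below 2^31
derive_seeds <- function(master_seed, n) {
  withr_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Permutation null for the cross-validated accuracy
#'
#' The phenotype values are shuffled uniformly across subjects and the full
#' k-fold run is re-executed (one fresh fold randomization per permutation);
#' the pooled accuracy of each shuffled run forms the null distribution. The
#' per-tail p-value is the observed accuracy's upper-tail percentile with the
#' add-one rule, p = (1 + #\{null_r >= observed\}) / (1 + n_perm), so p is
#' never 0.
#'
#' @inheritParams run_kfold
#' @param observed_r named numeric (positive, negative): the accuracy to test,
#'   typically `mean_r` from [repeat_cv()]
#' @param n_perm number of permutations (default 1000)
#' @param master_seed seed from which shuffle and fold seeds are derived
#' @return object of class `null_distribution`: `null_r` (n_perm x 2),
#'   `observed`, `p_value` (named, per tail), `n_perm`
#' @export
permutation_null <- function(edges, targets, k, observed_r,
                             p_threshold = 0.01, n_perm = 1000L,
                             master_seed = 1L) {
  stopifnot(n_perm >= 1, all(c("positive", "negative") %in% names(observed_r)))
  edges <- as.matrix(edges)
  seeds <- derive_seeds(master_seed, 2L * n_perm)
  null_r <- matrix(NA_real_, n_perm, 2,
                   dimnames = list(NULL, c("positive", "negative")))
  for (b in seq_len(n_perm)) {
    shuffled <- withr_seed(seeds[2L * b - 1L], sample(targets))
    res <- run_kfold(edges, shuffled, k, p_threshold, seed = seeds[2L * b])
    null_r[b, ] <- res$r[c("positive", "negative")]
  }
  p <- vapply(c("positive", "negative"), function(tail) {
    (1 + sum(null_r[, tail] >= observed_r[[tail]])) / (1 + n_perm)
  }, numeric(1))
  structure(list(null_r = null_r,
                 observed = observed_r[c("positive", "negative")],
                 p_value = p, n_perm = n_perm),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d permutations\n  positive: r = %.3f, p = %.4f\n  negative: r = %.3f, p = %.4f\n",
    x$n_perm, x$observed[["positive"]], x$p_value[["positive"]],
    x$observed[["negative"]], x$p_value[["negative"]]))
  invisible(x)
}

#' Motion-confound control model
#'
#' Runs the identical CPM pipeline with per-subject mean framewise
#' displacement as the target phenotype. A significant motion model would
#' indicate that apparent phenotype predictions may ride on head motion.
#'
#' @inheritParams repeat_cv
#' @param mean_fd per-subject mean FD over retained frames (see
#'   [mean_fd_subject()])
#' @param n_perm permutations for the null (default 1000)
#' @return list with `result` (a `prediction_result`) and `null` (a
#'   `null_distribution`)
#' @export
motion_control_run <- function(edges, mean_fd, k, p_threshold = 0.01,
                               n_iterations = 50L, n_perm = 1000L,
                               master_seed = 1L) {
  res <- repeat_cv(edges, mean_fd, k, p_threshold, n_iterations, master_seed)
  nul <- permutation_null(edges, mean_fd, k, res$mean_r, p_threshold,
                          n_perm, master_seed + 1L)
  list(result = res, null = nul)
}

#' Group summary (n, mean, sd) for one measure
#'
#' @param n group size (>= 2)
#' @param mean group mean
#' @param sd group standard deviation (>= 0)
#' @return list of class `group_summary`
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Recomputes the two-sample t statistic from (n, mean, sd) triplets alone,
#' as needed to check published demographics tables. Sign convention:
#' mean(a) - mean(b). Pooled-variance by default; Welch via `welch = TRUE`.
#'
#' @param a,b `group_summary` objects (or lists with n, mean, sd)
#' @param welch use the Welch unequal-variance form (default FALSE)
#' @return list: `t`, `df`, `p` (two-sided)
#' @export
summary_ttest <- function(a, b, welch = FALSE) {
  stopifnot(a$n >= 2, b$n >= 2, a$sd >= 0, b$sd >= 0)
  diff <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0) {
    if (diff == 0) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    return(list(t = sign(diff) * Inf, df = a$n + b$n - 2, p = 0))
  }
  if (welch) {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
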