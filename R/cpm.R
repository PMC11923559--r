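#' Construct an edge mask
#'
#' @param tail "positive" or "negative"
#' @param indices 1-based positions into the canonical edge vector
#' @param p_threshold significance level that produced the mask
#' @param rho optional Spearman rho at the masked edges
#' @return object of class `edge_mask`
#' @export
edge_mask <- function(tail = c("positive", "negative"), indices = integer(0),
                      p_threshold = 0.01, rho = NULL) {
  tail <- match.arg(tail)
  structure(list(tail = tail, indices = as.integer(indices),
                 p_threshold = p_threshold, rho = rho),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %s tail: %d edges (p < %g)\n",
              x$tail, length(x$indices), x$p_threshold))
  invisible(x)
}

#' Select phenotype-associated edges on a training set
#'
#' Each edge's functional-connectivity values across training subjects are
#' rank-correlated (Spearman, average ranks for ties) with the target
#' phenotype. Two-sided p-values come from the t-distribution approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom. Edges with
#' rho > 0 and p below the threshold form the positive mask; rho < 0 the
#' negative mask; an edge can never sit in both. Edges constant across the
#' training subjects are excluded.
#'
#' @param train_edges n_train x n_edges matrix of edge vectors
#' @param train_targets phenotype vector, length n_train
#' @param p_threshold two-sided significance level (default 0.01)
#' @return list with elements `positive` and `negative`, each an `edge_mask`
#' @export
edge_select <- function(train_edges, train_targets, p_threshold = 0.01) {
  train_edges <- as.matrix(train_edges)
  n <- nrow(train_edges)
  stopifnot(length(train_targets) == n)
  if (n < 4) stop("need at least 4 training subjects for edge selection")
  if (length(unique(train_targets)) == 1) {
    stop("all training targets equal; Spearman correlation undefined")
  }
  rho <- spearman_rho_cols(train_edges, as.numeric(train_targets))
  ok <- !is.na(rho) & abs(rho) < 1
  tstat <- rep(NA_real_, length(rho))
  tstat[ok] <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  tstat[!is.na(rho) & abs(rho) >= 1] <- Inf * sign(rho[!is.na(rho) & abs(rho) >= 1])
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- !is.na(p) & p < p_threshold
  pos <- which(sig & rho > 0)
  neg <- which(sig & rho < 0)
  list(positive = edge_mask("positive", pos, p_threshold, rho[pos]),
       negative = edge_mask("negative", neg, p_threshold, rho[neg]))
}

#' Network strength: summed FC over a mask's edges
#'
#' @param edge_vector one subject's canonical edge vector, or an
#'   n_subjects x n_edges matrix (one strength per row)
#' @param mask an `edge_mask`
#' @return scalar (or vector, for a matrix input); 0 for an empty mask
#' @export
network_strength <- function(edge_vector, mask) {
  idx <- mask$indices
  if (is.matrix(edge_vector)) {
    if (length(idx) == 0) return(numeric(nrow(edge_vector)))
    if (max(idx) > ncol(edge_vector)) stop("mask index out of range")
    return(rowSums(edge_vector[, idx, drop = FALSE]))
  }
  if (length(idx) == 0) return(0)
  if (max(idx) > length(edge_vector)) stop("mask index out of range")
  sum(edge_vector[idx])
}

#' Fit the strength-to-phenotype OLS model for one tail
#'
#' Univariate ordinary least squares of the target on the masked network
#' strength. If the mask is empty or the training strengths are constant, the
#' model is flagged degenerate and predicts the training-target mean.
#'
#' @param train_edges n_train x n_edges matrix
#' @param train_targets phenotype vector
#' @param mask an `edge_mask` for one tail
#' @return object of class `cpm_model`
#' @export
fit_cpm <- function(train_edges, train_targets, mask) {
  strengths <- network_strength(as.matrix(train_edges), mask)
  fallback <- mean(train_targets)
  degenerate <- length(mask$indices) == 0 || stats::sd(strengths) == 0
  if (degenerate) {
    slope <- NA_real_; intercept <- NA_real_
  } else {
    fit <- stats::lm.fit(cbind(1, strengths), train_targets)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  structure(list(tail = mask$tail, mask = mask, slope = slope,
                 intercept = intercept, training_strengths = strengths,
                 training_targets = train_targets, fallback_mean = fallback,
                 degenerate = degenerate),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<cpm_model> %s tail: degenerate, predicts mean %.4g\n",
                x$tail, x$fallback_mean))
  } else {
    cat(sprintf("<cpm_model> %s tail: %d edges, slope %.4g, intercept %.4g\n",
                x$tail, length(x$mask$indices), x$slope, x$intercept))
  }
  invisible(x)
}

#' Predict a phenotype from a connectome edge vector
#'
#' @param model a fitted `cpm_model`
#' @param edge_vector one subject's edge vector, or an n x n_edges matrix
#' @return predicted scalar(s); a degenerate model returns its fallback mean
#' @export
predict_cpm <- function(model, edge_vector) {
  n_out <- if (is.matrix(edge_vector)) nrow(edge_vector) else 1L
  if (model$degenerate) return(rep(model$fallback_mean, n_out))
  model$intercept + model$slope * network_strength(edge_vector, model$mask)
}
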