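#' @useDynLib cpmr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm pt qt sd rnorm runif var coef
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

#' Remove high-motion frames from one run
#'
#' Frames whose framewise displacement (FD) strictly exceeds the threshold are
#' dropped; the surviving frames keep their order. A missing FD value (the
#' first frame in fMRIPrep-style confounds) is treated as 0 and never censored.
#'
#' @param run_signal frames x nodes numeric matrix
#' @param fd_vector per-frame FD in mm, length nrow(run_signal)
#' @param fd_threshold_mm censoring threshold (default 0.2 mm)
#' @param min_frames minimum surviving frames before the run is declared
#'   unusable (default 10)
#' @return the censored frames x nodes matrix, with attribute `n_censored`
#' @export
censor_frames <- function(run_signal, fd_vector, fd_threshold_mm = 0.2,
                          min_frames = 10L) {
  run_signal <- as.matrix(run_signal)
  stopifnot(length(fd_vector) == nrow(run_signal), fd_threshold_mm > 0)
  fd <- ifelse(is.na(fd_vector), 0, fd_vector)
  keep <- fd <= fd_threshold_mm
  if (sum(keep) < min_frames) {
    stop("insufficient data: only ", sum(keep), " of ", length(keep),
         " frames survive FD censoring at ", fd_threshold_mm, " mm")
  }
  out <- run_signal[keep, , drop = FALSE]
  attr(out, "n_censored") <- sum(!keep)
  out
}

#' Censor, demean, regress out the global signal, and concatenate runs
#'
#' For each run of a subject: the initial dummy (T1-stabilization) frames are
#' dropped, high-motion frames are censored, every node's series is demeaned
#' over the surviving frames of that run, and the run's global signal (the
#' unweighted mean across all nodes at each frame) is regressed out of every
#' node by least squares, keeping residuals. Runs are then concatenated along
#' the frame axis. Censoring precedes demeaning and the global-signal
#' regression so that spike frames cannot contaminate either regressor.
#'
#' @param subject a `subject_timeseries` object (see [subject_timeseries()])
#' @param drop_dummy number of initial frames to drop per run (default 4)
#' @param fd_threshold_mm FD censoring threshold in mm (default 0.2)
#' @param verbose log per-run censoring counts (default FALSE)
#' @return frames x nodes matrix of residual signal across all runs, with
#'   attributes `n_frames_used` and `n_censored`
#' @export
preprocess_and_concatenate <- function(subject, drop_dummy = 4L,
                                       fd_threshold_mm = 0.2,
                                       verbose = FALSE) {
  stopifnot(inherits(subject, "subject_timeseries"), length(subject$runs) >= 1)
  total_censored <- 0L
  pieces <- vector("list", length(subject$runs))
  for (r in seq_along(subject$runs)) {
    sig <- as.matrix(subject$runs[[r]])
    fd <- subject$fd[[r]]
    stopifnot(length(fd) == nrow(sig))
    if (ncol(sig) < 2) {
      stop("degenerate input: global-signal regression on a single node ",
           "would zero the data")
    }
    if (drop_dummy > 0) {
      if (nrow(sig) <= drop_dummy) stop("run ", r, " shorter than dummy count")
      sig <- sig[-seq_len(drop_dummy), , drop = FALSE]
      fd <- fd[-seq_len(drop_dummy)]
    }
    sig <- censor_frames(sig, fd, fd_threshold_mm)
    n_cens <- attr(sig, "n_censored")
    total_censored <- total_censored + n_cens
    if (verbose) {
      message(sprintf("subject %s run %d: censored %d frames (FD > %g mm)",
                      subject$subject_id, r, n_cens, fd_threshold_mm))
    }
    sig <- scale(sig, center = TRUE, scale = FALSE)   # demean per node, per run
    g <- rowMeans(sig)                                 # global signal
    denom <- sum(g * g)
    if (denom > 0) {
      beta <- drop(crossprod(sig, g)) / denom          # per-node slope on g
      sig <- sig - tcrossprod(g, beta)                 # residuals
    }
    pieces[[r]] <- sig
  }
  out <- do.call(rbind, pieces)
  attr(out, "n_frames_used") <- nrow(out)
  attr(out, "n_censored") <- total_censored
  out
}

#' Pairwise Pearson connectome from a concatenated signal
#'
#' @param concatenated_signal frames x nodes matrix (>= 3 frames)
#' @param subject_id optional id stored on the result
#' @return a `connectome` object: list(subject_id, matrix, n_frames_used)
#' @export
compute_connectome <- function(concatenated_signal, subject_id = NA_character_) {
  x <- as.matrix(concatenated_signal)
  if (nrow(x) < 3) stop("need at least 3 frames to correlate")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop("zero-variance node(s): ", paste(bad - 1L, collapse = ", "),
         " (0-based); cannot correlate")
  }
  m <- stats::cor(x)
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  structure(
    list(subject_id = subject_id, matrix = m,
         n_frames_used = nrow(x)),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s: %d x %d, %d frames\n",
              x$subject_id, nrow(x$matrix), ncol(x$matrix), x$n_frames_used))
  invisible(x)
}

#' Build one connectome per subject from raw time series
#'
#' Convenience wrapper: preprocess each subject and stack the canonical edge
#' vectors into a subjects x edges matrix, the input shape expected by the
#' model-fitting and evaluation functions.
#'
#' @param subjects list of `subject_timeseries`
#' @inheritParams preprocess_and_concatenate
#' @return list with `edges` (n_subjects x n_edges matrix, rownames = subject
#'   ids), `n_nodes`, and `mean_fd` (per-subject mean FD over retained frames)
#' @export
build_cohort_edges <- function(subjects, drop_dummy = 4L, fd_threshold_mm = 0.2,
                               verbose = FALSE) {
  stopifnot(length(subjects) >= 1)
  n_nodes <- ncol(subjects[[1]]$runs[[1]])
  edges <- matrix(NA_real_, length(subjects), n_edges(n_nodes))
  ids <- character(length(subjects))
  mean_fd <- numeric(length(subjects))
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    sig <- preprocess_and_concatenate(subj, drop_dummy, fd_threshold_mm,
                                      verbose = verbose)
    cn <- compute_connectome(sig, subj$subject_id)
    edges[s, ] <- to_edge_vector(cn$matrix)
    ids[s] <- subj$subject_id
    mean_fd[s] <- mean_fd_subject(subj, drop_dummy, fd_threshold_mm)
  }
  rownames(edges) <- ids
  names(mean_fd) <- ids
  list(edges = edges, n_nodes = n_nodes, mean_fd = mean_fd)
}

#' Per-subject mean framewise displacement over retained frames
#'
#' Mean FD across all frames of all runs that survive dummy-dropping and
#' censoring; NA FD (first frame) counts as 0.
#'
#' @param subject a `subject_timeseries`
#' @param drop_dummy dummy frames per run
#' @param fd_threshold_mm censoring threshold
#' @return scalar mean FD in mm
#' @export
mean_fd_subject <- function(subject, drop_dummy = 4L, fd_threshold_mm = 0.2) {
  vals <- unlist(lapply(subject$fd, function(fd) {
    fd <- ifelse(is.na(fd), 0, fd)
    if (drop_dummy > 0) fd <- fd[-seq_len(drop_dummy)]
    fd[fd <= fd_threshold_mm]
  }))
  mean(vals)
}

#' Construct a subject_timeseries object
#'
#' @param subject_id identifier
#' @param runs list of frames x nodes matrices (same node count across runs)
#' @param fd list of FD vectors aligned to runs (mm)
#' @param tr_seconds repetition time (default 3 s)
#' @return object of class `subject_timeseries`
#' @export
subject_timeseries <- function(subject_id, runs, fd, tr_seconds = 3) {
  stopifnot(length(runs) == length(fd), length(runs) >= 1)
  ncols <- vapply(runs, ncol, integer(1))
  if (length(unique(ncols)) != 1) stop("node count differs across runs")
  for (r in seq_along(runs)) {
    if (length(fd[[r]]) != nrow(runs[[r]])) {
      stop("FD length mismatch in run ", r)
    }
  }
  structure(list(subject_id = subject_id, runs = runs, fd = fd,
                 tr_seconds = tr_seconds),
            class = "subject_timeseries")
}
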