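#' Specification for a synthetic CPM cohort
#'
#' Defines the data-generating conditions for a simulated resting-state
#' cohort: a scalar phenotype per subject, and per-subject connectivity whose
#' planted edges are monotonically coupled to the phenotype. Defaults mirror
#' the acquisition emulated throughout the package: two 120-TR runs at
#' TR = 3 s with 4 initial T1-stabilization frames, on a 449-node
#' parcellation.
#'
#' @param n_subjects cohort size
#' @param n_nodes parcellation size (default 449)
#' @param n_runs resting-state runs per subject (default 2)
#' @param frames_per_run TRs per run, including dummy frames (default 120)
#' @param dummy_frames initial frames to discard per run (default 4)
#' @param tr_seconds repetition time (default 3)
#' @param phenotype_mean,phenotype_sd moments of the simulated phenotype
#' @param positive_edges,negative_edges data.frames with 0-based columns
#'   `i`, `j` (i < j): edges whose FC increases (resp. decreases) with the
#'   phenotype
#' @param effect_size change in target edge correlation per +1 SD of
#'   phenotype (default 0.3)
#' @param baseline_correlation within-network baseline FC (default 0.25);
#'   across-network baseline is 0
#' @param fd_spike_rate per-frame probability of a motion spike (default 0.05)
#' @param fd_spike_magnitude_mm FD of a spike frame, must exceed the 0.2 mm
#'   censoring threshold (default 0.6)
#' @param seed integer RNG seed; the whole cohort is reproducible from it
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects, n_nodes = 449L, n_runs = 2L,
                        frames_per_run = 120L, dummy_frames = 4L,
                        tr_seconds = 3, phenotype_mean = 0, phenotype_sd = 1,
                        positive_edges = NULL, negative_edges = NULL,
                        effect_size = 0.3, baseline_correlation = 0.25,
                        fd_spike_rate = 0.05, fd_spike_magnitude_mm = 0.6,
                        seed = 1L) {
  empty <- data.frame(i = integer(0), j = integer(0))
  if (is.null(positive_edges)) positive_edges <- empty
  if (is.null(negative_edges)) negative_edges <- empty
  positive_edges <- as.data.frame(positive_edges)
  negative_edges <- as.data.frame(negative_edges)
  for (e in list(positive_edges, negative_edges)) {
    if (nrow(e)) {
      stopifnot(all(e$i < e$j), all(e$i >= 0), all(e$j < n_nodes))
    }
  }
  key <- function(e) paste(e$i, e$j)
  if (length(intersect(key(positive_edges), key(negative_edges)))) {
    stop("positive and negative planted edge sets must be disjoint")
  }
  if (abs(baseline_correlation) + 2 * abs(effect_size) >= 1) {
    stop("|baseline_correlation| + 2*|effect_size| must be < 1")
  }
  stopifnot(frames_per_run > dummy_frames, n_subjects >= 1,
            fd_spike_magnitude_mm > 0.2, fd_spike_rate >= 0,
            fd_spike_rate <= 1, phenotype_sd > 0)
  structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_runs = as.integer(n_runs), frames_per_run = as.integer(frames_per_run),
    dummy_frames = as.integer(dummy_frames), tr_seconds = tr_seconds,
    phenotype_mean = phenotype_mean, phenotype_sd = phenotype_sd,
    positive_edges = positive_edges, negative_edges = negative_edges,
    effect_size = effect_size, baseline_correlation = baseline_correlation,
    fd_spike_rate = fd_spike_rate,
    fd_spike_magnitude_mm = fd_spike_magnitude_mm, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Sample disjoint random edge sets to plant in a synthetic cohort
#'
#' Candidate edges are drawn uniformly, subject to two structural guards:
#' each node may carry at most `degree_cap` planted edges, and a cycle in the
#' planted graph may only close once it spans at least `min_cycle` nodes.
#' Unrestricted random planting concentrates several strong
#' phenotype-coupled edges on hub nodes and creates short cycles with
#' inconsistent sign patterns; the edge values such configurations demand
#' for extreme phenotypes are not completable to a valid (positive
#' semidefinite) correlation matrix. A sparse union of paths and long
#' cycles, by contrast, admits essentially arbitrary planted values.
#'
#' @param n_nodes parcellation size
#' @param n_positive,n_negative edges per tail
#' @param seed RNG seed
#' @param degree_cap maximum planted edges per node (default 2)
#' @param min_cycle minimum planted-cycle length (default 8)
#' @return list with `positive` and `negative` data.frames (0-based i < j)
#' @export
plant_edges <- function(n_nodes, n_positive, n_negative, seed = 1L,
                        degree_cap = 2L, min_cycle = 8L) {
  total <- n_positive + n_negative
  if (total > n_edges(n_nodes)) stop("more planted edges than edges exist")
  if (total > n_nodes * degree_cap / 2) {
    stop("degree cap ", degree_cap, " admits at most ",
         floor(n_nodes * degree_cap / 2), " planted edges on ", n_nodes,
         " nodes")
  }
  pairs <- edge_pairs(n_nodes)
  keep <- withr_seed(seed, {
    ord <- sample.int(nrow(pairs))
    deg <- integer(n_nodes)
    parent <- seq_len(n_nodes)          # union-find over planted components
    csize <- rep(1L, n_nodes)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- integer(0)
    for (e in ord) {
      a <- pairs$i[e] + 1L; b <- pairs$j[e] + 1L
      if (deg[a] >= degree_cap || deg[b] >= degree_cap) next
      ra <- find(a); rb <- find(b)
      if (ra == rb && csize[ra] < min_cycle) next # short cycle: skip
      keep <- c(keep, e)
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      if (ra != rb) { parent[rb] <- ra; csize[ra] <- csize[ra] + csize[rb] }
      if (length(keep) == total) break
    }
    if (length(keep) < total) {
      # near the degree-cap capacity the greedy sampler can strand itself;
      # fall back to a random chain (path, or one long cycle when every
      # node must carry two edges), which satisfies both guards exactly
      if (total > n_nodes) stop("could not place all planted edges")
      perm <- sample.int(n_nodes) - 1L
      ii <- perm[seq_len(total)]
      jj <- perm[c(seq_len(total - 1L) + 1L, 1L)]
      if (total <= n_nodes - 1L) jj[total] <- perm[total + 1L]
      else if (total < min_cycle) stop("could not place all planted edges")
      keep <- sample(pair_to_edge_index(ii, jj, n_nodes))
    }
    keep
  })
  list(positive = pairs[keep[seq_len(n_positive)], , drop = FALSE],
       negative = pairs[keep[n_positive + seq_len(n_negative)], , drop = FALSE])
}

# run code under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Planted edge sets as canonical edge masks
#'
#' Returns the generator's ground truth in the same indexing the CPM engine
#' uses, for recovery scoring.
#'
#' @param spec a `cohort_spec`
#' @param n_nodes node count (defaults to the spec's)
#' @return list of `edge_mask` objects, elements `positive` and `negative`
#' @export
truth_mask <- function(spec, n_nodes = spec$n_nodes) {
  to_mask <- function(e, tail) {
    idx <- if (nrow(e)) pair_to_edge_index(e$i, e$j, n_nodes) else integer(0)
    edge_mask(tail, sort(idx), p_threshold = NA_real_)
  }
  list(positive = to_mask(spec$positive_edges, "positive"),
       negative = to_mask(spec$negative_edges, "negative"))
}

# Project an edited correlation matrix onto the valid (symmetric, unit
# diagonal, positive semidefinite) set by Higham-style alternating
# projections, holding the planted edge values fixed at each sweep. The
# final matrix is PSD and unit-diagonal; if it sits more than `max_move`
# away from any planted edge's requested value the spec is infeasible.
project_correlation <- function(target, planted_rc = NULL,
                                planted_vals = NULL, max_move = 0.05,
                                tol = 1e-8, maxit = 100L) {
  X <- target
  psd <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) >= -tol) return(M)
    M <- e$vectors %*% (pmax(e$values, tol) * t(e$vectors))
    (M + t(M)) / 2
  }
  impose <- function(M) {
    d <- sqrt(pmax(diag(M), .Machine$double.eps))
    M <- M / tcrossprod(d)
    diag(M) <- 1
    M[M > 1] <- 1; M[M < -1] <- -1
    if (!is.null(planted_rc)) {
      M[planted_rc] <- planted_vals
      M[planted_rc[, 2:1, drop = FALSE]] <- planted_vals
    }
    M
  }
  for (sweep in seq_len(maxit)) {
    Y <- psd(X)
    Z <- impose(Y)
    if (max(abs(Z - Y)) < tol) { X <- Z; break }
    X <- Z
  }
  out <- psd(X)
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  if (!is.null(planted_rc)) {
    moved <- abs(out[planted_rc] - planted_vals)
    if (any(moved > max_move)) {
      stop("infeasible cohort spec: PSD projection moved a planted edge by ",
           format(max(moved), digits = 3), " (> ", max_move, ")")
    }
  }
  out
}

#' Generate a synthetic cohort with planted edge-phenotype couplings
#'
#' The phenotype is drawn first; each subject's target correlation matrix is
#' the block baseline (within-network `baseline_correlation`, zero across
#' networks) plus, on every planted edge, `effect_size` times the subject's
#' standardized phenotype (sign-flipped for negative edges, clamped to
#' |r| <= 0.97). The target is projected to the nearest valid correlation
#' matrix if needed and frames are sampled as zero-mean multivariate normal
#' draws. Motion spikes are planted in the FD trace at `fd_spike_rate`; the
#' corresponding signal frames are corrupted with additive noise of 3x the
#' signal SD, so FD censoring measurably improves edge recovery.
#'
#' @param spec a `cohort_spec`
#' @param parcellation optional parcellation table; defaults to
#'   [default_parcellation()] for 449 nodes, else [synthetic_parcellation()]
#' @return object of class `synthetic_cohort`: list(subjects, phenotypes,
#'   truth, parcellation, target_matrices); the per-subject target
#'   correlation matrices are retained so recovery error can be scored
#'   against the ground truth
#' @export
generate_cohort <- function(spec, parcellation = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(parcellation)) {
    parcellation <- if (spec$n_nodes == 449L) default_parcellation()
                    else synthetic_parcellation(spec$n_nodes)
  }
  validate_parcellation(parcellation)
  stopifnot(nrow(parcellation) == spec$n_nodes)

  n <- spec$n_subjects
  nn <- spec$n_nodes
  withr_seed(spec$seed, {
    phenotypes <- stats::rnorm(n, spec$phenotype_mean, spec$phenotype_sd)
    z <- (phenotypes - spec$phenotype_mean) / spec$phenotype_sd

    net <- parcellation$network[order(parcellation$node_id)]
    base <- outer(net, net, "==") * spec$baseline_correlation
    diag(base) <- 1
    pos_idx <- if (nrow(spec$positive_edges)) {
      pair_to_edge_index(spec$positive_edges$i, spec$positive_edges$j, nn)
    } else integer(0)
    neg_idx <- if (nrow(spec$negative_edges)) {
      pair_to_edge_index(spec$negative_edges$i, spec$negative_edges$j, nn)
    } else integer(0)
    planted <- c(pos_idx, neg_idx)
    signs <- c(rep(1, length(pos_idx)), rep(-1, length(neg_idx)))
    base_edges <- to_edge_vector(base)
    all_pairs <- edge_pairs(nn)
    planted_rc <- if (length(planted)) {
      as.matrix(all_pairs[planted, , drop = FALSE]) + 1L
    } else NULL

    ids <- sprintf("sub-%03d", seq_len(n))
    subjects <- vector("list", n)
    targets_list <- vector("list", n)
    for (s in seq_len(n)) {
      ev <- base_edges
      planted_vals <- NULL
      if (length(planted)) {
        # coupling saturates at +-2 SD of phenotype, the range the spec
        # invariant |baseline +- 2*effect| < 1 is designed around
        zc <- max(min(z[s], 2), -2)
        planted_vals <- pmin(0.97, pmax(-0.97,
          ev[planted] + signs * spec$effect_size * zc))
        ev[planted] <- planted_vals
      }
      target <- from_edge_vector(ev, nn)
      target <- project_correlation(target, planted_rc, planted_vals)
      targets_list[[s]] <- target
      frames_total <- spec$n_runs * spec$frames_per_run
      sig <- MASS::mvrnorm(frames_total, mu = rep(0, nn), Sigma = target)
      runs <- vector("list", spec$n_runs)
      fds <- vector("list", spec$n_runs)
      for (r in seq_len(spec$n_runs)) {
        rows <- (r - 1L) * spec$frames_per_run + seq_len(spec$frames_per_run)
        run <- sig[rows, , drop = FALSE]
        colnames(run) <- parcellation$label
        fd <- stats::runif(spec$frames_per_run, 0.02, 0.15)
        spike <- stats::runif(spec$frames_per_run) < spec$fd_spike_rate
        spike[1] <- FALSE
        fd[spike] <- spec$fd_spike_magnitude_mm
        fd[1] <- NA_real_                      # fMRIPrep dialect: no FD at frame 1
        if (any(spike)) {
          nsp <- sum(spike)
          run[spike, ] <- run[spike, , drop = FALSE] +
            matrix(stats::rnorm(nsp * nn, sd = 3), nsp, nn)
        }
        runs[[r]] <- run
        fds[[r]] <- fd
      }
      subjects[[s]] <- subject_timeseries(ids[s], runs, fds, spec$tr_seconds)
    }
    names(phenotypes) <- ids
    names(targets_list) <- ids
    structure(list(subjects = subjects, phenotypes = phenotypes,
                   truth = spec, parcellation = parcellation,
                   target_matrices = targets_list),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d nodes, %d runs x %d frames\n",
    length(x$subjects), x$truth$n_nodes, x$truth$n_runs,
    x$truth$frames_per_run))
  invisible(x)
}

#' Write / read a cohort in the on-disk layout
#'
#' One tab-separated time-series file per subject-run (header = node labels),
#' one confounds TSV per run with a `framewise_displacement` column (first
#' frame "n/a", fMRIPrep dialect), `phenotypes.csv` (subject_id,value) and
#' `parcellation.csv`.
#'
#' @param cohort a `synthetic_cohort` (or compatible list)
#' @param dir output directory, created if needed
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    for (r in seq_along(subj$runs)) {
      ts_path <- file.path(dir, sprintf("%s_run-%d_timeseries.tsv",
                                        subj$subject_id, r))
      utils::write.table(subj$runs[[r]], ts_path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      cf_path <- file.path(dir, sprintf("%s_run-%d_confounds.tsv",
                                        subj$subject_id, r))
      cf <- data.frame(framewise_displacement = subj$fd[[r]])
      utils::write.table(cf, cf_path, sep = "\t", row.names = FALSE,
                         quote = FALSE, na = "n/a")
    }
  }
  utils::write.csv(
    data.frame(subject_id = names(cohort$phenotypes),
               value = unname(cohort$phenotypes)),
    file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @param tr_seconds repetition time recorded on the loaded subjects
#' @return for `read_cohort`: a list with `subjects`, `phenotypes`,
#'   `parcellation`
#' @export
read_cohort <- function(dir, tr_seconds = 3) {
  pheno <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                           stringsAsFactors = FALSE)
  parcellation <- read_parcellation(file.path(dir, "parcellation.csv"))
  subjects <- lapply(pheno$subject_id, function(id) {
    ts_files <- sort(list.files(dir, sprintf("^%s_run-\\d+_timeseries\\.tsv$", id),
                                full.names = TRUE))
    if (!length(ts_files)) return(NULL)
    runs <- lapply(ts_files, function(f) {
      as.matrix(utils::read.delim(f, check.names = FALSE))
    })
    fds <- lapply(ts_files, function(f) {
      cf <- utils::read.delim(sub("_timeseries\\.tsv$", "_confounds.tsv", f),
                              na.strings = c("", "n/a", "NA"))
      cf$framewise_displacement
    })
    subject_timeseries(id, runs, fds, tr_seconds)
  })
  found <- !vapply(subjects, is.null, logical(1))
  if (any(!found)) {
    warning("no time series for subject(s): ",
            paste(pheno$subject_id[!found], collapse = ", "),
            "; excluded")
  }
  phenotypes <- stats::setNames(pheno$value, pheno$subject_id)[found]
  list(subjects = subjects[found], phenotypes = phenotypes,
       parcellation = parcellation)
}
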