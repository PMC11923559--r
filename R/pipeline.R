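#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis in one validated object.
#' Exactly one of `cohort_dir` (on-disk layout, see [write_cohort()]),
#' `cohort` (in-memory cohort list) or `edges` (precomputed subjects x edges
#' matrix, with `phenotypes` and `parcellation` supplied alongside) must be
#' given.
#'
#' @param cohort_dir directory with time series, confounds, phenotypes and
#'   parcellation
#' @param cohort in-memory cohort (as from [generate_cohort()] /
#'   [read_cohort()])
#' @param edges precomputed n_subjects x n_edges matrix (rownames = ids)
#' @param phenotypes named phenotype vector (required with `edges`)
#' @param parcellation parcellation table (required with `edges`)
#' @param subgroup optional character vector of subject ids to keep
#'   (e.g. carriers only, or carriers without MCI)
#' @param fd_threshold_mm FD censoring threshold (default 0.2)
#' @param dummy_frames initial frames dropped per run (default 4)
#' @param p_threshold edge-selection significance level (default 0.01)
#' @param k number of cross-validation folds
#' @param n_iterations k-fold repetitions averaged (default 50)
#' @param n_perm permutations for the null (default 1000)
#' @param frequency_cutoff consensus-mask binarization cutoff (default 0.5)
#' @param master_seed seed governing folds, iterations, permutations
#' @param out_dir if non-NULL, artifacts are written here
#' @return object of class `run_config`
#' @export
run_config <- function(cohort_dir = NULL, cohort = NULL, edges = NULL,
                       phenotypes = NULL, parcellation = NULL,
                       subgroup = NULL, fd_threshold_mm = 0.2,
                       dummy_frames = 4L, p_threshold = 0.01, k = 8L,
                       n_iterations = 50L, n_perm = 1000L,
                       frequency_cutoff = 0.5, master_seed = 1L,
                       out_dir = NULL) {
  n_sources <- sum(!is.null(cohort_dir), !is.null(cohort), !is.null(edges))
  if (n_sources != 1) {
    stop("give exactly one of cohort_dir, cohort, edges")
  }
  if (!is.null(edges) && (is.null(phenotypes) || is.null(parcellation))) {
    stop("precomputed edges need phenotypes and parcellation")
  }
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    stop("cohort_dir does not exist: ", cohort_dir)
  }
  stopifnot(fd_threshold_mm > 0, p_threshold > 0, p_threshold < 1, k >= 2,
            n_iterations >= 1, n_perm >= 0, frequency_cutoff >= 0,
            frequency_cutoff <= 1)
  structure(list(cohort_dir = cohort_dir, cohort = cohort, edges = edges,
                 phenotypes = phenotypes, parcellation = parcellation,
                 subgroup = subgroup, fd_threshold_mm = fd_threshold_mm,
                 dummy_frames = as.integer(dummy_frames),
                 p_threshold = p_threshold, k = as.integer(k),
                 n_iterations = as.integer(n_iterations),
                 n_perm = as.integer(n_perm),
                 frequency_cutoff = frequency_cutoff,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

# resolve config inputs into (edges, phenotypes, parcellation, mean_fd)
resolve_inputs <- function(config) {
  if (!is.null(config$edges)) {
    return(list(edges = as.matrix(config$edges),
                phenotypes = config$phenotypes,
                parcellation = config$parcellation, mean_fd = NULL))
  }
  cohort <- if (!is.null(config$cohort)) config$cohort
            else read_cohort(config$cohort_dir)
  built <- build_cohort_edges(cohort$subjects,
                              drop_dummy = config$dummy_frames,
                              fd_threshold_mm = config$fd_threshold_mm)
  ids <- rownames(built$edges)
  missing_ts <- setdiff(names(cohort$phenotypes), ids)
  if (length(missing_ts)) {
    warning("phenotype without time series, excluded: ",
            paste(missing_ts, collapse = ", "))
  }
  keep <- intersect(names(cohort$phenotypes), ids)
  list(edges = built$edges[keep, , drop = FALSE],
       phenotypes = cohort$phenotypes[keep],
       parcellation = cohort$parcellation,
       mean_fd = built$mean_fd[keep])
}

#' Run the end-to-end CPM pipeline
#'
#' Connectome building (skipped for precomputed edge matrices), optional
#' subgroup filtering, iterated k-fold cross-validation, permutation null,
#' consensus masks, node degree and network aggregation — with every output
#' reproducible from the recorded configuration and master seed. Artifacts
#' (per-subject predictions, per-iteration accuracies, consensus edge lists,
#' degree and network-pair tables, results and provenance JSON) are written
#' to `config$out_dir` when set.
#'
#' @param config a `run_config`
#' @return result bundle: `result` (`prediction_result`), `null`
#'   (`null_distribution` or NULL when n_perm = 0), `consensus`, `degree`,
#'   `networks`, `subcortical` (per tail), `subject_ids`, `mean_fd`,
#'   `config` echo
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- resolve_inputs(config)
  edges <- inp$edges
  phenotypes <- inp$phenotypes
  if (!is.null(config$subgroup)) {
    keep <- intersect(rownames(edges), config$subgroup)
    edges <- edges[keep, , drop = FALSE]
    phenotypes <- phenotypes[keep]
    if (!is.null(inp$mean_fd)) inp$mean_fd <- inp$mean_fd[keep]
  }
  if (nrow(edges) < 4) {
    stop("fewer than 4 subjects after filtering; aborting")
  }
  n_nodes <- nrow(inp$parcellation)

  result <- repeat_cv(edges, phenotypes, config$k, config$p_threshold,
                      config$n_iterations, config$master_seed)
  nul <- if (config$n_perm > 0) {
    permutation_null(edges, phenotypes, config$k, result$mean_r,
                     config$p_threshold, config$n_perm,
                     config$master_seed + 1L)
  } else NULL

  tails <- c("positive", "negative")
  consensus <- lapply(stats::setNames(tails, tails), function(tail) {
    consensus_from_cv(result, tail, config$frequency_cutoff)
  })
  degree <- lapply(consensus, node_degree, n_nodes = n_nodes)
  networks <- lapply(consensus, aggregate_networks,
                     parcellation = inp$parcellation)
  subcort <- lapply(degree, subcortical_summary,
                    parcellation = inp$parcellation)

  bundle <- list(result = result, null = nul, consensus = consensus,
                 degree = degree, networks = networks, subcortical = subcort,
                 subject_ids = rownames(edges), mean_fd = inp$mean_fd,
                 parcellation = inp$parcellation, config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# write all pipeline artifacts plus a provenance record
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- bundle$result
  utils::write.csv(
    data.frame(subject_id = bundle$subject_ids, actual = res$actual,
               predicted_positive = res$predictions$positive,
               predicted_negative = res$predictions$negative),
    file.path(out_dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(iteration = seq_len(res$n_iterations),
               r_positive = res$per_iteration_r[, "positive"],
               r_negative = res$per_iteration_r[, "negative"]),
    file.path(out_dir, "iteration_r.csv"), row.names = FALSE)
  n_nodes <- nrow(bundle$parcellation)
  for (tail in names(bundle$consensus)) {
    cm <- bundle$consensus[[tail]]
    utils::write.csv(
      mask_edge_list(cm, n_nodes, bundle$parcellation),
      file.path(out_dir, sprintf("consensus_%s.csv", tail)),
      row.names = FALSE)
    utils::write.csv(bundle$networks[[tail]]$pair_counts,
                     file.path(out_dir, sprintf("network_pairs_%s.csv", tail)))
  }
  deg <- data.frame(node_id = bundle$parcellation$node_id,
                    label = bundle$parcellation$label,
                    degree_positive = bundle$degree$positive,
                    degree_negative = bundle$degree$negative)
  utils::write.csv(deg, file.path(out_dir, "degree.csv"), row.names = FALSE)
  cfg <- bundle$config
  results <- list(
    mean_r = as.list(res$mean_r),
    p_value = if (!is.null(bundle$null)) as.list(bundle$null$p_value) else NULL,
    n_subjects = length(bundle$subject_ids),
    n_iterations = res$n_iterations, k = res$k,
    n_degenerate_fold_models = res$n_degenerate)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  provenance <- list(
    package_version = as.character(utils::packageVersion("cpmr")),
    master_seed = cfg$master_seed, k = cfg$k,
    n_iterations = cfg$n_iterations, n_perm = cfg$n_perm,
    p_threshold = cfg$p_threshold, fd_threshold_mm = cfg$fd_threshold_mm,
    dummy_frames = cfg$dummy_frames,
    frequency_cutoff = cfg$frequency_cutoff,
    subgroup = cfg$subgroup, subject_ids = bundle$subject_ids,
    fold_sizes = as.integer(table(assign_folds(
      bundle$subject_ids, cfg$k,
      derive_seeds(cfg$master_seed, 1L)[1])$folds)))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Sweep the edge-selection threshold
#'
#' Re-runs the iterated cross-validation (and optionally the permutation
#' null) at each edge-selection p-value threshold and consolidates the
#' accuracies into one comparison table. Masks grow as the threshold
#' loosens; a robust effect shows stable accuracy across the sweep.
#'
#' @param config a `run_config` (its own p_threshold is ignored)
#' @param thresholds p-value thresholds to sweep (default 0.2, 0.1, 0.05,
#'   0.01)
#' @param with_null also run the permutation null at each threshold
#' @return data.frame: threshold, tail, mean_r, and p_value when requested
#' @export
threshold_sweep <- function(config, thresholds = c(0.2, 0.1, 0.05, 0.01),
                            with_null = FALSE) {
  stopifnot(inherits(config, "run_config"),
            all(thresholds > 0), all(thresholds < 1))
  inp <- resolve_inputs(config)
  edges <- inp$edges
  phenotypes <- inp$phenotypes
  if (!is.null(config$subgroup)) {
    keep <- intersect(rownames(edges), config$subgroup)
    edges <- edges[keep, , drop = FALSE]
    phenotypes <- phenotypes[keep]
  }
  rows <- lapply(thresholds, function(th) {
    res <- repeat_cv(edges, phenotypes, config$k, th, config$n_iterations,
                     config$master_seed)
    out <- data.frame(threshold = th, tail = c("positive", "negative"),
                      mean_r = unname(res$mean_r[c("positive", "negative")]))
    if (with_null) {
      nul <- permutation_null(edges, phenotypes, config$k, res$mean_r, th,
                              config$n_perm, config$master_seed + 1L)
      out$p_value <- unname(nul$p_value[c("positive", "negative")])
    }
    out
  })
  do.call(rbind, rows)
}
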