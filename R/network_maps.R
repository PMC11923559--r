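#' Consensus ("averaged") edge mask across fold-models
#'
#' Per-edge selection frequency over all fold-models (optionally across
#' iterations), binarized at a frequency cutoff for reporting graph
#' properties such as degree.
#'
#' @param fold_masks list of `edge_mask` objects, all the same tail
#' @param n_edges total number of edges in the edge vector
#' @param frequency_cutoff minimum selection frequency for the binary mask
#'   (default 0.5)
#' @return object of class `consensus_mask`: tail, `frequency` (per edge),
#'   `indices` (binary mask, 1-based edge positions), cutoff, n_models
#' @export
consensus_mask <- function(fold_masks, n_edges, frequency_cutoff = 0.5) {
  stopifnot(length(fold_masks) >= 1)
  tails <- unique(vapply(fold_masks, function(m) m$tail, character(1)))
  if (length(tails) != 1) stop("fold masks mix tails: ",
                               paste(tails, collapse = ", "))
  counts <- numeric(n_edges)
  for (m in fold_masks) counts[m$indices] <- counts[m$indices] + 1
  freq <- counts / length(fold_masks)
  structure(list(tail = tails, frequency = freq,
                 indices = which(freq >= frequency_cutoff),
                 frequency_cutoff = frequency_cutoff,
                 n_models = length(fold_masks)),
            class = "consensus_mask")
}

#' Consensus mask from an iterated cross-validation result
#'
#' Uses the selection counts accumulated by [repeat_cv()] over every
#' fold-model of every iteration.
#'
#' @param result a `prediction_result`
#' @param tail "positive" or "negative"
#' @inheritParams consensus_mask
#' @return a `consensus_mask`
#' @export
consensus_from_cv <- function(result, tail = c("positive", "negative"),
                              frequency_cutoff = 0.5) {
  tail <- match.arg(tail)
  freq <- result$selection[[tail]] / result$selection$n_models
  structure(list(tail = tail, frequency = freq,
                 indices = which(freq >= frequency_cutoff),
                 frequency_cutoff = frequency_cutoff,
                 n_models = result$selection$n_models),
            class = "consensus_mask")
}

#' @export
print.consensus_mask <- function(x, ...) {
  cat(sprintf(
    "<consensus_mask> %s tail: %d of %d edges at frequency >= %g (%d fold-models)\n",
    x$tail, length(x$indices), length(x$frequency), x$frequency_cutoff,
    x$n_models))
  invisible(x)
}

#' Node degree of a binary feature network
#'
#' Counts, for every node, the mask edges incident to it — the number of
#' selected connections a region contributes to the model (maximum
#' n_nodes - 1; 448 on the default parcellation). The degree sum always
#' equals twice the mask size.
#'
#' @param mask an `edge_mask` or `consensus_mask` (its binary `indices`), or
#'   a plain integer vector of 1-based edge positions
#' @param n_nodes node count
#' @return integer vector of length n_nodes (0-based node order)
#' @export
node_degree <- function(mask, n_nodes) {
  idx <- if (is.list(mask)) mask$indices else as.integer(mask)
  deg <- integer(n_nodes)
  if (length(idx)) {
    if (max(idx) > n_edges(n_nodes)) stop("edge index out of range")
    p <- edge_pairs(n_nodes)[idx, , drop = FALSE]
    tab <- tabulate(c(p$i, p$j) + 1L, nbins = n_nodes)
    deg <- as.integer(tab)
  }
  deg
}

#' Aggregate a binary mask and degrees over parcellation networks
#'
#' Builds the symmetric network-by-network matrix whose (A, B) entry counts
#' mask edges with one endpoint in network A and the other in B
#' (within-network pairs counted once), plus per-network mean and summed node
#' degree. Cerebellar nodes share the cortical network labels; subcortical
#' structures act as their own groups.
#'
#' @param mask as in [node_degree()]
#' @param parcellation parcellation table covering all nodes
#' @return list: `pair_counts` (network x network symmetric matrix),
#'   `degree_summary` (data.frame: network, n_nodes, mean_degree, sum_degree)
#' @export
aggregate_networks <- function(mask, parcellation) {
  validate_parcellation(parcellation)
  n_nodes <- nrow(parcellation)
  net <- parcellation$network[order(parcellation$node_id)]
  nets <- unique(net)
  idx <- if (is.list(mask)) mask$indices else as.integer(mask)
  cnt <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  if (length(idx)) {
    p <- edge_pairs(n_nodes)[idx, , drop = FALSE]
    a <- match(net[p$i + 1L], nets)
    b <- match(net[p$j + 1L], nets)
    lo <- pmin(a, b); hi <- pmax(a, b)
    for (e in seq_along(lo)) {
      cnt[lo[e], hi[e]] <- cnt[lo[e], hi[e]] + 1
    }
    cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  }
  deg <- node_degree(idx, n_nodes)
  ds <- data.frame(
    network = nets,
    n_nodes = as.integer(table(factor(net, levels = nets))),
    mean_degree = as.numeric(tapply(deg, factor(net, levels = nets), mean)),
    sum_degree = as.integer(tapply(deg, factor(net, levels = nets), sum)))
  rownames(ds) <- NULL
  list(pair_counts = cnt, degree_summary = ds)
}

#' Degree by subcortical structure
#'
#' Restricts a degree map to the subcortical nodes and groups it by
#' structure, for assessing which subcortical seeds carry model weight.
#'
#' @param degree integer degree vector in 0-based node order (from
#'   [node_degree()])
#' @param parcellation parcellation table with `anatomical_class`
#' @return data.frame: structure, hemisphere, node_id, label, degree;
#'   empty (0 rows) when the parcellation has no subcortex
#' @export
subcortical_summary <- function(degree, parcellation) {
  validate_parcellation(parcellation)
  stopifnot(length(degree) == nrow(parcellation))
  p <- parcellation[order(parcellation$node_id), ]
  sub <- p$anatomical_class == "subcortex"
  out <- data.frame(structure = p$network[sub], hemisphere = p$hemisphere[sub],
                    node_id = p$node_id[sub], label = p$label[sub],
                    degree = degree[sub])
  rownames(out) <- NULL
  out[order(out$structure, out$hemisphere), ]
}

#' Export a mask as an edge-list table
#'
#' @param mask `edge_mask` or `consensus_mask`
#' @param n_nodes node count
#' @param parcellation optional table to attach node labels
#' @return data.frame: node_i, node_j (0-based), tail, and frequency or rho
#'   where available
#' @export
mask_edge_list <- function(mask, n_nodes, parcellation = NULL) {
  idx <- mask$indices
  p <- edge_pairs(n_nodes)[idx, , drop = FALSE]
  out <- data.frame(node_i = p$i, node_j = p$j, tail = mask$tail)
  if (!is.null(mask$frequency)) out$frequency <- mask$frequency[idx]
  if (!is.null(mask$rho)) out$rho <- mask$rho
  if (!is.null(parcellation)) {
    lab <- parcellation$label[order(parcellation$node_id)]
    out$label_i <- lab[p$i + 1L]
    out$label_j <- lab[p$j + 1L]
  }
  rownames(out) <- NULL
  out
}
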