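yeo17_networks <- c(
  "VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA", "DorsAttnB",
  "SalVentAttnA", "SalVentAttnB", "LimbicA", "LimbicB", "ContA", "ContB",
  "ContC", "DefaultA", "DefaultB", "DefaultC", "TempPar")

subcortical_structures <- c(
  "HIP-ant", "HIP-post", "AMY-lat", "AMY-med", "THA-ant", "THA-post",
  "THA-dorsal", "THA-ventral", "NAc-shell", "NAc-core", "GP-ant", "GP-post",
  "PUT-ant", "PUT-post", "CAU-ant", "CAU-post")

#' Default 449-node parcellation table
#'
#' 400 cortical nodes (200 per hemisphere) distributed over the 17 canonical
#' cortical networks, 17 cerebellar nodes (one per network), and 32
#' subcortical nodes (16 structures per hemisphere). Node ids are 0-based and
#' contiguous; the `network` column carries the cortical network name for
#' cortex and cerebellum and the structure name for subcortex.
#'
#' @return data.frame with columns node_id, label, anatomical_class
#'   ("cortex"/"cerebellum"/"subcortex"), network, hemisphere
#' @export
default_parcellation <- function() {
  per_net <- table(rep(yeo17_networks, length.out = 200)) # ~12 nodes/network/hemi
  cortex <- do.call(rbind, lapply(c("LH", "RH"), function(h) {
    nets <- rep(yeo17_networks, times = per_net[yeo17_networks])
    data.frame(
      label = paste0(h, "_", nets, "_", sequence(per_net[yeo17_networks])),
      anatomical_class = "cortex", network = nets, hemisphere = h)
  }))
  cerebellum <- data.frame(
    label = paste0("Cereb_", yeo17_networks),
    anatomical_class = "cerebellum", network = yeo17_networks,
    hemisphere = "BI")
  subcortex <- do.call(rbind, lapply(c("LH", "RH"), function(h) {
    data.frame(label = paste0(h, "_", subcortical_structures),
               anatomical_class = "subcortex",
               network = subcortical_structures, hemisphere = h)
  }))
  out <- rbind(cortex, cerebellum, subcortex)
  out <- cbind(node_id = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  out
}

#' Synthetic reduced parcellation for small simulated cohorts
#'
#' Assigns `n_nodes` nodes in contiguous blocks to `n_networks` pseudo
#' networks; all nodes are marked cortical. Used by the cohort generator when
#' a full 449-node table is not wanted.
#'
#' @param n_nodes node count
#' @param n_networks number of network blocks (default: about one per 10
#'   nodes, between 2 and 17)
#' @return parcellation data.frame (same columns as [default_parcellation()])
#' @export
synthetic_parcellation <- function(n_nodes,
                                   n_networks = max(2L, min(17L, n_nodes %/% 10L))) {
  stopifnot(n_nodes >= 2, n_networks >= 1, n_networks <= n_nodes)
  nets <- paste0("Net", sort(rep_len(seq_len(n_networks), n_nodes)))
  data.frame(node_id = seq_len(n_nodes) - 1L,
             label = paste0("node", seq_len(n_nodes) - 1L),
             anatomical_class = "cortex", network = nets,
             hemisphere = "BI")
}

#' Validate and read/write a parcellation table
#'
#' @param parcellation data.frame to validate
#' @return the table, invisibly, after checking node ids are 0-based and
#'   contiguous and required columns exist
#' @export
validate_parcellation <- function(parcellation) {
  req <- c("node_id", "label", "anatomical_class", "network", "hemisphere")
  missing_cols <- setdiff(req, names(parcellation))
  if (length(missing_cols)) {
    stop("parcellation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- sort(parcellation$node_id)
  if (!identical(as.integer(ids), seq_len(nrow(parcellation)) - 1L)) {
    stop("node_id must be 0-based and contiguous")
  }
  if (anyNA(parcellation$network)) stop("node without network label")
  invisible(parcellation)
}

#' @rdname validate_parcellation
#' @param path CSV file path
#' @export
read_parcellation <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_parcellation(p)
  p
}

#' @rdname validate_parcellation
#' @export
write_parcellation <- function(parcellation, path) {
  validate_parcellation(parcellation)
  utils::write.csv(parcellation, path, row.names = FALSE)
  invisible(path)
}
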