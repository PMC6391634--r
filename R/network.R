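# Activity-cliff networks and cluster analysis.
#
# Nodes are cliff compounds, edges are cliffs; compounds not involved in any
# cliff are absent. Multi-node connected components (>2 nodes) are clusters
# of coordinated cliffs; 2-node components are isolated pairs. Comparing the
# sd-only network with the combined sd+isd network reveals which clusters
# the inactive analogs create (new) or enlarge (extended).

#' Build an activity-cliff network
#'
#' @param cliffs Cliff data.frame (from [call_sd_cliffs()],
#'   [call_isd_cliffs()] or a row-bound union), expected to originate from a
#'   single target set and MMP family. Duplicate edges per compound pair are
#'   collapsed (each edge represents one unique cliff).
#' @param set Optional [target_set()] providing node status and potency.
#' @param acrp Optional `acrp_result` used to flag ACRP nodes.
#' @return An `ac_network` object wrapping an igraph graph with node
#'   attributes `status`, `pki`, `acrp` and edge attributes `cliff_type`,
#'   `family`, `delta_pki`.
#' @export
build_network <- function(cliffs, set = NULL, acrp = NULL) {
  nodes <- unique(c(cliffs$compound_a, cliffs$compound_b))
  if (length(nodes) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g), class = "ac_network"))
  }
  ekey <- paste(pmin(cliffs$compound_a, cliffs$compound_b),
                pmax(cliffs$compound_a, cliffs$compound_b), sep = "\1")
  cliffs <- cliffs[!duplicated(ekey), , drop = FALSE]

  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(set)) {
    ai <- match(nodes, set$actives$compound_id)
    vert$status <- ifelse(is.na(ai), "inactive", "active")
    vert$pki <- set$actives$pki[ai]
  } else {
    vert$status <- ifelse(nodes %in%
      cliffs$other_partner[cliffs$cliff_type == "isd"], "inactive", "active")
    pk <- c(stats::setNames(cliffs$pki_a, cliffs$compound_a),
            stats::setNames(cliffs$pki_b, cliffs$compound_b))
    pk <- pk[!is.na(pk)]
    vert$pki <- unname(pk[nodes])
  }
  vert$acrp <- if (!is.null(acrp)) nodes %in% acrp$acrp_compound_ids else NA

  edges <- data.frame(from = cliffs$compound_a, to = cliffs$compound_b,
                      cliff_type = cliffs$cliff_type, family = cliffs$family,
                      delta_pki = cliffs$delta_pki, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  structure(list(graph = g), class = "ac_network")
}

#' @export
print.ac_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<ac_network> %d nodes, %d edges, %d components\n",
              igraph::vcount(g), igraph::ecount(g),
              igraph::components(g)$no))
  invisible(x)
}

network_components <- function(net) {
  igraph::components(net$graph)$membership
}

#' Identify clusters of coordinated cliffs
#'
#' Connected components of the cliff network. Components with more than two
#' nodes are clusters (coordinated, overlapping cliffs from one analog
#' series); 2-node components are isolated pairs.
#'
#' @param net An `ac_network`.
#' @return data.frame with one row per component: `cluster_id`, `n_nodes`,
#'   `n_edges`, `kind` (`"isolated_pair"` or `"cluster"`), `n_sd_edges`,
#'   `n_isd_edges`, `n_inactive_nodes`, `members` (semicolon-joined ids).
#' @export
find_clusters <- function(net) {
  stopifnot(inherits(net, "ac_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0L) {
    return(data.frame(cluster_id = integer(0), n_nodes = integer(0),
                      n_edges = integer(0), kind = character(0),
                      n_sd_edges = integer(0), n_isd_edges = integer(0),
                      n_inactive_nodes = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  memb <- network_components(net)
  names_v <- igraph::V(g)$name
  status <- igraph::V(g)$status
  etype <- igraph::E(g)$cliff_type
  eends <- igraph::ends(g, igraph::E(g), names = FALSE)
  ecomp <- memb[eends[, 1L]]
  ncomp <- max(memb)
  rows <- lapply(seq_len(ncomp), function(ci) {
    vs <- which(memb == ci)
    es <- which(ecomp == ci)
    data.frame(cluster_id = ci, n_nodes = length(vs), n_edges = length(es),
               kind = if (length(vs) > 2L) "cluster" else "isolated_pair",
               n_sd_edges = sum(etype[es] == "sd"),
               n_isd_edges = sum(etype[es] == "isd"),
               n_inactive_nodes = sum(status[vs] == "inactive"),
               members = paste(sort(names_v[vs]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare the sd-only network with the combined sd+isd network
#'
#' Classifies the combined network's multi-node components (>2 nodes):
#' "new" clusters contain no sd edge (created entirely by inactive analogs),
#' "extended" clusters strictly contain at least one sd component plus at
#' least one inactive node; components identical to an sd component are
#' unchanged. An extended cluster merging two or more sd components through
#' an inactive bridge is additionally flagged as merged.
#'
#' @param sd_net Network built from the sd cliffs alone.
#' @param combined_net Network built from the union of sd and isd cliffs.
#' @return An `ac_network_comparison`: counts plus a per-component table.
#' @export
compare_networks <- function(sd_net, combined_net) {
  stopifnot(inherits(sd_net, "ac_network"),
            inherits(combined_net, "ac_network"))
  gs <- sd_net$graph; gc <- combined_net$graph

  sd_edges <- apply(igraph::ends(gs, igraph::E(gs)), 1L,
                    function(e) paste(sort(e), collapse = "\1"))
  comb_edges <- apply(igraph::ends(gc, igraph::E(gc)), 1L,
                      function(e) paste(sort(e), collapse = "\1"))
  if (!all(sd_edges %in% comb_edges)) {
    stop("combined network is missing sd edges; it must be built from a superset of the sd cliffs",
         call. = FALSE)
  }

  memb_c <- if (igraph::vcount(gc) > 0L) network_components(combined_net)
            else integer(0)
  names_c <- igraph::V(gc)$name
  status_c <- igraph::V(gc)$status
  etype_c <- igraph::E(gc)$cliff_type
  ends_c <- if (igraph::ecount(gc) > 0L)
    igraph::ends(gc, igraph::E(gc), names = FALSE) else
    matrix(integer(0), ncol = 2L)

  # sd components as node-id sets
  sd_comp_sets <- list()
  if (igraph::vcount(gs) > 0L) {
    memb_s <- network_components(sd_net)
    names_s <- igraph::V(gs)$name
    sd_comp_sets <- split(names_s, memb_s)
  }

  ncomp <- if (length(memb_c) > 0L) max(memb_c) else 0L
  rows <- vector("list", ncomp)
  for (ci in seq_len(ncomp)) {
    vs <- names_c[memb_c == ci]
    es <- which(memb_c[ends_c[, 1L]] == ci)
    n_sd <- sum(etype_c[es] == "sd")
    n_isd <- sum(etype_c[es] == "isd")
    n_inact <- sum(status_c[memb_c == ci] == "inactive")
    contained <- vapply(sd_comp_sets, function(s) all(s %in% vs), logical(1))
    n_contained <- sum(contained)
    identical_to_sd <- n_contained == 1L &&
      setequal(vs, sd_comp_sets[[which(contained)]])
    class_ <- if (identical_to_sd) {
      "unchanged"
    } else if (length(vs) <= 2L) {
      "isolated_pair"
    } else if (n_sd == 0L) {
      "new_cluster"
    } else if (n_contained >= 1L && n_inact >= 1L) {
      if (n_contained >= 2L) "extended_cluster_merged" else
        "extended_cluster"
    } else {
      "extended_cluster"  # grown by sd-compound bridging without inactives
    }
    rows[[ci]] <- data.frame(
      component_id = ci, n_nodes = length(vs), n_edges = length(es),
      n_sd_edges = n_sd, n_isd_edges = n_isd,
      n_inactive_nodes = n_inact, n_sd_components = n_contained,
      classification = class_,
      members = paste(sort(vs), collapse = ";"), stringsAsFactors = FALSE)
  }
  per_comp <- if (ncomp > 0L) do.call(rbind, rows) else
    data.frame(component_id = integer(0), n_nodes = integer(0),
               n_edges = integer(0), n_sd_edges = integer(0),
               n_isd_edges = integer(0), n_inactive_nodes = integer(0),
               n_sd_components = integer(0), classification = character(0),
               members = character(0), stringsAsFactors = FALSE)
  structure(list(
    n_new_clusters = sum(per_comp$classification == "new_cluster"),
    n_extended_clusters = sum(per_comp$classification %in%
                                c("extended_cluster",
                                  "extended_cluster_merged")),
    n_merged_clusters = sum(per_comp$classification ==
                              "extended_cluster_merged"),
    n_unchanged_components = sum(per_comp$classification == "unchanged"),
    n_new_isolated_pairs = sum(per_comp$classification == "isolated_pair"),
    components = per_comp), class = "ac_network_comparison")
}

#' @export
print.ac_network_comparison <- function(x, ...) {
  cat(sprintf(
    "<ac_network_comparison> new clusters: %d; extended: %d (merged: %d); unchanged components: %d; new isolated pairs: %d\n",
    x$n_new_clusters, x$n_extended_clusters, x$n_merged_clusters,
    x$n_unchanged_components, x$n_new_isolated_pairs))
  invisible(x)
}

#' Export a cliff network for external viewers
#'
#' Writes `<prefix>_nodes.tsv` and `<prefix>_edges.tsv` (tab-separated node
#' and edge tables) plus `<prefix>.graphml` (GraphML, loadable by Cytoscape
#' and friends).
#'
#' @param net An `ac_network`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
export_graph <- function(net, prefix) {
  stopifnot(inherits(net, "ac_network"))
  g <- net$graph
  nodes <- data.frame(compound_id = as.character(igraph::V(g)$name %||%
                                                  character(0)),
                      status = igraph::V(g)$status %||% character(0),
                      pki = igraph::V(g)$pki %||% numeric(0),
                      acrp = igraph::V(g)$acrp %||% logical(0),
                      stringsAsFactors = FALSE)
  if (igraph::ecount(g) > 0L) {
    e <- igraph::ends(g, igraph::E(g))
    edges <- data.frame(from = e[, 1L], to = e[, 2L],
                        cliff_type = igraph::E(g)$cliff_type,
                        family = igraph::E(g)$family,
                        delta_pki = igraph::E(g)$delta_pki,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        cliff_type = character(0), family = character(0),
                        delta_pki = numeric(0), stringsAsFactors = FALSE)
  }
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  gml_path <- paste0(prefix, ".graphml")
  write_tsv_stable(nodes, node_path)
  write_tsv_stable(edges, edge_path)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(nodes = node_path, edges = edge_path, graphml = gml_path))
}

#' Rebuild a cliff network from exported node/edge tables
#'
#' @param prefix The prefix passed to [export_graph()].
#' @return An `ac_network`.
#' @export
import_graph_tables <- function(prefix) {
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, quote = "", comment.char = "",
                             stringsAsFactors = FALSE,
                             colClasses = c(compound_id = "character"))
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, quote = "", comment.char = "",
                             stringsAsFactors = FALSE,
                             colClasses = c(from = "character",
                                            to = "character"))
  if (nrow(nodes) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g), class = "ac_network"))
  }
  vert <- data.frame(name = nodes$compound_id, status = nodes$status,
                     pki = nodes$pki, acrp = nodes$acrp,
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  structure(list(graph = g), class = "ac_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic, locale-independent TSV writer (numbers via %.17g so values
# round-trip exactly; byte-stable output).
write_tsv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt_cell <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  }
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) {
    writeLines(header, con, useBytes = TRUE)
    return(invisible(path))
  }
  cols <- lapply(df, fmt_cell)
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}
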