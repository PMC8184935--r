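#' Define a node partition for a resting-state network set
#'
#' A node partition records, for each network node, whether it is a
#' higher-order network (multimodal/executive, e.g. default-mode or
#' fronto-parietal components), a unimodal sensory network, or other, and
#' whether it belongs to the consciousness-linked DMN / fronto-parietal
#' subset. The partition defines the edge subsets used by the angular and
#' transition analyses.
#'
#' @param nodes Character vector of unique node names; the order fixes the
#'   edge index.
#' @param classes Character vector, one of `"higher_order"`, `"sensory"`,
#'   `"other"` per node.
#' @param dmn_fp Logical vector; `TRUE` for DMN or fronto-parietal nodes.
#'   Every DMN/F-P node must be classed `higher_order`.
#' @return A `node_partition` data frame with columns `node`, `class`,
#'   `dmn_fp`.
#' @export
node_partition <- function(nodes, classes, dmn_fp) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (length(classes) != length(nodes) || length(dmn_fp) != length(nodes)) {
    stop("'classes' and 'dmn_fp' must have one entry per node")
  }
  ok <- classes %in% c("higher_order", "sensory", "other")
  if (!all(ok)) {
    stop("invalid node class for: ", paste(nodes[!ok], collapse = ", "))
  }
  dmn_fp <- as.logical(dmn_fp)
  if (anyNA(dmn_fp)) stop("'dmn_fp' must be TRUE/FALSE for every node")
  bad <- dmn_fp & classes != "higher_order"
  if (any(bad)) {
    stop("DMN/F-P nodes must be higher_order: ", paste(nodes[bad], collapse = ", "))
  }
  out <- data.frame(node = nodes, class = classes, dmn_fp = dmn_fp,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_partition", "data.frame")
  out
}

#' Default 14-node demonstration partition
#'
#' Seven higher-order nodes (anterior/posterior default-mode, executive
#' control, left/right fronto-parietal, dorsal attention, salience) and seven
#' non-higher-order nodes (auditory, somato-motor, striate / extrastriate /
#' ventral-stream visual, cerebellar, basal ganglia). Four nodes (aDMN, pDMN,
#' lFP, rFP) carry the DMN/F-P flag. With 14 nodes this yields 91 edges, of
#' which 70 touch a higher-order node and 46 touch a DMN/F-P node.
#'
#' @return A [node_partition()].
#' @export
default_partition <- function() {
  node_partition(
    nodes = c("aDMN", "pDMN", "ECN", "lFP", "rFP", "DAN", "SAL",
              "A", "SM", "sV", "esV", "vsV", "Cb", "BG"),
    classes = c(rep("higher_order", 7), rep("sensory", 5), rep("other", 2)),
    dmn_fp = c(TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 9))
  )
}

#' Edge index for a node set
#'
#' Edges are the unordered node pairs, ordered lexicographically by
#' (node index a, node index b) with a < b, fixed once per dataset so that
#' edge ids are reproducible across runs.
#'
#' @param partition A [node_partition()] or a character vector of node names.
#' @return Data frame with columns `edge_id`, `node_a`, `node_b`.
#' @export
edge_index <- function(partition) {
  nodes <- if (inherits(partition, "node_partition")) partition$node else as.character(partition)
  n <- length(nodes)
  if (n < 2) stop("need at least two nodes to form edges")
  pairs <- utils::combn(n, 2)
  data.frame(
    edge_id = paste(nodes[pairs[1, ]], nodes[pairs[2, ]], sep = "--"),
    node_a = nodes[pairs[1, ]],
    node_b = nodes[pairs[2, ]],
    stringsAsFactors = FALSE
  )
}

#' Select an edge subset by node class
#'
#' @param partition A [node_partition()].
#' @param mode `"all"` for every edge, `"higher_order"` for edges with at
#'   least one higher-order endpoint, `"dmn_fp"` for edges with at least one
#'   DMN/F-P endpoint.
#' @param index Optional precomputed [edge_index()]; defaults to the
#'   partition's own.
#' @return Character vector of edge ids.
#' @export
subset_edges <- function(partition, mode = c("all", "higher_order", "dmn_fp"),
                         index = edge_index(partition)) {
  mode <- match.arg(mode)
  if (mode == "all") return(index$edge_id)
  flagged <- switch(mode,
    higher_order = partition$node[partition$class == "higher_order"],
    dmn_fp = partition$node[partition$dmn_fp]
  )
  keep <- index$node_a %in% flagged | index$node_b %in% flagged
  index$edge_id[keep]
}

#' Write / read a node partition as JSON
#'
#' @param partition A [node_partition()].
#' @param path File path.
#' @return `read_partition` returns a [node_partition()];
#'   `write_partition` returns `path` invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "node_partition"))
  jsonlite::write_json(
    list(nodes = data.frame(name = partition$node, class = partition$class,
                            dmn_fp = partition$dmn_fp)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  if (is.null(nodes) || !all(c("name", "class", "dmn_fp") %in% names(nodes))) {
    stop("not a node-partition JSON file: ", path)
  }
  node_partition(nodes$name, nodes$class, nodes$dmn_fp)
}
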