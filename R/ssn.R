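# Sequence similarity networks: thresholded graph construction, exact
# centralities, centrality-guided threshold selection, annotation and
# Cytoscape-compatible export (GraphML and XGMML).

#' Build a thresholded SSN from an edge list
#'
#' Retains edges with \code{AS >= threshold}, computes connected components
#' and numbers clusters deterministically: by decreasing size, ties broken
#' by the lexicographically smallest member id.  Nodes named in
#' \code{nodeIds} but absent from retained edges appear as singletons, so a
#' threshold above the maximum AS yields all-singleton graphs.
#'
#' @param edges data.frame with columns \code{id_a}, \code{id_b}, \code{AS}
#'   (e.g. from \code{\link{allVsAll}}).
#' @param threshold AS threshold (>= 0 in normal use).
#' @param nodeIds optional character vector of all node ids; defaults to
#'   the ids present in \code{edges}.
#' @return an \linkS4class{SSNGraph}
#' @examples
#' e <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"), AS = c(5, 1))
#' ssnClusters(buildSSN(e, threshold = 2))
#' @export
buildSSN <- function(edges, threshold, nodeIds = NULL) {
  stopifnotScalarNumber(threshold, "threshold")
  if (is.null(nodeIds))
    nodeIds <- union(edges$id_a, edges$id_b)
  nodeIds <- sort(unique(as.character(nodeIds)))
  keep <- edges$AS >= threshold
  kept <- edges[keep, c("id_a", "id_b", "AS"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept, directed = FALSE,
    vertices = data.frame(name = nodeIds, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  # deterministic cluster numbering: size desc, then smallest member id
  minId <- vapply(seq_len(comp$no), function(i)
    min(nodeIds[comp$membership == i]), character(1))
  ord <- order(-comp$csize, minId)
  renum <- integer(comp$no)
  renum[ord] <- seq_len(comp$no)
  cluster <- renum[comp$membership]
  nd <- S4Vectors::DataFrame(id = nodeIds, cluster = cluster)
  new("SSNGraph", graph = g, threshold = as.numeric(threshold),
      nodeData = nd)
}

#' Exact per-node centralities of an SSN
#'
#' Degree, betweenness (unnormalised shortest-path pair counts), closeness
#' (within-component) and eigenvector centrality, computed exactly — no
#' sampling — for graphs of up to about 1e4 nodes.
#'
#' @param x an \linkS4class{SSNGraph}
#' @return data.frame with columns \code{id}, \code{degree},
#'   \code{betweenness}, \code{closeness}, \code{eigenvector}.
#' @export
centralityProfile <- function(x) {
  stopifnot(is(x, "SSNGraph"))
  g <- x@graph
  if (igraph::vcount(g) == 0L) stop("graph is empty", call. = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  deg <- igraph::degree(g)
  cls <- suppressWarnings(igraph::closeness(g, normalized = FALSE))
  eig <- if (igraph::ecount(g) > 0L)
    igraph::eigen_centrality(g)$vector
  else rep(0, igraph::vcount(g))
  data.frame(id = igraph::V(g)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(cls),
             eigenvector = as.numeric(eig), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Sweep AS thresholds and select one by network centrality
#'
#' For each grid threshold the SSN is rebuilt and summarised (cluster
#' count, singletons, mean degree, mean unnormalised betweenness).  The
#' default strategy finds the maximal plateaus of the cluster count (runs
#' of at least three grid points with an unchanged number of clusters) and
#' keeps those at whose first point the mean betweenness has collapsed
#' below \code{collapseFraction} of its maximum over the sweep before the
#' plateau (exactly zero when betweenness never rose earlier).  The
#' selected threshold is the smallest grid point of the last such plateau:
#' the rise and collapse of betweenness marks where inter-cluster bridges
#' thin out and disappear, and the plateau after the final collapse is the
#' stable clustering.  In sweeps where betweenness never rises (families
#' already separated, or a single clique) the first plateau — the grid
#' minimum — wins.  When the graph at the grid minimum has no edges the
#' sweep is degenerate and no threshold is selected; when no plateau
#' qualifies the sweep is returned with \code{selected = NA} and a warning
#' status.
#'
#' @param edges data.frame edge list (id_a, id_b, AS).
#' @param grid strictly increasing numeric vector of at least 3 thresholds.
#' @param strategy \code{"auto"} (plateau + betweenness collapse) or
#'   \code{"manual"} (take \code{manualThreshold}).
#' @param collapseFraction betweenness collapse fraction (default 0.1).
#' @param manualThreshold threshold used when \code{strategy = "manual"}.
#' @param nodeIds optional full node id set (passed to
#'   \code{\link{buildSSN}}).
#' @return a \linkS4class{ThresholdSweep}
#' @export
selectThreshold <- function(edges, grid, strategy = c("auto", "manual"),
                            collapseFraction = 0.1, manualThreshold = NULL,
                            nodeIds = NULL) {
  strategy <- match.arg(strategy)
  grid <- as.numeric(grid)
  if (length(grid) < 3L || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing with >= 3 points",
         call. = FALSE)

  rows <- lapply(grid, function(th) {
    g <- buildSSN(edges, th, nodeIds = nodeIds)
    cl <- g@nodeData$cluster
    btw <- igraph::betweenness(g@graph, directed = FALSE,
                               normalized = FALSE)
    data.frame(threshold = th, n_clusters = max(c(cl, 0L)),
               n_singletons = sum(tabulate(cl) == 1L),
               mean_degree = mean(igraph::degree(g@graph)),
               mean_betweenness = mean(btw))
  })
  tab <- do.call(rbind, rows)

  if (strategy == "manual") {
    if (is.null(manualThreshold))
      stop("manual strategy needs 'manualThreshold'", call. = FALSE)
    return(new("ThresholdSweep", table = tab,
               selected = as.numeric(manualThreshold), status = "manual"))
  }

  if (tab$mean_degree[1L] == 0)
    return(new("ThresholdSweep", table = tab, selected = NA_real_,
               status = "degenerate"))

  # plateau: grid point lies in a run of identical cluster counts whose
  # length is >= 3 (i.e. the count is unchanged over >= 2 grid steps)
  r <- rle(tab$n_clusters)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  btw <- tab$mean_betweenness
  qualifying <- integer(0)
  for (p in which(r$lengths >= 3L)) {
    s <- starts[p]
    before <- if (s > 1L) max(btw[seq_len(s - 1L)]) else 0
    collapsed <- if (before > 0) btw[s] <= collapseFraction * before
    else btw[s] == 0
    if (collapsed) qualifying <- c(qualifying, s)
  }
  if (!length(qualifying)) {
    warning("no threshold satisfied the plateau + collapse criterion")
    return(new("ThresholdSweep", table = tab, selected = NA_real_,
               status = "no-plateau"))
  }
  new("ThresholdSweep", table = tab,
      selected = grid[qualifying[length(qualifying)]], status = "ok")
}

# simple deterministic qualitative palette (Okabe-Ito, recycled)
#' @noRd
classPalette <- function(classes) {
  pal <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
           "#D55E00", "#CC79A7", "#999999")
  setNames(rep(pal, length.out = length(classes)), classes)
}

#' Annotate an SSN and export it for Cytoscape
#'
#' Attaches a colour class per node from a metadata table — by taxonomy or
#' by genome-context pathway label — and writes GraphML and/or XGMML.
#' Unannotated nodes get the label \code{"unannotated"}.  The XGMML writer
#' round-trips losslessly through \code{\link{readXGMML}}.
#'
#' @param x an \linkS4class{SSNGraph}.
#' @param metadata data.frame with column \code{id} plus \code{taxonomy}
#'   and/or \code{context}; ids must be unique.
#' @param scheme \code{"taxonomy"} or \code{"pathway-context"}.
#' @param path output file path without extension.
#' @param formats subset of \code{c("graphml", "xgmml")}.
#' @return named character vector of written files, invisibly.
#' @export
annotateAndExport <- function(x, metadata, scheme = c("taxonomy",
                                                      "pathway-context"),
                              path, formats = c("graphml", "xgmml")) {
  stopifnot(is(x, "SSNGraph"))
  scheme <- match.arg(scheme)
  formats <- match.arg(formats, several.ok = TRUE)
  if (anyDuplicated(metadata$id))
    stop("metadata id collisions", call. = FALSE)
  col <- if (scheme == "taxonomy") "taxonomy" else "context"
  if (!col %in% names(metadata))
    stop("metadata lacks column '", col, "'", call. = FALSE)
  ids <- igraph::V(x@graph)$name
  lab <- metadata[[col]][match(ids, metadata$id)]
  lab[is.na(lab)] <- "unannotated"
  pal <- classPalette(sort(unique(lab)))
  g <- igraph::set_vertex_attr(x@graph, "label", value = lab)
  g <- igraph::set_vertex_attr(g, "colorClass", value = lab)
  g <- igraph::set_vertex_attr(g, "fillColor", value = unname(pal[lab]))
  g <- igraph::set_vertex_attr(g, "cluster",
                               value = x@nodeData$cluster)
  out <- character(0)
  if ("graphml" %in% formats) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(g, f, format = "graphml")
    out["graphml"] <- f
  }
  if ("xgmml" %in% formats) {
    f <- paste0(path, ".xgmml")
    writeXGMML(g, f, label = basename(path))
    out["xgmml"] <- f
  }
  invisible(out)
}

# Cytoscape-dialect XGMML writer for an igraph object with character or
# numeric vertex attributes and an AS edge attribute.
#' @noRd
writeXGMML <- function(g, path, label = "ssn") {
  doc <- xml2::xml_new_root(
    "graph", label = label, directed = "0",
    xmlns = "http://www.cs.rpi.edu/XGMML")
  ids <- igraph::V(g)$name
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  for (i in seq_along(ids)) {
    nd <- xml2::xml_add_child(doc, "node", id = as.character(i),
                              label = ids[i])
    for (a in vattrs) {
      v <- igraph::vertex_attr(g, a)[[i]]
      xml2::xml_add_child(nd, "att", name = a,
                          type = if (is.numeric(v)) "real" else "string",
                          value = as.character(v))
    }
  }
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_data_frame(g, what = "edges")
    for (k in seq_len(nrow(el))) {
      ed <- xml2::xml_add_child(
        doc, "edge",
        source = as.character(match(el$from[k], ids)),
        target = as.character(match(el$to[k], ids)),
        label = paste0(el$from[k], "--", el$to[k]))
      for (a in setdiff(names(el), c("from", "to")))
        xml2::xml_add_child(ed, "att", name = a,
                            type = if (is.numeric(el[[a]])) "real"
                            else "string",
                            value = as.character(el[[a]][k]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an XGMML network written by \code{annotateAndExport}
#'
#' @param path XGMML file.
#' @return an \pkg{igraph} graph with the stored node/edge attributes.
#' @export
readXGMML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(x = "http://www.cs.rpi.edu/XGMML")
  nodes <- xml2::xml_find_all(doc, ".//x:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  labels <- xml2::xml_attr(nodes, "label")
  vdf <- data.frame(name = labels, stringsAsFactors = FALSE)
  for (nd in seq_along(nodes)) {
    atts <- xml2::xml_find_all(nodes[[nd]], "./x:att", ns)
    for (a in atts) {
      nm <- xml2::xml_attr(a, "name")
      val <- xml2::xml_attr(a, "value")
      if (identical(xml2::xml_attr(a, "type"), "real"))
        val <- as.numeric(val)
      if (is.null(vdf[[nm]]))
        vdf[[nm]] <- if (is.numeric(val)) NA_real_ else NA_character_
      vdf[[nm]][nd] <- val
    }
  }
  edges <- xml2::xml_find_all(doc, ".//x:edge", ns)
  if (length(edges)) {
    edf <- data.frame(
      from = labels[match(xml2::xml_attr(edges, "source"), ids)],
      to = labels[match(xml2::xml_attr(edges, "target"), ids)],
      stringsAsFactors = FALSE)
    for (ed in seq_along(edges)) {
      atts <- xml2::xml_find_all(edges[[ed]], "./x:att", ns)
      for (a in atts) {
        nm <- xml2::xml_attr(a, "name")
        val <- xml2::xml_attr(a, "value")
        if (identical(xml2::xml_attr(a, "type"), "real"))
          val <- as.numeric(val)
        if (is.null(edf[[nm]]))
          edf[[nm]] <- if (is.numeric(val)) NA_real_ else NA_character_
        edf[[nm]][ed] <- val
      }
    }
  } else {
    edf <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}
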