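# Undirected simple molecular graphs and the two structural operators that
# the entropy pipeline composes: subdivision S(.) and line graph L(.).
# Graphs are igraph objects with stable character vertex names; operators
# return new graphs and never modify their input.

#' Construct a molecular graph
#'
#' Builds an undirected simple graph from an edge list.  Vertex identifiers
#' are arbitrary character strings; they are kept verbatim so that derived
#' vertices (subdivision points, line-graph vertices) can be traced back to
#' their source.
#'
#' @param edges two-column matrix or data frame of vertex identifiers, one
#'   edge per row.  Coerced to character.
#' @param vertices optional character vector of vertex identifiers; must
#'   contain every endpoint.  Use it to declare isolated vertices.
#' @return an undirected simple `igraph` object with named vertices.
#' @examples
#' benzene <- molecular_graph(cbind(1:6, c(2:6, 1)))
#' igraph::ecount(benzene)
#' @export
molecular_graph <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns", call. = FALSE)
  }
  mode(edges) <- "character"
  if (anyNA(edges) || any(edges == "")) {
    stop("edge endpoints must be non-missing, non-empty identifiers",
         call. = FALSE)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed in a molecular graph", call. = FALSE)
  }
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  if (anyDuplicated(paste0(lo, "\r", hi))) {
    stop("parallel edges are not allowed in a molecular graph", call. = FALSE)
  }
  ids <- unique(c(lo, hi))
  if (!is.null(vertices)) {
    vertices <- as.character(vertices)
    if (anyDuplicated(vertices)) {
      stop("duplicated vertex identifiers", call. = FALSE)
    }
    if (!all(ids %in% vertices)) {
      stop("every edge endpoint must be a declared vertex", call. = FALSE)
    }
    ids <- vertices
  }
  igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
}

#' Validate (and normalise) a molecular graph
#'
#' Checks that `g` is an undirected simple igraph object and that its
#' vertices carry names; unnamed vertices are given their index as a name.
#'
#' @param g an `igraph` object.
#' @return the validated graph.
#' @export
as_molecular_graph <- function(g) {
  if (!igraph::is_igraph(g)) {
    stop("`g` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(g)) {
    stop("molecular graphs are undirected", call. = FALSE)
  }
  if (!igraph::is_simple(g)) {
    stop("molecular graphs are simple: no loops or parallel edges",
         call. = FALSE)
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Vertex degrees
#'
#' @param g a molecular graph.
#' @param v optional vector of vertex names; defaults to all vertices.
#' @return named integer vector of degrees.
#' @export
vertex_degrees <- function(g, v = NULL) {
  g <- as_molecular_graph(g)
  if (is.null(v)) {
    return(igraph::degree(g))
  }
  v <- as.character(v)
  missing <- setdiff(v, igraph::V(g)$name)
  if (length(missing)) {
    stop("unknown vertex identifier(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  igraph::degree(g, v = v)
}

#' Neighbour degree sums
#'
#' For each vertex, the sum of the degrees of its neighbours.  This is the
#' vertex label used by the ABC4 and GA5 weight schemes.
#'
#' @inheritParams vertex_degrees
#' @return named numeric vector of neighbour degree sums.
#' @examples
#' c12 <- molecular_graph(cbind(1:12, c(2:12, 1)))
#' unique(neighbor_degree_sum(c12))  # 4: two neighbours of degree 2
#' @export
neighbor_degree_sum <- function(g, v = NULL) {
  g <- as_molecular_graph(g)
  deg <- igraph::degree(g)
  nds <- vapply(
    igraph::adjacent_vertices(g, igraph::V(g)),
    function(nb) sum(deg[nb]),
    numeric(1)
  )
  names(nds) <- igraph::V(g)$name
  if (is.null(v)) {
    return(nds)
  }
  v <- as.character(v)
  missing <- setdiff(v, names(nds))
  if (length(missing)) {
    stop("unknown vertex identifier(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nds[v]
}

# canonical low/high endpoint labels for every edge of g
.edge_ends_canonical <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(e) == 0L) {
    return(cbind(lo = character(), hi = character()))
  }
  cbind(lo = pmin(e[, 1L], e[, 2L]), hi = pmax(e[, 1L], e[, 2L]))
}

#' Subdivision graph S(G)
#'
#' Replaces every edge of `g` by a path of length two.  The inserted vertex
#' for edge \{u, v\} is named `"s:u|v"` with the endpoints in canonical
#' (lexicographic) order, so the output is reproducible across runs.
#'
#' @param g a molecular graph.
#' @return the subdivision graph, with `|V(g)| + |E(g)|` vertices and
#'   `2 |E(g)|` edges.
#' @examples
#' c6 <- molecular_graph(cbind(1:6, c(2:6, 1)))
#' igraph::vcount(subdivision(c6))  # C12
#' @export
subdivision <- function(g) {
  g <- as_molecular_graph(g)
  ends <- .edge_ends_canonical(g)
  if (nrow(ends) == 0L) {
    return(g)
  }
  sv <- sprintf("s:%s|%s", ends[, "lo"], ends[, "hi"])
  molecular_graph(
    rbind(cbind(ends[, "lo"], sv), cbind(sv, ends[, "hi"])),
    vertices = c(igraph::V(g)$name, sv)
  )
}

#' Line graph L(G)
#'
#' The vertices of the line graph are the edges of `g`; two of them are
#' adjacent iff the corresponding edges share an endpoint.  Line-graph
#' vertices are named `"u~v"` (canonical endpoint order) and additionally
#' carry the vertex attributes `src_lo` and `src_hi`, exposing the
#' bijection with the edges of `g`.
#'
#' @param g a molecular graph.
#' @return the line graph of `g`.
#' @examples
#' k3 <- molecular_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' igraph::ecount(line_graph(k3))  # K3 is self-dual: 3 edges
#' @export
line_graph <- function(g) {
  g <- as_molecular_graph(g)
  lg <- igraph::make_line_graph(g)
  ends <- .edge_ends_canonical(g)
  if (nrow(ends) > 0L) {
    igraph::V(lg)$name <- sprintf("%s~%s", ends[, "lo"], ends[, "hi"])
    igraph::V(lg)$src_lo <- ends[, "lo"]
    igraph::V(lg)$src_hi <- ends[, "hi"]
  }
  lg
}

#' Line graph of the subdivision graph
#'
#' Convenience composition `line_graph(subdivision(g))`, the graph all
#' published partition tables refer to.
#'
#' @param g a molecular graph.
#' @return `L(S(g))`.
#' @export
line_of_subdivision <- function(g) {
  line_graph(subdivision(g))
}

#' Read / write an edge-list file
#'
#' Plain-text edge list: one edge per line, two whitespace-separated vertex
#' tokens; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return `read_edgelist()` returns a molecular graph.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(molecular_graph(matrix(character(), ncol = 2L)))
  }
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop("malformed edge-list line(s): ",
         paste(utils::head(lines[bad], 3L), collapse = "; "), call. = FALSE)
  }
  molecular_graph(do.call(rbind, toks))
}

#' @rdname read_edgelist
#' @param g a molecular graph.
#' @export
write_edgelist <- function(g, path) {
  g <- as_molecular_graph(g)
  ends <- .edge_ends_canonical(g)
  ord <- order(ends[, "lo"], ends[, "hi"])
  writeLines(paste(ends[ord, "lo"], ends[ord, "hi"], sep = "\t"), path)
  invisible(path)
}

#' Read / write GraphML
#'
#' Thin wrappers over igraph's GraphML support, validating the result as a
#' molecular graph on the way in.
#'
#' @param path file path.
#' @return `read_graphml()` returns a molecular graph.
#' @export
read_graphml <- function(path) {
  as_molecular_graph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname read_graphml
#' @param g a molecular graph.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_molecular_graph(g), path, format = "graphml")
  invisible(path)
}
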