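#' Undirected simple network
#'
#' `elpa_network` is the package's immutable graph container: an undirected,
#' unweighted simple graph (no self-loops, no parallel edges) with opaque
#' vertex ids. Vertices carry a canonical total order -- numeric when every id
#' parses as an integer, lexicographic otherwise -- which fixes every
#' tie-break in the propagation so that results are deterministic.
#'
#' @param edges a two-column matrix or data frame of endpoint ids (coerced to
#'   character), one edge per row.
#' @param sort_vertices if `TRUE`, store vertices in canonical order instead
#'   of order of first appearance.
#' @return An object of class `elpa_network` with components `vertices`
#'   (character ids), `edges` (m x 2 integer matrix of vertex indices, rows in
#'   canonical order), `n`, `m`, `adj` (neighbor index lists) and `adj_eid`
#'   (parallel edge-id lists).
#' @examples
#' net <- elpa_network(cbind(c(1, 2, 1), c(2, 3, 3)))
#' net$n; net$m
#' @export
elpa_network <- function(edges, sort_vertices = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("'edges' needs two endpoint columns")
  ea <- as.character(edges[, 1L])
  eb <- as.character(edges[, 2L])
  if (any(ea == eb)) {
    bad <- which(ea == eb)[1L]
    stop(sprintf("self-loop at edge %d (vertex '%s'): only simple graphs are supported",
                 bad, ea[bad]))
  }
  verts <- unique(c(rbind(ea, eb)))   # first-appearance order
  if (sort_vertices) verts <- verts[canonical_rank(verts)]
  i <- match(ea, verts)
  j <- match(eb, verts)
  crank <- canonical_rank(verts)
  # canonical endpoint order within each edge, then canonical row order
  swap <- crank[i] > crank[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  dup <- duplicated(cbind(i, j))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    i <- i[!dup]; j <- j[!dup]
  }
  o <- order(crank[i], crank[j])
  i <- i[o]; j <- j[o]
  build_network(verts, cbind(i = i, j = j), crank)
}

# assemble the container from validated pieces
build_network <- function(verts, eidx, crank) {
  n <- length(verts)
  m <- nrow(eidx)
  adj <- rep(list(integer(0)), n)
  adj_eid <- rep(list(integer(0)), n)
  if (m > 0L) {
    ii <- c(eidx[, 1L], eidx[, 2L])
    jj <- c(eidx[, 2L], eidx[, 1L])
    ee <- rep.int(seq_len(m), 2L)
    sp <- split(seq_along(ii), ii)
    for (k in names(sp)) {
      v <- as.integer(k)
      idx <- sp[[k]]
      o <- order(jj[idx])
      adj[[v]] <- jj[idx][o]
      adj_eid[[v]] <- ee[idx][o]
    }
  }
  structure(list(vertices = verts, edges = eidx, n = n, m = m,
                 adj = adj, adj_eid = adj_eid, crank = crank),
            class = "elpa_network")
}

# canonical total order of vertex ids: numeric when all ids are integers,
# else lexicographic (radix: locale-independent); returns a rank vector
canonical_rank <- function(verts) {
  if (all(grepl("^[+-]?[0-9]+$", verts))) {
    r <- order(as.numeric(verts))
  } else {
    r <- order(verts, method = "radix")
  }
  rank <- integer(length(verts))
  rank[r] <- seq_along(verts)
  rank
}

#' Read an edge list file
#'
#' Parses a plain-text edge list: one edge per line, two whitespace- or
#' tab-separated vertex ids, `#` comments and blank lines ignored. Self-loops
#' are rejected; duplicate edges are collapsed with a warning.
#'
#' @param path file path.
#' @param delimiter optional single-character field separator; default splits
#'   on any whitespace run.
#' @param sort_vertices store vertices in canonical order rather than order of
#'   first appearance.
#' @return An [elpa_network].
#' @export
read_edge_list <- function(path, delimiter = NULL, sort_vertices = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(sprintf("empty edge list: '%s'", path))
  splitter <- if (is.null(delimiter)) "\\s+" else delimiter
  toks <- strsplit(trimws(lines), splitter)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("parse error in '%s' line %d: expected two vertex ids, got '%s'",
                 path, lineno[bad[1L]], lines[bad[1L]]))
  }
  ends <- t(vapply(toks, function(x) x[1:2], character(2L)))
  elpa_network(ends, sort_vertices = sort_vertices)
}

#' Write an edge list file
#'
#' Mirror of [read_edge_list()]: writes one `u<TAB>v` line per edge, in
#' canonical edge order, so that a read/write round trip reproduces the same
#' edge set.
#'
#' @param net an [elpa_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "elpa_network"))
  lines <- paste(net$vertices[net$edges[, 1L]], net$vertices[net$edges[, 2L]],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Vertex degrees
#'
#' @param net an [elpa_network].
#' @return Named integer vector of degrees.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "elpa_network"))
  d <- lengths(net$adj)
  names(d) <- net$vertices
  d
}

#' Vertices in descending degree order
#'
#' Orders vertices by degree, largest first, breaking ties by the canonical
#' vertex order. This is the default sweep order for community
#' initialization: edges around hubs seed the candidate link communities.
#'
#' @param net an [elpa_network].
#' @return Character vector of vertex ids (a permutation of `net$vertices`).
#' @examples
#' net <- load_fixture("karate")
#' head(degree_order(net), 5)  # "34" "1" "33" "3" "2"
#' @export
degree_order <- function(net) {
  stopifnot(inherits(net, "elpa_network"))
  if (net$n == 0L) stop("empty network")
  d <- lengths(net$adj)
  net$vertices[order(-d, net$crank)]
}

# internal: vertex indices in canonical order
canonical_vertex_order <- function(net) order(net$crank)

# internal: same, in descending degree order
degree_order_idx <- function(net) order(-lengths(net$adj), net$crank)

#' Coerce to an elpa_network
#'
#' Accepts an `elpa_network` (returned unchanged), a two-column matrix or
#' data frame of endpoints, a path to an edge list file, or an `igraph`
#' object (undirected, simple).
#'
#' @param x object to coerce.
#' @param ... passed to the underlying constructor.
#' @return An [elpa_network].
#' @export
as_elpa_network <- function(x, ...) {
  if (inherits(x, "elpa_network")) return(x)
  if (inherits(x, "igraph")) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("coercing from igraph requires the igraph package")
    el <- igraph::as_edgelist(x, names = TRUE)
    return(elpa_network(el, ...))
  }
  if (is.character(x) && length(x) == 1L) return(read_edge_list(x, ...))
  if (is.matrix(x) || is.data.frame(x)) return(elpa_network(x, ...))
  stop("cannot interpret 'x' as a network")
}

#' Convert to an igraph object
#'
#' @param net an [elpa_network].
#' @return An undirected `igraph` graph with the same vertex names and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "elpa_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("as_igraph() requires the igraph package")
  g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$vertices)
  igraph::add_edges(g, t(net$edges))
}

#' @export
print.elpa_network <- function(x, ...) {
  cat(sprintf("Undirected simple network: %d vertices, %d edges\n", x$n, x$m))
  invisible(x)
}

# internal: "u-v" tokens for a set of edge ids
edge_tokens <- function(net, eids = seq_len(net$m)) {
  paste(net$vertices[net$edges[eids, 1L]], net$vertices[net$edges[eids, 2L]],
        sep = "-")
}

# internal: connected component id per vertex (BFS)
component_ids <- function(net) {
  comp <- integer(net$n)
  cur <- 0L
  for (s in seq_len(net$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- net$adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
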