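#' Detect communities by edge label propagation
#'
#' Runs the full ELPA pipeline on an undirected, unweighted simple graph:
#' degree-seeded greedy edge covering ([elpa_initialize()]), triangle-rule
#' edge label propagation ([elpa_stage1()]), trend-label augmented
#' propagation ([elpa_stage2()]), node label propagation
#' ([elpa_node_propagation()]) and bridge identification ([elpa_bridges()]
#' with a re-check loop that repeats node propagation with bridge edges
#' removed from the incident-edge tally until the bridge set stabilizes).
#'
#' The output contains both partitions the method produces: link communities
#' (a partition of the edge set) and node communities (a cover of the vertex
#' set, possibly overlapping). With the default settings the algorithm is
#' fully deterministic: all sweeps run in the canonical vertex/edge order and
#' every tie is broken by community size then smallest label id.
#'
#' @param x the network: an [elpa_network], an `igraph` object, a two-column
#'   edge matrix/data frame, or the path to an edge list file.
#' @param init seeding order for the initial edge covering (`"degree"`,
#'   `"index"` or `"random"`; see [elpa_initialize()]).
#' @param seed integer seed, used only when `init = "random"`.
#' @param sync synchronous edge-label updates (the default; reproduces the
#'   method's t / t-1 update equations); `FALSE` switches the edge stages to
#'   asynchronous in-order sweeps.
#' @param max_sweeps per-stage sweep cap (exceeding it flags
#'   `converged = FALSE` rather than failing).
#' @param recompute_trend recompute trend labels at every stage-II pass
#'   (default) or once per stage.
#' @return An object of class `"elpa"`; see [print.elpa()],
#'   [node_communities()], [link_communities()], [overlapping_nodes()],
#'   [bridges()].
#' @examples
#' fit <- elpa(load_fixture("karate"))
#' fit$stage_counts        # 15 initial, 9 after stage I, 5 after stage II
#' length(node_communities(fit))
#' @export
elpa <- function(x, init = c("degree", "index", "random"), seed = NULL,
                 sync = TRUE, max_sweeps = 100L, recompute_trend = TRUE) {
  net <- as_elpa_network(x)
  init <- match.arg(init)
  if (net$m == 0L) {
    return(structure(list(network = net, edge_labels = integer(0),
                          node_labels = list(), stage_counts = c(init = 0L,
                          stage1 = 0L, stage2 = 0L), iterations = c(stage1 = 0L,
                          stage2 = 0L, node = 0L, bridge_rounds = 0L),
                          converged = TRUE, bridge_eids = integer(0),
                          work = 0, call = match.call()), class = "elpa"))
  }
  pre <- elpa_precompute(net)

  lab0 <- elpa_initialize(net, order = init, seed = seed)
  s1 <- elpa_stage1(net, lab0, max_sweeps = max_sweeps, sync = sync, pre = pre)
  s2 <- elpa_stage2(net, s1$labels, max_sweeps = max_sweeps, sync = sync,
                    recompute_trend = recompute_trend, pre = pre)
  np <- elpa_node_propagation(net, s2$labels, view = s2$view,
                              max_sweeps = max_sweeps, pre = pre)
  nl <- np$node_labels
  # bridge re-check: drop bridges from the tier-2 tally and re-propagate
  # until the flagged set stops changing
  br <- elpa_bridges(net, nl)
  rounds <- 0L
  np_work <- np$work
  while (rounds < 10L) {
    rounds <- rounds + 1L
    np2 <- elpa_node_propagation(net, s2$labels, view = s2$view,
                                 exclude_eids = br, max_sweeps = max_sweeps,
                                 pre = pre)
    np_work <- np_work + np2$work
    br2 <- elpa_bridges(net, np2$node_labels)
    if (identical(br2, br)) { nl <- np2$node_labels; break }
    br <- br2
    nl <- np2$node_labels
  }

  structure(list(
    network = net,
    edge_labels = s2$labels,
    node_labels = nl,
    stage_counts = c(init = attr(lab0, "n_communities"),
                     stage1 = s1$n_communities, stage2 = s2$n_communities),
    iterations = c(stage1 = s1$sweeps, stage2 = s2$sweeps, node = np$sweeps,
                   bridge_rounds = rounds),
    converged = s1$converged && s2$converged && np$converged,
    bridge_eids = br,
    work = s1$work + s2$work + np_work + net$m,
    call = match.call()), class = "elpa")
}

#' Link communities of a fit
#'
#' @param fit an `"elpa"` object.
#' @return Named list (by label id) of two-column character matrices, each
#'   row one edge of that link community. The groups partition the edge set.
#' @export
link_communities <- function(fit) {
  stopifnot(inherits(fit, "elpa"))
  net <- fit$network
  if (net$m == 0L) return(list())
  sp <- split(seq_len(net$m), fit$edge_labels)
  lapply(sp, function(eids)
    matrix(net$vertices[net$edges[eids, , drop = FALSE]], ncol = 2L,
           dimnames = list(NULL, c("u", "v"))))
}

#' Node communities of a fit
#'
#' @param fit an `"elpa"` object.
#' @return Named list (by label id) of character vectors of vertex ids; a
#'   vertex appears in every community whose label it ended with, so the
#'   groups may overlap.
#' @export
node_communities <- function(fit) {
  stopifnot(inherits(fit, "elpa"))
  net <- fit$network
  if (net$n == 0L) return(list())
  labs <- sort(unique(unlist(fit$node_labels, use.names = FALSE)))
  out <- lapply(labs, function(l)
    net$vertices[vapply(fit$node_labels, function(s) l %in% s, logical(1L))])
  names(out) <- labs
  out
}

#' Overlapping nodes of a fit
#'
#' @param fit an `"elpa"` object.
#' @return Character vector of vertices that ended with two or more community
#'   labels.
#' @export
overlapping_nodes <- function(fit) {
  stopifnot(inherits(fit, "elpa"))
  fit$network$vertices[lengths(fit$node_labels) >= 2L]
}

#' Bridges of a fit
#'
#' @param fit an `"elpa"` object.
#' @return Two-column character matrix of edges whose endpoints share no
#'   final community label (the community-crossing edges).
#' @export
bridges <- function(fit) {
  stopifnot(inherits(fit, "elpa"))
  net <- fit$network
  matrix(net$vertices[net$edges[fit$bridge_eids, , drop = FALSE]], ncol = 2L,
         dimnames = list(NULL, c("u", "v")))
}

#' @rdname elpa
#' @param ... ignored.
#' @export
print.elpa <- function(x, ...) {
  cat("Edge label propagation community detection\n")
  cat(sprintf("  network: %d vertices, %d edges\n", x$network$n, x$network$m))
  sc <- x$stage_counts
  cat(sprintf("  link communities: %d initial -> %d after stage I -> %d final\n",
              sc[["init"]], sc[["stage1"]], sc[["stage2"]]))
  cat(sprintf("  node communities: %d (%d overlapping node(s), %d bridge(s))\n",
              length(node_communities(x)), length(overlapping_nodes(x)),
              length(x$bridge_eids)))
  if (!x$converged) cat("  WARNING: sweep cap hit before convergence\n")
  invisible(x)
}

#' Summarize an ELPA fit
#'
#' @param object an `"elpa"` object.
#' @param ... ignored.
#' @return An object of class `summary.elpa` with community size tables and
#'   the quality metrics computable without ground truth (modularity of the
#'   node cover, partition density of the link cover).
#' @export
summary.elpa <- function(object, ...) {
  nc <- node_communities(object)
  lc <- link_communities(object)
  q <- if (length(nc)) modularity_overlapping(object$network, nc) else NA_real_
  d <- if (length(lc)) partition_density(object$network, lc) else NA_real_
  structure(list(fit = object,
                 node_sizes = sort(lengths(nc), decreasing = TRUE),
                 link_sizes = sort(vapply(lc, nrow, 1L), decreasing = TRUE),
                 overlap_modularity = q, partition_density = d),
            class = "summary.elpa")
}

#' @export
print.summary.elpa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  node community sizes: %s\n",
              paste(x$node_sizes, collapse = " ")))
  cat(sprintf("  link community sizes (edges): %s\n",
              paste(x$link_sizes, collapse = " ")))
  cat(sprintf("  overlap modularity: %.4f   partition density: %.4f\n",
              x$overlap_modularity, x$partition_density))
  cat(sprintf("  sweeps: stage I %d, stage II %d, node %d; bridge rounds %d\n",
              x$fit$iterations[["stage1"]], x$fit$iterations[["stage2"]],
              x$fit$iterations[["node"]], x$fit$iterations[["bridge_rounds"]]))
  invisible(x)
}

#' Plot an ELPA fit
#'
#' Draws the network (via igraph) with vertices colored by node community,
#' overlapping nodes shown square, and bridges dashed.
#'
#' @param x an `"elpa"` object.
#' @param ... passed to `plot.igraph`.
#' @export
plot.elpa <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plot.elpa() requires the igraph package")
  g <- as_igraph(x$network)
  first_label <- vapply(x$node_labels, function(s)
    if (length(s)) s[[1L]] else NA_integer_, integer(1L))
  pal <- grDevices::hcl.colors(max(1L, length(unique(first_label))), "Dark 3")
  col <- pal[match(first_label, sort(unique(first_label)))]
  shape <- ifelse(lengths(x$node_labels) >= 2L, "square", "circle")
  lty <- rep(1L, x$network$m)
  lty[x$bridge_eids] <- 2L
  ecol <- rep("grey40", x$network$m)
  ecol[x$bridge_eids] <- "darkgreen"
  igraph::plot.igraph(g, vertex.color = col, vertex.shape = shape,
                      edge.lty = lty, edge.color = ecol, ...)
  invisible(x)
}
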