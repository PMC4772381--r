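# Core edge label propagation ------------------------------------------------
#
# Link communities are the level sets of a total edge -> label map. All label
# dynamics below only ever ADOPT labels of existing communities, so the number
# of non-empty link communities is non-increasing after initialization.
# Every sweep visits edges/vertices in the canonical order and (by default)
# reads the latest state, which makes the whole pipeline deterministic.

# Static per-network structures used by every sweep:
#   tri[[e]] : 2-column matrix of edge-id pairs (e_ab, e_ac), one row per
#              common neighbor a of e's endpoints (the triangle witnesses)
#   nbe[[v]] : ids of edges whose BOTH endpoints are neighbors of v
elpa_precompute <- function(net) {
  m <- net$m
  tri <- vector("list", m)
  nbe_acc <- rep(list(integer(0)), net$n)
  empty <- matrix(integer(0), 0L, 2L)
  adj <- net$adj
  eid <- net$adj_eid
  tri_rows <- 0L
  for (e in seq_len(m)) {
    b <- net$edges[e, 1L]; cc <- net$edges[e, 2L]
    common <- intersect(adj[[b]], adj[[cc]])
    if (length(common)) {
      pb <- match(common, adj[[b]])
      pc <- match(common, adj[[cc]])
      tri[[e]] <- cbind(eid[[b]][pb], eid[[cc]][pc])
      tri_rows <- tri_rows + length(common)
      for (a in common) nbe_acc[[a]] <- c(nbe_acc[[a]], e)
    } else {
      tri[[e]] <- empty
    }
  }
  list(tri = tri, nbe = nbe_acc, tri_rows = tri_rows,
       vorder = canonical_vertex_order(net))
}

#' Initialize link communities by greedy edge covering
#'
#' Visits vertices in a chosen order (hubs first by default) and opens a new
#' link community holding ALL not-yet-assigned edges incident to the visited
#' vertex, until every edge carries a label. Label ids are 1, 2, ... in
#' creation order. High-degree seeding keeps the number of initial
#' communities small (about n/2 in practice) and speeds up convergence.
#'
#' @param net an [elpa_network].
#' @param order seeding order: `"degree"` (descending degree, canonical
#'   tie-break; the default), `"index"` (canonical vertex order), or
#'   `"random"` (seeded shuffle).
#' @param seed integer seed, used only for `order = "random"`.
#' @return Integer vector of edge labels, one per edge, with attribute
#'   `n_communities`.
#' @examples
#' lab <- elpa_initialize(load_fixture("karate"))
#' attr(lab, "n_communities")  # 15
#' @export
elpa_initialize <- function(net, order = c("degree", "index", "random"),
                            seed = NULL) {
  stopifnot(inherits(net, "elpa_network"))
  if (net$n == 0L) stop("empty network")
  order <- match.arg(order)
  vord <- switch(order,
    degree = degree_order_idx(net),
    index  = canonical_vertex_order(net),
    random = local_seed(seed, sample.int(net$n)))
  labels <- integer(net$m)
  nxt <- 0L
  for (v in vord) {
    free <- net$adj_eid[[v]][labels[net$adj_eid[[v]]] == 0L]
    if (length(free)) {
      nxt <- nxt + 1L
      labels[free] <- nxt
    }
  }
  attr(labels, "n_communities") <- nxt
  labels
}

# run `expr` under a temporary RNG state (NULL seed = leave RNG alone)
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Triangle-rule candidate labels for one edge
#'
#' An edge (b, c) may adopt label l when some common neighbor a of b and c
#' carries l on both triangle legs (a, b) and (a, c): the two endpoints then
#' demonstrably share membership in community l.
#'
#' @param net an [elpa_network].
#' @param labels integer edge-label vector (see [elpa_initialize()]).
#' @param edge either a single edge id, or a length-2 vector of vertex ids.
#' @return Sorted integer vector of candidate label ids (possibly empty).
#' @export
elpa_triangle_candidates <- function(net, labels, edge) {
  stopifnot(inherits(net, "elpa_network"))
  e <- resolve_edge(net, edge)
  b <- net$edges[e, 1L]; cc <- net$edges[e, 2L]
  common <- intersect(net$adj[[b]], net$adj[[cc]])
  if (!length(common)) return(integer(0))
  l1 <- labels[net$adj_eid[[b]][match(common, net$adj[[b]])]]
  l2 <- labels[net$adj_eid[[cc]][match(common, net$adj[[cc]])]]
  sort(unique(l1[l1 == l2]))
}

resolve_edge <- function(net, edge) {
  if (length(edge) == 1L && is.numeric(edge)) return(as.integer(edge))
  idx <- match(as.character(edge), net$vertices)
  if (anyNA(idx)) stop("unknown vertex id in 'edge'")
  hit <- which((net$edges[, 1L] == idx[1L] & net$edges[, 2L] == idx[2L]) |
               (net$edges[, 1L] == idx[2L] & net$edges[, 2L] == idx[1L]))
  if (!length(hit)) stop("no such edge")
  hit[1L]
}

# one asynchronous stage-I sweep; mutates labels/sizes in the caller's frame
# via returned values. cand_extra(e) supplies stage-II's shared-vertex-label
# candidates (NULL in stage I).
propagation_sweep <- function(net, pre, labels, sizes, extra = NULL,
                              sync = FALSE) {
  changed <- 0L
  tri <- pre$tri
  if (sync) {
    new_labels <- labels
    for (e in seq_len(net$m)) {
      cand <- sweep_candidates(tri[[e]], labels, extra, e)
      if (!length(cand)) next
      best <- pick_largest(cand, sizes, labels[e])
      if (best != labels[e]) { new_labels[e] <- best; changed <- changed + 1L }
    }
    if (changed) sizes <- tabulate(new_labels, nbins = length(sizes))
    labels <- new_labels
  } else {
    for (e in seq_len(net$m)) {
      cand <- sweep_candidates(tri[[e]], labels, extra, e)
      if (!length(cand)) next
      best <- pick_largest(cand, sizes, labels[e])
      old <- labels[e]
      if (best != old) {
        labels[e] <- best
        sizes[old] <- sizes[old] - 1L
        sizes[best] <- sizes[best] + 1L
        changed <- changed + 1L
      }
    }
  }
  list(labels = labels, sizes = sizes, changed = changed)
}

sweep_candidates <- function(trie, labels, extra, e) {
  cand <- integer(0)
  if (nrow(trie)) {
    l1 <- labels[trie[, 1L]]
    l2 <- labels[trie[, 2L]]
    cand <- l1[l1 == l2]
  }
  if (!is.null(extra) && length(extra[[e]])) cand <- c(cand, extra[[e]])
  cand
}

# largest community wins; ties -> smallest label id
pick_largest <- function(cand, sizes, own) {
  cand <- unique(cand)
  cand <- cand[sizes[cand] > 0L]
  if (!length(cand)) return(own)
  s <- sizes[cand]
  min(cand[s == max(s)])
}

#' Stage I: triangle-rule edge label propagation
#'
#' Repeated sweeps over the edges in canonical order; each edge with at least
#' one triangle-rule candidate adopts the candidate belonging to the largest
#' link community (community size in edges; ties broken by smallest label
#' id). Edges without triangle witnesses keep their label. Sweeps continue
#' until a full pass changes nothing, or `max_sweeps` is hit.
#'
#' @param net an [elpa_network].
#' @param labels initial edge labels from [elpa_initialize()].
#' @param max_sweeps sweep cap (non-convergence is flagged, not an error).
#' @param sync synchronous updates (the default: every edge reads the label
#'   state of the previous sweep, matching the t / t-1 update equations);
#'   `FALSE` switches to asynchronous in-order sweeps for experimentation.
#' @param pre precomputed triangle structure (internal; recomputed if `NULL`).
#' @return List with `labels`, `n_communities`, `sweeps`, `converged`.
#' @export
elpa_stage1 <- function(net, labels, max_sweeps = 100L, sync = TRUE,
                        pre = NULL) {
  stopifnot(inherits(net, "elpa_network"), length(labels) == net$m)
  if (is.null(pre)) pre <- elpa_precompute(net)
  labels <- as.integer(labels)            # drop any attributes of the input
  sizes <- tabulate(labels, nbins = max(labels, 1L))
  sweeps <- 0L
  converged <- FALSE
  cycle <- FALSE
  work <- 0
  prev2 <- labels
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    work <- work + net$m + pre$tri_rows
    st <- propagation_sweep(net, pre, labels, sizes, sync = sync)
    if (st$changed == 0L) { labels <- st$labels; sizes <- st$sizes
                            converged <- TRUE; break }
    # synchronous updates can fall into a period-2 limit cycle; stop on it
    # (keeping the current state makes a re-run return the same labeling)
    if (sweeps >= 2L && identical(st$labels, prev2)) {
      labels <- st$labels; sizes <- st$sizes
      converged <- TRUE; cycle <- TRUE; break
    }
    prev2 <- labels
    labels <- st$labels; sizes <- st$sizes
  }
  if (!converged) warning(sprintf("stage I hit the sweep cap (%d)", max_sweeps))
  list(labels = labels, n_communities = sum(sizes > 0L), sweeps = sweeps,
       converged = converged, limit_cycle = cycle, work = work)
}

#' Trend labels for a vertex
#'
#' During stage I a vertex can lose a membership it genuinely has: all its
#' own edges get overwritten by one community while its neighborhood still
#' concentrates in another. The trend label recovers it. The rule pools the
#' labels of ALL edges incident to the neighbors of `vertex`: if one label
#' holds a strict majority of that multiset it is the trend label; otherwise
#' the label(s) carried by the greatest number of distinct neighbors are
#' returned (all ties kept).
#'
#' @param net an [elpa_network].
#' @param labels integer edge-label vector.
#' @param vertex a vertex id (or index).
#' @return Sorted integer vector of trend label ids (empty for an isolated
#'   vertex).
#' @export
elpa_trend_labels <- function(net, labels, vertex) {
  stopifnot(inherits(net, "elpa_network"))
  k <- if (is.numeric(vertex) && vertex %in% seq_len(net$n) &&
           !(as.character(vertex) %in% net$vertices)) as.integer(vertex)
       else match(as.character(vertex), net$vertices)
  if (is.na(k)) stop("unknown vertex")
  trend_for_vertex(net, labels, k)
}

trend_for_vertex <- function(net, labels, k) {
  nbr <- net$adj[[k]]
  if (!length(nbr)) return(integer(0))
  pool <- labels[unlist(net$adj_eid[nbr], use.names = FALSE)]
  cnt <- tabulate(pool)
  mx <- max(cnt)
  if (2L * mx > length(pool)) return(which(cnt == mx)[1L])
  # no strict majority: label(s) most distinct neighbors joined in
  per_nbr <- lapply(nbr, function(j) unique(labels[net$adj_eid[[j]]]))
  cnt2 <- tabulate(unlist(per_nbr, use.names = FALSE))
  sort(which(cnt2 == max(cnt2)))
}

# vertex label view: labels of incident edges, optionally + trend labels
incident_label_sets <- function(net, labels) {
  lapply(net$adj_eid, function(eids) sort(unique(labels[eids])))
}

trend_label_sets <- function(net, labels) {
  lapply(seq_len(net$n), function(k) trend_for_vertex(net, labels, k))
}

#' Stage II: trend-label augmented edge label propagation
#'
#' Each outer pass first rebuilds every vertex's label view (incident-edge
#' labels plus trend labels, see [elpa_trend_labels()]), then performs one
#' edge sweep in which an edge (b, c) considers both its triangle-rule
#' candidates and the labels shared by the views of b and c (excluding the
#' edge's own label, so an edge cannot justify itself). The largest-community
#' candidate wins, ties to the smallest label id. Passes repeat until no edge
#' label changes.
#'
#' @inheritParams elpa_stage1
#' @param recompute_trend recompute trend labels every outer pass (default)
#'   or only once at the start of the stage.
#' @return List with `labels`, `view` (per-vertex label sets at the
#'   fixpoint), `trend` (per-vertex trend label sets), `n_communities`,
#'   `sweeps`, `converged`.
#' @export
elpa_stage2 <- function(net, labels, max_sweeps = 100L, sync = TRUE,
                        recompute_trend = TRUE, pre = NULL) {
  stopifnot(inherits(net, "elpa_network"), length(labels) == net$m)
  if (is.null(pre)) pre <- elpa_precompute(net)
  labels <- as.integer(labels)
  sizes <- tabulate(labels, nbins = max(labels, 1L))
  sweeps <- 0L
  converged <- FALSE
  cycle <- FALSE
  work <- 0
  trend <- NULL
  prev2 <- labels
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    if (is.null(trend) || recompute_trend) trend <- trend_label_sets(net, labels)
    inc <- incident_label_sets(net, labels)
    view <- mapply(function(a, b) sort(unique(c(a, b))), inc, trend,
                   SIMPLIFY = FALSE)
    extra <- shared_view_candidates(net, view, labels)
    work <- work + net$m + pre$tri_rows + sum(lengths(net$adj)) * 2
    st <- propagation_sweep(net, pre, labels, sizes, extra = extra, sync = sync)
    if (st$changed == 0L) { labels <- st$labels; sizes <- st$sizes
                            converged <- TRUE; break }
    if (sweeps >= 2L && identical(st$labels, prev2)) {
      labels <- st$labels; sizes <- st$sizes
      converged <- TRUE; cycle <- TRUE; break
    }
    prev2 <- labels
    labels <- st$labels; sizes <- st$sizes
  }
  if (!converged) warning(sprintf("stage II hit the sweep cap (%d)", max_sweeps))
  inc <- incident_label_sets(net, labels)
  trend <- trend_label_sets(net, labels)
  view <- mapply(function(a, b) sort(unique(c(a, b))), inc, trend,
                 SIMPLIFY = FALSE)
  list(labels = labels, view = view, trend = trend,
       n_communities = sum(sizes > 0L), sweeps = sweeps, converged = converged,
       limit_cycle = cycle, work = work)
}

# per-edge candidates from the endpoints' shared vertex labels, own label
# excluded (an edge cannot vote for itself through its endpoints)
shared_view_candidates <- function(net, view, labels) {
  lapply(seq_len(net$m), function(e) {
    shared <- intersect(view[[net$edges[e, 1L]]], view[[net$edges[e, 2L]]])
    setdiff(shared, labels[e])
  })
}

#' Node label propagation
#'
#' Resolves each vertex's label set by repeated sweeps in canonical order.
#' A vertex k is decided by a three-tier rule: (1) the unique label carried
#' by the most neighbors (counting each neighbor's whole current label set);
#' (2) failing a unique winner, the unique most frequent label among k's own
#' incident edges; (3) failing that, the label(s) in which the edges BETWEEN
#' k's neighbors concentrate, keeping all maximal ties -- the only tier that
#' can leave a vertex with several labels, i.e. overlapping membership.
#' Sweeps repeat until no vertex's set changes.
#'
#' @param net an [elpa_network].
#' @param labels converged edge labels (after stage II).
#' @param view per-vertex starting label sets (from [elpa_stage2()]); default
#'   rebuilds incident-edge label sets.
#' @param exclude_eids edge ids left out of the tier-2 incident tally (used
#'   by the bridge re-check loop).
#' @param max_sweeps sweep cap.
#' @param pre precomputed structure (internal).
#' @return List with `node_labels` (per-vertex integer label sets),
#'   `sweeps`, `converged`.
#' @export
elpa_node_propagation <- function(net, labels, view = NULL,
                                  exclude_eids = integer(0),
                                  max_sweeps = 100L, pre = NULL) {
  stopifnot(inherits(net, "elpa_network"), length(labels) == net$m)
  if (is.null(pre)) pre <- elpa_precompute(net)
  if (is.null(view)) view <- incident_label_sets(net, labels)
  nl <- view
  keep2 <- rep(TRUE, net$m)
  keep2[exclude_eids] <- FALSE
  sweeps <- 0L
  converged <- FALSE
  work <- 0
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (k in pre$vorder) {
      nbr <- net$adj[[k]]
      if (!length(nbr)) next
      work <- work + length(nbr)
      new <- NULL
      # tier 1: plurality over neighbors' label sets, unique winner required
      cnt <- tabulate(unlist(nl[nbr], use.names = FALSE))
      if (length(cnt)) {
        top <- which(cnt == max(cnt))
        if (length(top) == 1L) new <- top
      }
      if (is.null(new)) {
        # tier 2: plurality over own incident edge labels, unique winner
        own <- net$adj_eid[[k]]
        own <- own[keep2[own]]
        if (length(own)) {
          cnt <- tabulate(labels[own])
          top <- which(cnt == max(cnt))
          if (length(top) == 1L) new <- top
        }
      }
      if (is.null(new)) {
        # tier 3: labels of edges between k's neighbors, all maximal ties
        amng <- pre$nbe[[k]]
        if (length(amng)) {
          cnt <- tabulate(labels[amng])
          new <- which(cnt == max(cnt))
        }
      }
      if (is.null(new)) next        # nothing to decide on: keep current set
      new <- sort(new)
      if (!identical(new, nl[[k]])) { nl[[k]] <- new; changed <- TRUE }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged) warning(sprintf("node propagation hit the sweep cap (%d)",
                                  max_sweeps))
  list(node_labels = nl, sweeps = sweeps, converged = converged, work = work)
}

#' Identify bridges
#'
#' A bridge is an edge whose two endpoints share no final community label:
#' it crosses communities instead of sitting inside one.
#'
#' @param net an [elpa_network].
#' @param node_labels per-vertex label sets (from [elpa_node_propagation()]).
#' @return Integer vector of bridge edge ids.
#' @export
elpa_bridges <- function(net, node_labels) {
  stopifnot(inherits(net, "elpa_network"))
  which(vapply(seq_len(net$m), function(e) {
    !any(node_labels[[net$edges[e, 1L]]] %in% node_labels[[net$edges[e, 2L]]])
  }, logical(1L)))
}
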