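# Cover-quality metrics -------------------------------------------------------
#
# A "cover" here is a plain list of character vectors of vertex ids; groups
# may overlap. A cover is disjoint when the groups are pairwise disjoint.
# Link covers are lists of edge sets, given as two-column matrices.

as_cover <- function(x) {
  if (inherits(x, "elpa")) return(node_communities(x))
  stopifnot(is.list(x), length(x) > 0L)
  x <- lapply(x, as.character)
  if (any(lengths(x) == 0L)) stop("empty group in cover")
  x
}

cover_universe <- function(a) sort(unique(unlist(a, use.names = FALSE)))

is_disjoint_cover <- function(a) {
  all_members <- unlist(a, use.names = FALSE)
  !anyDuplicated(all_members)
}

#' Read / write community cover files
#'
#' The de-facto plain-text format for vertex covers: one community per line,
#' members whitespace-separated, `#` comments ignored.
#'
#' @param path file path.
#' @return `read_cover`: a list of character vectors of vertex ids.
#' @export
read_cover <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop(sprintf("empty cover file: '%s'", path))
  lapply(strsplit(trimws(lines), "\\s+"), as.character)
}

#' @rdname read_cover
#' @param cover a list of character vectors (one community per element).
#' @export
write_cover <- function(cover, path) {
  writeLines(vapply(as_cover(cover), paste, "", collapse = " "), path)
  invisible(path)
}

# entropy helper: -p log p termwise, natural log, 0 log 0 = 0
h <- function(p) ifelse(p > 0, -p * log(p), 0)

#' Normalized mutual information between two disjoint partitions
#'
#' Standard NMI from the confusion matrix of the two partitions, normalized
#' by the arithmetic mean of the partition entropies:
#' `NMI = 2 I(A;B) / (H(A) + H(B))`. Symmetric, in `[0, 1]`; two identical
#' (even trivial) partitions score 1, a one-block partition against anything
#' else scores 0.
#'
#' @param a,b disjoint covers over the same vertex universe (lists of
#'   character vectors, or `"elpa"` fits).
#' @return A number in `[0, 1]`.
#' @export
nmi_disjoint <- function(a, b) {
  a <- as_cover(a); b <- as_cover(b)
  if (!is_disjoint_cover(a) || !is_disjoint_cover(b))
    stop("nmi_disjoint() needs disjoint partitions; see nmi_overlapping()")
  ua <- cover_universe(a); ub <- cover_universe(b)
  if (!identical(ua, ub)) stop("covers are over different vertex universes")
  n <- length(ua)
  la <- integer(n); for (g in seq_along(a)) la[match(a[[g]], ua)] <- g
  lb <- integer(n); for (g in seq_along(b)) lb[match(b[[g]], ua)] <- g
  tab <- table(la, lb) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- sum(h(pa)); hb <- sum(h(pb))
  if (ha + hb == 0) return(1)           # both trivial and identical
  outer_p <- outer(pa, pb)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer_p[nz]))
  val <- 2 * mi / (ha + hb)
  min(max(val, 0), 1)
}

#' Normalized mutual information between two (possibly overlapping) covers
#'
#' The best-match conditional-entropy construction for covers: each group is
#' a binary membership variable over the vertices; the conditional entropy of
#' a group given the other cover is the minimum over that cover's groups,
#' subject to the usual validity constraint (the joint must be closer to
#' agreement than to disagreement, else the unconditional entropy is used).
#' `NMI = 1 - (H(A|B)/H(A) + H(B|A)/H(B)) / 2` with per-group normalization.
#' Symmetric, in `[0, 1]`, and 1 exactly for identical covers.
#'
#' @param a,b covers over the same universe (overlap allowed).
#' @return A number in `[0, 1]`.
#' @export
nmi_overlapping <- function(a, b) {
  a <- as_cover(a); b <- as_cover(b)
  u <- sort(unique(c(cover_universe(a), cover_universe(b))))
  n <- length(u)
  amat <- vapply(a, function(g) u %in% g, logical(n))
  bmat <- vapply(b, function(g) u %in% g, logical(n))
  if (n == 1L) { amat <- matrix(amat, nrow = 1L); bmat <- matrix(bmat, nrow = 1L) }
  0.5 * (lfk_half(amat, bmat) + lfk_half(bmat, amat))
}

# 1 - <H(X_k | Y) / H(X_k)>_k for membership matrices (vertices x groups)
lfk_half <- function(xm, ym) {
  n <- nrow(xm)
  ratios <- vapply(seq_len(ncol(xm)), function(k) {
    x <- xm[, k]
    p1 <- mean(x); p0 <- 1 - p1
    hx <- h(p1) + h(p0)
    if (hx == 0) return(0)              # degenerate group: perfect self-match
    best <- hx
    for (l in seq_len(ncol(ym))) {
      y <- ym[, l]
      p11 <- sum(x & y) / n;  p10 <- sum(x & !y) / n
      p01 <- sum(!x & y) / n; p00 <- sum(!x & !y) / n
      if (h(p11) + h(p00) >= h(p01) + h(p10)) {
        hy <- h(mean(y)) + h(1 - mean(y))
        hcond <- h(p11) + h(p10) + h(p01) + h(p00) - hy
        if (hcond < best) best <- hcond
      }
    }
    best / hx
  }, numeric(1L))
  1 - mean(ratios)
}

#' Girvan-Newman modularity of a disjoint partition
#'
#' `Q = sum_c [ e_cc / m - (d_c / 2m)^2 ]` where `e_cc` is the number of
#' intra-community edges and `d_c` the total degree of community `c`.
#'
#' @param net an [elpa_network].
#' @param a a disjoint partition of the vertices (list of character vectors,
#'   or an `"elpa"` fit).
#' @return Modularity (at most 1; 0 for the one-community partition).
#' @export
modularity_gn <- function(net, a) {
  stopifnot(inherits(net, "elpa_network"))
  a <- as_cover(a)
  if (!is_disjoint_cover(a))
    stop("overlapping cover: use modularity_overlapping()")
  modularity_overlapping(net, a)
}

#' Belonging-coefficient overlap modularity
#'
#' Extends Girvan-Newman modularity to overlapping covers: a vertex `v` in
#' `|M(v)|` communities contributes belonging weight `a_vc = 1/|M(v)|` to
#' each. `Q = sum_c [ W_c / m - (D_c / 2m)^2 ]` with
#' `W_c = sum over intra-c edges of a_uc a_vc` and
#' `D_c = sum over members of a_vc d_v`. On a disjoint cover every weight is
#' 1 and the formula reduces exactly to [modularity_gn()].
#'
#' @param net an [elpa_network].
#' @param a a cover of all vertices (overlap allowed).
#' @return Overlap modularity.
#' @export
modularity_overlapping <- function(net, a) {
  stopifnot(inherits(net, "elpa_network"))
  a <- as_cover(a)
  u <- cover_universe(a)
  missing_v <- setdiff(net$vertices, u)
  if (length(missing_v))
    stop(sprintf("vertex '%s' belongs to no community", missing_v[1L]))
  if (!all(u %in% net$vertices)) stop("cover names vertices not in the network")
  m <- net$m
  if (m == 0L) stop("network has no edges")
  memb <- integer(net$n)                     # membership multiplicities
  for (g in a) {
    idx <- match(unique(g), net$vertices)
    memb[idx] <- memb[idx] + 1L
  }
  alpha <- 1 / memb
  deg <- lengths(net$adj)
  q <- 0
  for (g in a) {
    idx <- match(unique(g), net$vertices)
    inc <- logical(net$n); inc[idx] <- TRUE
    e1 <- net$edges[, 1L]; e2 <- net$edges[, 2L]
    intra <- inc[e1] & inc[e2]
    wc <- sum(alpha[e1[intra]] * alpha[e2[intra]])
    dc <- sum(alpha[idx] * deg[idx])
    q <- q + wc / m - (dc / (2 * m))^2
  }
  q
}

#' Partition density of a link cover
#'
#' The edge-weighted mean link density of the link communities:
#' `D = (2/M) sum_c m_c (m_c - (n_c - 1)) / ((n_c - 2)(n_c - 1))`, where
#' `m_c` is the number of edges and `n_c` the number of induced vertices of
#' community `c`; a two-vertex community contributes 0. `D = 1` when every
#' community is a clique spanning its vertices, 0 when every community is a
#' tree.
#'
#' @param net an [elpa_network].
#' @param lc a link cover partitioning the edges: a list of two-column edge
#'   matrices (as from [link_communities()]) or of `"u-v"` edge tokens.
#' @return Partition density (at most 1).
#' @export
partition_density <- function(net, lc) {
  stopifnot(inherits(net, "elpa_network"), is.list(lc), length(lc) > 0L)
  groups <- lapply(lc, function(g) {
    if (is.character(g) && is.null(dim(g)))   # vector of "u-v" tokens
      g <- do.call(rbind, strsplit(g, "-", fixed = TRUE))
    g <- as.matrix(g)
    if (ncol(g) != 2L) stop("link cover groups must be 2-column edge matrices")
    g
  })
  toks <- unlist(lapply(groups, function(g)
    paste(pmin(g[, 1L], g[, 2L]), pmax(g[, 1L], g[, 2L]))), use.names = FALSE)
  all_toks <- paste(pmin(net$vertices[net$edges[, 1L]],
                         net$vertices[net$edges[, 2L]]),
                    pmax(net$vertices[net$edges[, 1L]],
                         net$vertices[net$edges[, 2L]]))
  if (length(toks) != net$m || anyDuplicated(toks) ||
      !setequal(toks, all_toks))
    stop("link cover must partition the network's edge set")
  dsum <- 0
  for (g in groups) {
    mc <- nrow(g)
    nc <- length(unique(c(g)))
    if (nc <= 2L) next
    dsum <- dsum + mc * (mc - (nc - 1)) / ((nc - 2) * (nc - 1))
  }
  2 * dsum / net$m
}
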