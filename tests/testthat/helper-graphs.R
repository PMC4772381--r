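# Fixture builders and independent oracles used across the suite. All
# fixtures are constructed in code; anything random is seeded per test.

edge_mat <- function(...) {
  v <- c(...)
  matrix(as.character(v), ncol = 2L, byrow = TRUE)
}

complete_graph <- function(vertices) {
  t(utils::combn(as.character(vertices), 2L))
}

path_graph <- function(vertices) {
  v <- as.character(vertices)
  cbind(v[-length(v)], v[-1L])
}

star_graph <- function(center, leaves) {
  cbind(rep(as.character(center), length(leaves)), as.character(leaves))
}

cycle_graph <- function(vertices) {
  v <- as.character(vertices)
  rbind(cbind(v[-length(v)], v[-1L]), c(v[length(v)], v[1L]))
}

# random simple graph on n vertices with edge probability p (never empty)
random_graph <- function(n, p = 0.4) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  elpa_network(matrix(as.character(pairs[keep, , drop = FALSE]), ncol = 2L))
}

# random spanning tree on n vertices (random attachment)
random_tree <- function(n) {
  parent <- vapply(2:n, function(v) sample.int(v - 1L, 1L), 1L)
  elpa_network(cbind(as.character(parent), as.character(2:n)))
}

# independent reference for the overlapping (cover) NMI: direct termwise
# entropy evaluation over per-vertex membership indicators
lfk_nmi_ref <- function(A, B) {
  u <- sort(unique(c(unlist(A), unlist(B))))
  hh <- function(p) if (p > 0) -p * log(p) else 0
  half <- function(X, Y) {
    mean(vapply(X, function(xk) {
      x <- u %in% xk
      Hx <- hh(mean(x)) + hh(1 - mean(x))
      if (Hx == 0) return(0)
      best <- Hx
      for (yl in Y) {
        y <- u %in% yl
        p00 <- mean(!x & !y); p01 <- mean(!x & y)
        p10 <- mean(x & !y);  p11 <- mean(x & y)
        if (hh(p11) + hh(p00) >= hh(p01) + hh(p10)) {
          Hy <- hh(mean(y)) + hh(1 - mean(y))
          cond <- hh(p00) + hh(p01) + hh(p10) + hh(p11) - Hy
          if (cond < best) best <- cond
        }
      }
      best / Hx
    }, numeric(1L)))
  }
  1 - 0.5 * (half(A, B) + half(B, A))
}

# membership vector (1-based community index per vertex) for igraph oracles;
# only valid for disjoint covers over exactly the network's vertices
membership_of <- function(net, cover) {
  m <- integer(net$n)
  for (g in seq_along(cover)) m[match(cover[[g]], net$vertices)] <- g
  m
}

# cover as a canonical set-of-sets signature (label-renumbering invariant)
cover_signature <- function(cover) {
  unname(sort(vapply(cover, function(g) paste(sort(g), collapse = ","), "")))
}
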