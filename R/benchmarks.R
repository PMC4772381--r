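# Synthetic benchmark graphs with planted community structure ----------------

#' Planted-partition benchmark (GN-style)
#'
#' The classic four-group benchmark: `n` vertices in equally sized groups,
#' each pair connected independently with probability `p_in` inside a group
#' and `p_out` across groups. The probabilities are solved from the expected
#' degree `avg_degree` and the mixing fraction `mu` (fraction of a vertex's
#' edges expected to leave its group): `p_in = (1-mu) k / (g-1)`,
#' `p_out = mu k / (n-g)` with group size `g`. Defaults are 128 vertices in
#' 4 groups of 32 with expected degree 16.
#'
#' @param n number of vertices (divisible by `groups`).
#' @param groups number of planted groups.
#' @param avg_degree expected vertex degree.
#' @param mu mixing fraction in `[0, 1]`.
#' @param seed integer seed (reproducible for a fixed seed).
#' @return A list with `network` (an [elpa_network]; isolated vertices are
#'   avoided by attaching a random in-group edge) and `cover` (the planted
#'   disjoint cover, a list of character vectors).
#' @examples
#' b <- generate_gn(mu = 0.1, seed = 1)
#' b$network$n
#' lengths(b$cover)
#' @export
generate_gn <- function(n = 128L, groups = 4L, avg_degree = 16, mu = 0.1,
                        seed = NULL) {
  if (n %% groups != 0L) stop("'n' must be divisible by 'groups'")
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (avg_degree >= n) stop("'avg_degree' must be below 'n'")
  gs <- n %/% groups
  p_in <- (1 - mu) * avg_degree / (gs - 1)
  p_out <- if (groups > 1L) mu * avg_degree / (n - gs) else 0
  if (p_in > 1 || p_out > 1)
    stop(sprintf("infeasible parameters: p_in = %.3f, p_out = %.3f", p_in, p_out))
  local_seed(seed, {
    member <- rep(seq_len(groups), each = gs)
    edges <- vector("list", (groups * (groups + 1L)) %/% 2L)
    kk <- 0L
    for (g1 in seq_len(groups)) for (g2 in g1:groups) {
      kk <- kk + 1L
      v1 <- which(member == g1); v2 <- which(member == g2)
      if (g1 == g2) {
        pairs <- npairs(gs)
        cnt <- stats::rbinom(1L, pairs, p_in)
        idx <- if (cnt) sample.int(pairs, cnt) else integer(0)
        edges[[kk]] <- decode_pairs(idx, v1)
      } else {
        pairs <- gs * gs
        cnt <- stats::rbinom(1L, pairs, p_out)
        idx <- if (cnt) sample.int(pairs, cnt) else integer(0)
        edges[[kk]] <- cbind(v1[((idx - 1L) %% gs) + 1L],
                             v2[((idx - 1L) %/% gs) + 1L])
      }
    }
    em <- do.call(rbind, edges)
    # keep every planted vertex in the graph: attach isolates inside their group
    present <- tabulate(em, nbins = n)
    for (v in which(present == 0L)) {
      peers <- setdiff(which(member == member[v]), v)
      em <- rbind(em, c(v, sample(peers, 1L)))
    }
    net <- elpa_network(matrix(as.character(em), ncol = 2L))
    cover <- split(as.character(seq_len(n)), member)
    list(network = net, cover = unname(cover))
  })
}

# (%/% binds tighter than *, hence the explicit parentheses)
npairs <- function(k) (k * (k - 1L)) %/% 2L

# decode linear indices of the upper triangle of the pair space of `verts`
decode_pairs <- function(idx, verts) {
  if (!length(idx)) return(matrix(integer(0), 0L, 2L))
  k <- length(verts)
  # row-major upper triangle: pair t -> (i, j), i < j
  ii <- integer(length(idx)); jj <- integer(length(idx))
  starts <- cumsum(c(0L, (k - 1L):1L))
  for (t in seq_along(idx)) {
    row <- findInterval(idx[t], starts, left.open = TRUE)
    ii[t] <- row
    jj[t] <- row + (idx[t] - starts[row])
  }
  cbind(verts[ii], verts[jj])
}

#' LFR-style benchmark with overlapping planted communities
#'
#' A reduced LFR-like construction: vertex degrees follow a truncated power
#' law (exponent `tau1`, cap `max_degree`, lower cut-off calibrated so the
#' mean matches `avg_degree`); community sizes follow a truncated power law
#' (exponent `tau2`, bounds `min_community`/`max_community`); `on` vertices
#' are planted in `om` communities each, all others in one. Each vertex
#' splits its stubs into an intra fraction `1 - mu` (shared equally among its
#' memberships, capped at community size minus one) and an inter remainder.
#' Each community's intra subgraph realizes its members' intra degrees
#' exactly (Havel-Hakimi construction randomized by degree-preserving
#' double-edge swaps); inter stubs are matched globally by a configuration
#' model that rejects self-loops, duplicate edges and pairs falling inside a
#' shared community. This reproduces the statistical structure of LFR
#' benchmarks -- not the byte-exact output of the reference generator.
#'
#' @param n number of vertices.
#' @param avg_degree target mean degree.
#' @param max_degree degree cap.
#' @param min_community,max_community community size bounds.
#' @param mu target per-vertex mixing fraction in `[0, 1)`.
#' @param on number of overlapping vertices.
#' @param om memberships per overlapping vertex.
#' @param tau1,tau2 power-law exponents for degrees and community sizes.
#' @param seed integer seed.
#' @return A list with `network`, `cover` (the planted cover; overlapping
#'   when `on > 0`), and `target_mu`.
#' @export
generate_lfr_like <- function(n = 1000L, avg_degree = 10, max_degree = 50L,
                              min_community = 5L, max_community = 50L,
                              mu = 0.1, on = 0L, om = 2L, tau1 = 2,
                              tau2 = 1, seed = NULL) {
  if (min_community > max_community || max_community > n)
    stop("need min_community <= max_community <= n")
  if (on > n) stop("'on' cannot exceed 'n'")
  if (om < 1L) stop("'om' must be at least 1")
  if (mu < 0 || mu >= 1) stop("'mu' must be in [0, 1)")
  local_seed(seed, {
    deg <- sample_powerlaw_degrees(n, avg_degree, max_degree, tau1)
    sizes <- sample_community_sizes(n + on * (om - 1L), min_community,
                                    max_community, tau2)
    ncomm <- length(sizes)
    if (ncomm < om) stop("unsatisfiable: fewer communities than 'om'")
    # memberships: overlapping vertices drawn at random; a vertex may only
    # join communities larger than its per-membership intra degree (else the
    # planted intra subgraph is infeasible). Vertices are placed in random
    # order; a vertex finding every feasible community full kicks a movable
    # member out of one (the usual LFR repair).
    ov <- sort(sample.int(n, on))
    memb <- vector("list", n)
    need <- rep(1L, n); need[ov] <- om
    d_share <- ceiling(round((1 - mu) * deg) / need)
    # a vertex needing more intra neighbors than the largest community holds
    # gets clamped; its excess stubs go inter (negligible shift of mu)
    d_share <- pmin(d_share, max(sizes) - 1L)
    avail <- sizes
    members <- rep(list(integer(0)), ncomm)
    place <- function(v, exclude) {
      open <- setdiff(which(avail > 0L), exclude)
      feas <- open[sizes[open] > d_share[v]]
      if (length(feas)) {
        return(if (length(feas) == 1L) feas else
               sample(feas, 1L, prob = avail[feas]))
      }
      # every feasible community is full (or excluded): evict a member that
      # itself fits into some open community, then take its slot
      fullfeas <- setdiff(which(sizes > d_share[v]), exclude)
      for (cc in sample(fullfeas)) {
        for (w in sample(members[[cc]])) {
          wopen <- setdiff(open, memb[[w]])
          wfeas <- wopen[sizes[wopen] > d_share[w]]
          if (length(wfeas)) {
            dest <- if (length(wfeas) == 1L) wfeas else
              sample(wfeas, 1L, prob = avail[wfeas])
            members[[cc]] <<- setdiff(members[[cc]], w)
            memb[[w]] <<- c(setdiff(memb[[w]], cc), dest)
            members[[dest]] <<- c(members[[dest]], w)
            avail[dest] <<- avail[dest] - 1L
            avail[cc] <<- avail[cc] + 1L
            return(cc)
          }
        }
      }
      if (!length(open)) stop("unsatisfiable membership assignment")
      open[which.max(sizes[open])]            # last resort: largest open one
    }
    for (v in sample.int(n)) {
      take <- integer(0)
      for (r in seq_len(need[v])) {
        pick <- place(v, take)
        take <- c(take, pick)
        avail[pick] <- avail[pick] - 1L
        members[[pick]] <- c(members[[pick]], v)
      }
      memb[[v]] <- take
    }
    # split stubs into intra (per membership) and inter
    d_in_total <- round((1 - mu) * deg)
    intra <- matrix(0L, nrow = n, ncol = 0L)  # handled per community below
    comm_members <- lapply(seq_len(ncomm), function(cc)
      which(vapply(memb, function(s) cc %in% s, logical(1L))))
    csize <- lengths(comm_members)
    intra_deg <- vector("list", n)
    for (v in seq_len(n)) {
      ms <- memb[[v]]
      share <- floor(d_in_total[v] / length(ms))
      dd <- rep(share, length(ms))
      extra <- d_in_total[v] - sum(dd)
      if (extra > 0L) dd[seq_len(extra)] <- dd[seq_len(extra)] + 1L
      dd <- pmin(dd, csize[ms] - 1L)          # cannot exceed community size - 1
      intra_deg[[v]] <- dd
    }
    edges <- vector("list", ncomm + 1L)
    for (cc in seq_len(ncomm)) {
      mem <- comm_members[[cc]]
      dd <- vapply(mem, function(v)
        as.integer(intra_deg[[v]][match(cc, memb[[v]])]), 1L)
      edges[[cc]] <- degree_graph(mem, dd)
    }
    used <- tabulate(unlist(lapply(edges, as.vector), use.names = FALSE),
                     nbins = n)
    d_ext <- pmax(deg - used, 0L)
    ext_stubs <- rep.int(seq_len(n), d_ext)
    edges[[ncomm + 1L]] <- match_stubs(ext_stubs, forbid = memb)
    em <- unique(do.call(rbind, edges))
    present <- tabulate(em, nbins = n)
    for (v in which(present == 0L)) {
      peers <- setdiff(comm_members[[memb[[v]][1L]]], v)
      if (!length(peers)) peers <- setdiff(seq_len(n), v)
      em <- rbind(em, sort(c(v, sample(peers, 1L))))
    }
    em <- unique(em)
    net <- elpa_network(matrix(as.character(em), ncol = 2L))
    cover <- lapply(comm_members, as.character)
    list(network = net, cover = cover, target_mu = mu)
  })
}

# degrees from a truncated continuous power law, rounded; lower cut-off
# solved so the mean hits `target`
sample_powerlaw_degrees <- function(n, target, kmax, tau) {
  if (target >= kmax) stop("'avg_degree' must be below 'max_degree'")
  mean_for <- function(a) {
    if (abs(tau - 2) < 1e-9) a * log(kmax / a) / (1 - a / kmax)
    else ((1 - tau) / (2 - tau)) *
      (kmax^(2 - tau) - a^(2 - tau)) / (kmax^(1 - tau) - a^(1 - tau))
  }
  lo <- 1; hi <- kmax - 1e-6
  a <- stats::uniroot(function(x) mean_for(x) - target, c(lo, hi),
                      tol = 1e-8)$root
  u <- stats::runif(n)
  x <- (a^(1 - tau) + u * (kmax^(1 - tau) - a^(1 - tau)))^(1 / (1 - tau))
  deg <- pmax(1L, pmin(as.integer(round(x)), kmax))
  if (sum(deg) %% 2L == 1L) deg[which.max(deg < kmax)] <- deg[which.max(deg < kmax)] + 1L
  deg
}

# community sizes from a truncated discrete power law summing to `slots`
sample_community_sizes <- function(slots, smin, smax, tau) {
  if (slots < smin) stop("too few membership slots for one community")
  support <- smin:smax
  prob <- support^(-tau)
  sizes <- integer(0)
  while (sum(sizes) < slots) {
    sizes <- c(sizes, sample(support, 1L, prob = prob))
  }
  excess <- sum(sizes) - slots
  if (excess > 0L) {
    last <- sizes[length(sizes)] - excess
    if (last >= smin) {
      sizes[length(sizes)] <- last
    } else {
      sizes <- sizes[-length(sizes)]
      short <- slots - sum(sizes)            # spread the shortfall
      i <- 1L
      while (short > 0L) {
        if (sizes[i] < smax) { sizes[i] <- sizes[i] + 1L; short <- short - 1L }
        i <- if (i == length(sizes)) 1L else i + 1L
      }
    }
  }
  sizes
}

# random simple graph on `verts` with exact target degrees `d` (planted
# communities are small, often dense, sometimes complete): Havel-Hakimi
# construction realizes the sequence exactly, then double-edge swaps
# randomize while preserving every degree. A non-graphical remainder (rare;
# only after clamping) drops the unrealizable stubs.
degree_graph <- function(verts, d) {
  s <- length(verts)
  if (s < 2L || sum(d) == 0L) return(matrix(integer(0), 0L, 2L))
  d <- pmin(d, s - 1L)
  if (sum(d) %% 2L) { i <- which.max(d); d[i] <- d[i] - 1L }
  A <- matrix(FALSE, s, s)
  res <- as.integer(d)
  repeat {
    v <- which.max(res)
    if (res[v] == 0L) break
    cand <- setdiff(order(-res), v)
    cand <- cand[res[cand] > 0L & !A[v, cand]]
    k <- min(res[v], length(cand))
    if (k > 0L) {
      tgt <- cand[seq_len(k)]
      A[v, tgt] <- TRUE; A[tgt, v] <- TRUE
      res[tgt] <- res[tgt] - 1L
    }
    res[v] <- 0L
  }
  eidx <- which(A & upper.tri(A), arr.ind = TRUE)
  ne <- nrow(eidx)
  if (ne > 1L) {
    for (t in seq_len(4L * ne)) {
      ij <- sample.int(ne, 2L)
      u <- eidx[ij[1L], 1L]; v <- eidx[ij[1L], 2L]
      x <- eidx[ij[2L], 1L]; y <- eidx[ij[2L], 2L]
      if (stats::runif(1L) < 0.5) { tmp <- x; x <- y; y <- tmp }
      if (length(unique(c(u, v, x, y))) == 4L && !A[u, x] && !A[v, y]) {
        A[u, v] <- A[v, u] <- FALSE; A[x, y] <- A[y, x] <- FALSE
        A[u, x] <- A[x, u] <- TRUE;  A[v, y] <- A[y, v] <- TRUE
        eidx[ij[1L], ] <- range(c(u, x)); eidx[ij[2L], ] <- range(c(v, y))
      }
    }
  }
  e <- which(A & upper.tri(A), arr.ind = TRUE)
  cbind(verts[e[, 1L]], verts[e[, 2L]])
}

# configuration-model stub matching with double-edge-swap repair: self-pairs,
# duplicate edges and (optionally) pairs whose endpoints share a planted
# community are repaired by swapping partners with random other pairs; the
# few pairs still invalid after repair are dropped
match_stubs <- function(stubs, forbid = NULL) {
  if (length(stubs) < 2L) return(matrix(integer(0), 0L, 2L))
  stubs <- sample(stubs)
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  a <- stubs[c(TRUE, FALSE)]
  b <- stubs[c(FALSE, TRUE)]
  npair <- length(a)
  bad_pairs <- function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b))
    bad <- (a == b) | duplicated(key)
    if (!is.null(forbid)) {
      chk <- which(!bad)
      if (length(chk))
        bad[chk] <- mapply(function(x, y) any(forbid[[x]] %in% forbid[[y]]),
                           a[chk], b[chk])
    }
    bad
  }
  for (iter in 1:200) {
    bad <- bad_pairs(a, b)
    if (!any(bad)) break
    # one transposition at a time: keeps the stub multiset intact even when
    # the random partner is itself a bad pair
    for (i in which(bad)) {
      j <- sample.int(npair, 1L)
      tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
    }
  }
  bad <- bad_pairs(a, b)
  cbind(pmin(a, b), pmax(a, b))[!bad, , drop = FALSE]
}

#' Realized mixing of a network against a planted cover
#'
#' The per-vertex fraction of incident edges whose other endpoint shares no
#' planted community with the vertex, averaged over vertices. Used to verify
#' that generated benchmarks hit their target `mu`.
#'
#' @param net an [elpa_network].
#' @param cover the planted cover.
#' @return Mean per-vertex mixing fraction.
#' @export
realized_mixing <- function(net, cover) {
  stopifnot(inherits(net, "elpa_network"))
  cover <- as_cover(cover)
  memb <- rep(list(integer(0)), net$n)
  for (g in seq_along(cover)) {
    idx <- match(unique(cover[[g]]), net$vertices)
    idx <- idx[!is.na(idx)]
    for (v in idx) memb[[v]] <- c(memb[[v]], g)
  }
  frac <- vapply(seq_len(net$n), function(v) {
    nb <- net$adj[[v]]
    if (!length(nb)) return(NA_real_)
    ext <- vapply(nb, function(w) !any(memb[[v]] %in% memb[[w]]), logical(1L))
    mean(ext)
  }, numeric(1L))
  mean(frac, na.rm = TRUE)
}
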