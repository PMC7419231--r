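# Independent oracles: breadth-first search over single-DCJ moves, and
# exhaustive enumeration of all genomes on a small marker universe.  Both
# work on partner vectors (see dcjmedian:::partner_vector) but never use the
# adjacency-graph distance formula they are meant to check.

# all single-DCJ neighbours of a partner vector
bfs_neighbors <- function(p) {
  m <- length(p)
  adjs <- which(p > seq_len(m))
  telos <- which(p == 0L)
  out <- list()
  add <- function(q) out[[length(out) + 1L]] <<- q
  if (length(adjs) >= 2L)
    for (i in seq_along(adjs)[-length(adjs)]) for (j in (i + 1L):length(adjs)) {
      a <- adjs[i]; b <- p[a]; c <- adjs[j]; d <- p[c]
      q <- p; q[a] <- c; q[c] <- a; q[b] <- d; q[d] <- b; add(q)
      q <- p; q[a] <- d; q[d] <- a; q[b] <- c; q[c] <- b; add(q)
    }
  for (a in adjs) for (t in telos) {
    b <- p[a]
    q <- p; q[a] <- t; q[t] <- a; q[b] <- 0L; add(q)
    q <- p; q[b] <- t; q[t] <- b; q[a] <- 0L; add(q)
  }
  for (a in adjs) { q <- p; q[p[a]] <- 0L; q[a] <- 0L; add(q) }
  if (length(telos) >= 2L)
    for (i in seq_along(telos)[-length(telos)])
      for (j in (i + 1L):length(telos)) {
        a <- telos[i]; b <- telos[j]
        q <- p; q[a] <- b; q[b] <- a; add(q)
      }
  out
}

# bidirectional BFS shortest path in the single-DCJ move graph
bfs_distance <- function(pa, pb, max_depth = 14L) {
  ka <- paste(pa, collapse = ","); kb <- paste(pb, collapse = ",")
  if (ka == kb) return(0L)
  fa <- list(pa); fb <- list(pb)
  va <- new.env(hash = TRUE, parent = emptyenv())
  vb <- new.env(hash = TRUE, parent = emptyenv())
  assign(ka, 0L, va); assign(kb, 0L, vb)
  depth <- 0L
  repeat {
    depth <- depth + 1L
    if (depth > max_depth) stop("BFS depth exceeded")
    swap <- length(fa) > length(fb)
    if (swap) { tmp <- fa; fa <- fb; fb <- tmp
                tmpv <- va; va <- vb; vb <- tmpv }
    nf <- list()
    for (p in fa) {
      dp <- get(paste(p, collapse = ","), va)
      for (q in bfs_neighbors(p)) {
        k <- paste(q, collapse = ",")
        if (exists(k, vb, inherits = FALSE))
          return(get(k, vb) + dp + 1L)
        if (!exists(k, va, inherits = FALSE)) {
          assign(k, dp + 1L, va)
          nf[[length(nf) + 1L]] <- q
        }
      }
    }
    fa <- nf
    if (swap) { tmp <- fa; fa <- fb; fb <- tmp
                tmpv <- va; va <- vb; vb <- tmpv }
    if (!length(fa) && !length(fb)) stop("state space exhausted")
  }
}

# every genome on extremities 1..m as a partner vector (all matchings with
# telomeres allowed)
enum_partners <- function(m) {
  out <- list()
  rec <- function(p) {
    e <- which(is.na(p))
    if (!length(e)) { out[[length(out) + 1L]] <<- p; return(invisible()) }
    e <- e[1L]
    p2 <- p; p2[e] <- 0L; rec(p2)
    for (f in which(is.na(p))) if (f > e) {
      p2 <- p; p2[e] <- f; p2[f] <- e; rec(p2)
    }
  }
  rec(rep(NA_integer_, m))
  out
}

oracle_distance <- function(a, b) {
  u <- marker_universe(list(a, b))
  bfs_distance(dcjmedian:::partner_vector(a, u),
               dcjmedian:::partner_vector(b, u))
}

# brute-force median total by enumeration over every genome on 1..n
oracle_median_total <- function(gs) {
  u <- marker_universe(gs)
  pls <- lapply(gs, dcjmedian:::partner_vector, universe = u)
  dp <- dcjmedian:::distance_partners
  min(vapply(enum_partners(2L * length(u)), function(p)
    sum(vapply(pls, function(pl) dp(p, pl), integer(1L))), integer(1L)))
}
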