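# ---------------------------------------------------------------------------
# The DCJ median (ancestral genome) problem: given three genomes on a shared
# marker universe, find a genome m minimising the total distance
# d_sigma = sum_g d(m, g).  NP-hard; solved here exactly by branch-and-bound
# over median adjacency choices (with shared adjacencies fixed first,
# ASMedian-style), or approximately by steepest-descent local search.
# ---------------------------------------------------------------------------

#' Lower and upper bounds on the median total distance
#'
#' For pairwise distances d12, d23, d13, the total distance of any median
#' genome satisfies `ceil((d12 + d23 + d13) / 2) <= total <=
#' d12 + d23 + d13 - max(d12, d23, d13)` (the upper bound is attained by
#' placing the median on the closest input genome).
#'
#' @param d12,d23,d13 Non-negative pairwise distances; alternatively pass a
#'   length-3 vector as `d12`.
#' @return Named integer vector `c(lower, upper)`.
#' @examples
#' median_bounds(96, 98, 52)  # 123, 148
#' @export
median_bounds <- function(d12, d23 = NULL, d13 = NULL) {
  d <- if (is.null(d23)) d12 else c(d12, d23, d13)
  if (length(d) != 3L || anyNA(d)) stop("need three pairwise distances")
  if (any(d < 0)) stop("distances must be non-negative")
  s <- sum(d)
  c(lower = as.integer(ceiling(s / 2)), upper = as.integer(s - max(d)))
}

# -- internal helpers -------------------------------------------------------

# one DCJ on a full partner vector: join extremities e, f
pm_join <- function(p, e, f) {
  u <- p[e]; v <- p[f]
  p[e] <- f; p[f] <- e
  if (u > 0L && v > 0L) { p[u] <- v; p[v] <- u }
  else if (u > 0L) p[u] <- 0L
  else if (v > 0L) p[v] <- 0L
  p
}

pm_cut <- function(p, e) {
  f <- p[e]
  if (f > 0L) { p[e] <- 0L; p[f] <- 0L }
  p
}

total_distance <- function(p, pls) {
  sum(vapply(pls, function(pl) distance_partners(p, pl), integer(1L)))
}

# Greedy consensus start: adjacencies/telomeres by descending leaf vote.
consensus_partners <- function(pls) {
  m <- length(pls[[1L]])
  p <- rep(NA_integer_, m)
  for (e in seq_len(m)) {
    if (!is.na(p[e])) next
    cand <- sort(unique(vapply(pls, `[`, integer(1L), e)))
    votes <- vapply(cand, function(f)
      sum(vapply(pls, function(pl) pl[e] == f, logical(1L))), integer(1L))
    # highest vote first; telomere (0) after real partners on ties
    ord <- order(-votes, cand == 0L, cand)
    placed <- FALSE
    for (f in cand[ord]) {
      if (f == 0L) { p[e] <- 0L; placed <- TRUE; break }
      if (f != e && is.na(p[f])) { p[e] <- f; p[f] <- e; placed <- TRUE; break }
    }
    if (!placed) p[e] <- 0L
  }
  p
}

# Total adjacency agreement of a median candidate with the leaves; used as
# a secondary objective so that, among equally parsimonious medians, the one
# sharing most adjacencies/telomeres with the inputs is preferred.
leaf_agreement <- function(p, pls)
  sum((pls[[1L]] == p) + (pls[[2L]] == p) + (pls[[3L]] == p))

# Steepest-descent local search over single-DCJ moves that realise an
# adjacency or telomere of some leaf.  Moves are ranked by (total distance,
# -agreement); equal-distance moves are taken only when agreement strictly
# increases, so the search terminates.  Returns list(p, total, agreement).
descend_median <- function(p, pls) {
  total <- total_distance(p, pls)
  agr <- leaf_agreement(p, pls)
  m <- length(p)
  repeat {
    # candidate moves: for any leaf element absent from p, create it
    joins <- list(); cuts <- integer(0)
    for (pl in pls) {
      for (e in seq_len(m)) {
        f <- pl[e]
        if (f > e && p[e] != f) joins[[length(joins) + 1L]] <- c(e, f)
        if (f == 0L && p[e] > e) cuts <- c(cuts, e)
      }
    }
    if (length(joins)) {
      jm <- unique(do.call(rbind, joins))
      jm <- jm[order(jm[, 1L], jm[, 2L]), , drop = FALSE]
    } else jm <- matrix(integer(0), 0L, 2L)
    cuts <- sort(unique(cuts))
    cand <- c(lapply(seq_len(nrow(jm)), function(i)
                pm_join(p, jm[i, 1L], jm[i, 2L])),
              lapply(cuts, pm_cut, p = p))
    if (!length(cand)) break
    tt <- vapply(cand, total_distance, numeric(1L), pls)
    aa <- vapply(cand, leaf_agreement, numeric(1L), pls)
    i <- order(tt, -aa)[1L]
    if (tt[i] < total || (tt[i] == total && aa[i] > agr)) {
      p <- cand[[i]]; total <- tt[i]; agr <- aa[i]
    } else break
  }
  list(p = p, total = total, agreement = agr)
}

# Exact branch-and-bound over median partner assignments.
# pls: list of 3 leaf partner vectors.  Returns list(p, total, nodes,
# completed, n_co_optimal).
median_bnb <- function(pls, budget = 1e6, incumbent_p = NULL,
                       fix_shared = TRUE) {
  m <- length(pls[[1L]])
  N <- m %/% 2L
  pd <- c(distance_partners(pls[[1L]], pls[[2L]]),
          distance_partners(pls[[2L]], pls[[3L]]),
          distance_partners(pls[[1L]], pls[[3L]]))
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$exhausted <- FALSE
  env$n_co <- 0L
  if (!is.null(incumbent_p)) {
    env$best_p <- incumbent_p
    env$best <- total_distance(incumbent_p, pls)
    env$n_co <- 1L
  } else {
    env$best_p <- NULL
    env$best <- sum(pd)  # worse than any median
  }
  p0 <- rep(NA_integer_, m)
  if (fix_shared) {
    # an adjacency (or telomere) present in all three genomes is part of
    # some optimal median; fix it up front
    for (e in seq_len(m)) {
      v <- vapply(pls, `[`, integer(1L), e)
      if (v[1L] == v[2L] && v[2L] == v[3L]) p0[e] <- v[1L]
    }
  }
  pm_code <- function(p) { q <- p; q[is.na(q)] <- -1L; q }
  bound_total <- function(p) {
    q <- pm_code(p)
    u <- sum(q == -1L)
    s2 <- vapply(pls, function(pl) score2_cpp(q, pl), integer(1L))
    # per-leaf: d_i >= N - (score2_i + u)/2
    b1 <- 3L * N - (sum(s2) + 3L * u) / 2
    # pair route: total >= d(jk) + d_i
    b2 <- max(pd[2L] + N - (s2[1L] + u) / 2,
              pd[3L] + N - (s2[2L] + u) / 2,
              pd[1L] + N - (s2[3L] + u) / 2)
    max(b1, b2, ceiling(sum(pd) / 2))
  }
  recurse <- function(p) {
    if (env$exhausted) return(invisible())
    env$nodes <- env$nodes + 1L
    if (env$nodes > budget) { env$exhausted <- TRUE; return(invisible()) }
    e <- which(is.na(p))
    if (!length(e)) {
      tot <- total_distance(p, pls)
      if (tot < env$best) {
        env$best <- tot; env$best_p <- p; env$n_co <- 1L
      } else if (tot == env$best) {
        env$n_co <- env$n_co + 1L
        # keep the lexicographically least adjacency set
        if (is.null(env$best_p)) env$best_p <- p
        else {
          d <- which(p != env$best_p)
          if (length(d) && p[d[1L]] < env$best_p[d[1L]]) env$best_p <- p
        }
      }
      return(invisible())
    }
    if (bound_total(p) > env$best) return(invisible())
    e <- e[1L]
    free <- which(is.na(p)); free <- free[free != e]
    cand <- c(free, 0L)
    votes <- vapply(cand, function(f)
      sum(vapply(pls, function(pl) pl[e] == f, logical(1L))), integer(1L))
    ord <- order(-votes, cand == 0L, cand)
    for (f in cand[ord]) {
      p2 <- p
      if (f == 0L) p2[e] <- 0L else { p2[e] <- f; p2[f] <- e }
      recurse(p2)
      if (env$exhausted) break
    }
    invisible()
  }
  recurse(p0)
  list(p = env$best_p, total = env$best, nodes = env$nodes,
       completed = !env$exhausted, n_co_optimal = env$n_co)
}

#' Solve the DCJ median problem for three genomes
#'
#' Exact mode runs a branch-and-bound over median adjacency choices on the
#' multiple breakpoint graph: adjacencies shared by all three genomes are
#' fixed first (they belong to some optimal median), remaining extremities
#' are branched in order of leaf support, and partial assignments are pruned
#' against completed-component bounds.  Heuristic mode runs a
#' steepest-descent search over single-DCJ moves from each input genome and
#' from a majority-vote consensus; moves and final candidates are ranked by
#' total distance and then by adjacency agreement with the inputs, which
#' selects, among equally parsimonious medians, the one most similar to the
#' extant genomes.  Both modes are deterministic.
#'
#' @param g1,g2,g3 `genome` objects on a shared marker universe.
#' @param mode `"exact"` or `"heuristic"`.
#' @param budget Maximum branch-and-bound nodes in exact mode.
#' @return A `median_result`: list with `median` (genome), `per_leaf` (named
#'   distances), `total`, `lower`, `upper`, `optimal`, `nodes_explored`,
#'   `n_co_optimal` and `status`.
#' @examples
#' r <- solve_median(genome("A", c(1, 2, 3)), genome("B", c(1, 2, 3)),
#'                   genome("C", c(1, -2, 3)), mode = "exact")
#' r$total  # 1
#' @export
solve_median <- function(g1, g2, g3, mode = c("exact", "heuristic"),
                         budget = 1e6) {
  mode <- match.arg(mode)
  gs <- list(g1, g2, g3)
  labels <- vapply(gs, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  rep <- validate_genome_set(gs)
  if (!rep$ok)
    stop("genomes do not share a marker universe:\n",
         paste(rep$messages, collapse = "\n"))
  u <- rep$universe
  pls <- lapply(gs, partner_vector, universe = u)
  pd <- c(d12 = distance_partners(pls[[1L]], pls[[2L]]),
          d23 = distance_partners(pls[[2L]], pls[[3L]]),
          d13 = distance_partners(pls[[1L]], pls[[3L]]))
  b <- median_bounds(pd)
  # heuristic pass (also seeds the exact search)
  starts <- c(list(consensus_partners(pls)), pls)
  best <- NULL
  for (s in starts) {
    r <- descend_median(s, pls)
    if (is.null(best) || r$total < best$total ||
        (r$total == best$total && r$agreement > best$agreement)) best <- r
  }
  nodes <- 0L; n_co <- NA_integer_; status <- "heuristic"
  optimal <- best$total == b[["lower"]]
  p <- best$p; total <- best$total
  if (mode == "exact") {
    if (optimal) {
      status <- "lower_bound_attained"; n_co <- NA_integer_
    } else {
      bb <- median_bnb(pls, budget = budget, incumbent_p = best$p)
      p <- bb$p; total <- bb$total; nodes <- bb$nodes; n_co <- bb$n_co_optimal
      optimal <- bb$completed || total == b[["lower"]]
      status <- if (bb$completed) "search_exhaustive" else "budget_exhausted"
    }
  } else if (optimal) status <- "lower_bound_attained"
  med <- genome_from_partners(p, u, "median")
  per_leaf <- vapply(pls, function(pl) distance_partners(p, pl), integer(1L))
  names(per_leaf) <- labels
  structure(list(median = med, per_leaf = per_leaf,
                 total = as.integer(total),
                 lower = b[["lower"]], upper = b[["upper"]],
                 pairwise = pd, optimal = optimal,
                 nodes_explored = nodes, n_co_optimal = n_co,
                 status = status, labels = labels),
            class = "median_result")
}

#' @export
print.median_result <- function(x, ...) {
  cat(sprintf("DCJ median: total = %d (bounds %d..%d), %s\n", x$total,
              x$lower, x$upper,
              if (x$optimal) "optimal" else paste0("not certified (", x$status, ")")))
  cat("  per-leaf distances:",
      paste(sprintf("%s = %d", names(x$per_leaf), x$per_leaf),
            collapse = ", "), "\n")
  cat(sprintf("  median genome: %d chromosomes (%d circular)\n",
              length(x$median$chromosomes),
              sum(vapply(x$median$chromosomes, `[[`, logical(1L), "circular"))))
  invisible(x)
}

#' Verify a median result against its input genomes
#'
#' Recomputes per-leaf distances, the total and the bound sandwich from
#' scratch and reports any violated invariant.
#'
#' @param result A `median_result`.
#' @param g1,g2,g3 The three input genomes.
#' @return A `validation_report` with `ok` and `messages`.
#' @export
verify_median <- function(result, g1, g2, g3) {
  msgs <- character(0)
  gs <- list(g1, g2, g3)
  u <- marker_universe(c(gs, list(result$median)))
  per <- vapply(gs, function(g) dcj_distance(result$median, g), integer(1L))
  if (!all(per == unname(result$per_leaf)))
    msgs <- c(msgs, sprintf("per-leaf distances disagree: stored %s, recomputed %s",
                            paste(result$per_leaf, collapse = "/"),
                            paste(per, collapse = "/")))
  if (result$total != sum(per))
    msgs <- c(msgs, sprintf("total %d != sum of per-leaf distances %d",
                            result$total, sum(per)))
  b <- median_bounds(dcj_distance(g1, g2), dcj_distance(g2, g3),
                     dcj_distance(g1, g3))
  if (result$lower != b[["lower"]] || result$upper != b[["upper"]])
    msgs <- c(msgs, "stored bounds disagree with recomputed bounds")
  if (sum(per) < b[["lower"]])
    msgs <- c(msgs, "total below the lower bound: impossible state")
  if (result$optimal && !(b[["lower"]] <= result$total &&
                          result$total <= b[["upper"]]))
    msgs <- c(msgs, "optimal result outside the bound sandwich")
  structure(list(ok = length(msgs) == 0L, duplicated_ids = list(),
                 missing_ids = list(), messages = msgs, universe = u),
            class = "validation_report")
}
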