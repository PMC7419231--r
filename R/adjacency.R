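# ---------------------------------------------------------------------------
# Extremity encoding and the adjacency ("breakpoint") graph.
#
# Marker m contributes two extremities, its tail (m,t) and head (m,h).
# Internally extremities are coded against a sorted universe of n markers:
# the marker at universe index i has tail 2i-1 and head 2i.  A genome is then
# a partner vector p of length 2n: p[e] is the extremity adjacent to e, or 0
# when e is a telomere.  In user-facing operation records, extremities are
# coded by marker id instead (tail 2*id-1, head 2*id), which is stable across
# universes.
# ---------------------------------------------------------------------------

ext_other <- function(e) ifelse(e %% 2L == 1L, e + 1L, e - 1L)

ext_label <- function(code) {
  id <- (code + 1L) %/% 2L
  paste0(id, ifelse(code %% 2L == 1L, "t", "h"))
}

#' Extremity code for a marker end
#'
#' @param id Positive marker id.
#' @param side `"t"` (tail) or `"h"` (head).
#' @return Integer extremity code `2*id - 1` (tail) or `2*id` (head), the
#'   id-based coding used in [dcj_op()] records.
#' @export
extremity <- function(id, side = c("t", "h")) {
  side <- match.arg(side)
  id <- as.integer(id)
  stopifnot(all(id >= 1L))
  if (side == "t") 2L * id - 1L else 2L * id
}

# Partner vector of a genome against a sorted marker universe (index coding).
partner_vector <- function(g, universe) {
  n <- length(universe)
  p <- integer(2L * n)
  for (chr in g$chromosomes) {
    idx <- match(abs(chr$markers), universe)
    if (anyNA(idx))
      stop("genome '", g$label, "' contains markers outside the universe")
    pos <- sign(chr$markers) > 0
    left  <- ifelse(pos, 2L * idx - 1L, 2L * idx)      # extremity entered first
    right <- ifelse(pos, 2L * idx,      2L * idx - 1L) # extremity left last
    m <- length(idx)
    if (m > 1L) {
      a <- right[-m]; b <- left[-1L]
      p[a] <- b; p[b] <- a
    }
    if (chr$circular) {
      p[right[m]] <- left[1L]; p[left[1L]] <- right[m]
    }
  }
  p
}

# Convert id-based extremity codes to index coding for a given universe.
ext_id_to_index <- function(code, universe) {
  id <- (code + 1L) %/% 2L
  idx <- match(id, universe)
  if (anyNA(idx))
    stop("extremity refers to marker ", paste(id[is.na(idx)], collapse = ", "),
         " absent from the genome")
  2L * idx - (code %% 2L)
}

ext_index_to_id <- function(code, universe) {
  idx <- (code + 1L) %/% 2L
  2L * universe[idx] - (code %% 2L)
}

#' Adjacency/telomere set of a genome
#'
#' Decomposes a genome into its set of adjacencies (unordered pairs of
#' neighbouring marker extremities) and telomeres (chromosome-end
#' extremities).  A linear chromosome with m markers yields m - 1 adjacencies
#' and 2 telomeres; a circular one yields m adjacencies and none.
#'
#' @param g A `genome`.
#' @return An `adjacency_set`: list with `adjacencies` (two-column integer
#'   matrix of id-based extremity codes, rows sorted), `telomeres` (sorted
#'   integer vector) and `universe`.
#' @examples
#' adjacencies(genome("A", c(1, 2, 3)))
#' @export
adjacencies <- function(g) {
  u <- marker_universe(list(g))
  stop_unless_valid(list(g))
  p <- partner_vector(g, u)
  e <- which(p > 0L & p > seq_along(p))  # each adjacency once
  a1 <- ext_index_to_id(e, u); a2 <- ext_index_to_id(p[e], u)
  adj <- cbind(pmin(a1, a2), pmax(a1, a2))
  adj <- adj[order(adj[, 1L], adj[, 2L]), , drop = FALSE]
  colnames(adj) <- c("ext1", "ext2")
  telo <- sort(ext_index_to_id(which(p == 0L), u))
  structure(list(adjacencies = adj, telomeres = telo, universe = u,
                 label = g$label),
            class = "adjacency_set")
}

#' @export
print.adjacency_set <- function(x, ...) {
  cat(sprintf("Adjacency set of '%s': %d adjacencies, %d telomeres\n",
              x$label, nrow(x$adjacencies), length(x$telomeres)))
  if (nrow(x$adjacencies))
    cat("  adjacencies:",
        paste(ext_label(x$adjacencies[, 1L]), ext_label(x$adjacencies[, 2L]),
              sep = "-", collapse = " "), "\n")
  if (length(x$telomeres))
    cat("  telomeres:", paste(ext_label(x$telomeres), collapse = " "), "\n")
  invisible(x)
}

# Rebuild a genome from a partner vector (index coding).  Linear chromosomes
# are emitted starting from their smaller telomere extremity; circular ones
# from the tail of their smallest marker, so the representation is canonical.
genome_from_partners <- function(p, universe, label = "genome") {
  n <- length(universe)
  stopifnot(length(p) == 2L * n)
  visited <- logical(2L * n)
  chrs <- list()
  emit <- function(markers, circular) {
    chrs[[length(chrs) + 1L]] <<-
      new_chromosome(markers, name = paste0("chr", length(chrs) + 1L),
                     circular = circular)
  }
  for (s in which(p == 0L)) {
    if (visited[s]) next
    mk <- integer(0); e <- s
    repeat {
      visited[e] <- TRUE
      i <- (e + 1L) %/% 2L
      mk <- c(mk, if (e %% 2L == 1L) universe[i] else -universe[i])
      o <- ext_other(e); visited[o] <- TRUE
      if (p[o] == 0L) break
      e <- p[o]
    }
    emit(mk, FALSE)
  }
  for (s in seq_len(2L * n)) {
    if (visited[s]) next
    mk <- integer(0); e <- s
    repeat {
      visited[e] <- TRUE
      i <- (e + 1L) %/% 2L
      mk <- c(mk, if (e %% 2L == 1L) universe[i] else -universe[i])
      o <- ext_other(e); visited[o] <- TRUE
      if (p[o] == s) break
      e <- p[o]
    }
    emit(mk, TRUE)
  }
  new_genome(chrs, label)
}

#' Adjacency graph of two genomes
#'
#' Builds the component decomposition of the adjacency ("breakpoint") graph
#' of two genomes on the same marker universe: cycles, odd paths and even
#' paths, the quantities behind the DCJ distance
#' `d = N - (C + I/2)` with `N` markers, `C` cycles and `I` odd paths.
#'
#' @param a,b `genome` objects with identical marker content.
#' @return An `adjacency_graph`: list with `n_markers`, `n_cycles`,
#'   `n_odd_paths`, `n_even_paths` and `components` (list of lists with
#'   `type` and the member extremities in id coding).
#' @examples
#' build_adjacency_graph(genome("A", c(1, 2)), genome("B", c(1, -2)))
#' @export
build_adjacency_graph <- function(a, b) {
  rep <- validate_genome_set(list(a, b))
  if (!rep$ok)
    stop("genomes do not share a marker universe:\n",
         paste(rep$messages, collapse = "\n"))
  u <- rep$universe
  pa <- partner_vector(a, u); pb <- partner_vector(b, u)
  comps <- list()
  visited <- logical(2L * length(u))
  walk <- function(s, first_graph) {
    v <- integer(0); cur <- s; gph <- first_graph
    repeat {
      visited[cur] <<- TRUE
      v <- c(v, cur)
      nxt <- if (gph == 0L) pa[cur] else pb[cur]
      if (nxt == 0L || nxt == s) return(list(v = v, closed = nxt == s))
      cur <- nxt; gph <- 1L - gph
    }
  }
  for (s in seq_along(visited)) {
    if (visited[s] || (pa[s] != 0L && pb[s] != 0L)) next
    res <- walk(s, if (pa[s] == 0L) 1L else 0L)
    type <- if (length(res$v) %% 2L == 1L) "odd_path" else "even_path"
    comps[[length(comps) + 1L]] <-
      list(type = type, extremities = ext_index_to_id(res$v, u))
  }
  for (s in seq_along(visited)) {
    if (visited[s]) next
    res <- walk(s, 0L)
    comps[[length(comps) + 1L]] <-
      list(type = "cycle", extremities = ext_index_to_id(res$v, u))
  }
  types <- vapply(comps, `[[`, character(1L), "type")
  structure(list(n_markers = length(u),
                 n_cycles = sum(types == "cycle"),
                 n_odd_paths = sum(types == "odd_path"),
                 n_even_paths = sum(types == "even_path"),
                 components = comps,
                 labels = c(a$label, b$label)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf(
    "Adjacency graph %s vs %s: N = %d, cycles = %d, odd paths = %d, even paths = %d\n",
    x$labels[1L], x$labels[2L], x$n_markers, x$n_cycles, x$n_odd_paths,
    x$n_even_paths))
  cat(sprintf("DCJ distance = %d\n",
              x$n_markers - x$n_cycles - x$n_odd_paths %/% 2L))
  invisible(x)
}

# Distance on partner vectors (index coding); hot path in C++.
distance_partners <- function(pa, pb) {
  cnt <- ag_counts_cpp(pa, pb)
  length(pa) %/% 2L - cnt[1L] - cnt[2L] %/% 2L
}

#' DCJ genomic distance between two genomes
#'
#' The minimum number of double-cut-and-join operations (reversals,
#' translocations, fusions, fissions; a transposition counts as two)
#' transforming one genome into the other, computed from the adjacency graph
#' as `N - (C + I/2)`.
#'
#' @param a,b `genome` objects with identical marker content.
#' @return Non-negative integer distance.
#' @examples
#' dcj_distance(genome("A", c(1, 2, 3)), genome("B", c(1, -2, 3)))  # 1
#' @export
dcj_distance <- function(a, b) {
  rep <- validate_genome_set(list(a, b))
  if (!rep$ok)
    stop("genomes do not share a marker universe:\n",
         paste(rep$messages, collapse = "\n"))
  u <- rep$universe
  distance_partners(partner_vector(a, u), partner_vector(b, u))
}
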