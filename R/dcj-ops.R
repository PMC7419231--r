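# ---------------------------------------------------------------------------
# DCJ operations: cut up to two adjacencies/telomeres and rejoin the freed
# extremities differently.  An operation is recorded as the elements it
# consumes and produces; elements are integer vectors of id-based extremity
# codes, length 2 (adjacency) or 1 (telomere).
# ---------------------------------------------------------------------------

#' Construct a DCJ operation record
#'
#' @param consumed,produced Lists of integer vectors in id-based extremity
#'   coding (see [extremity()]): length-2 vectors are adjacencies, length-1
#'   vectors telomeres.  Consumed and produced must cover the same
#'   extremities.
#' @param kind Free-text descriptor (e.g. `"join"`, `"cut"`, `"reversal"`).
#' @return A `dcj_op` object.
#' @export
dcj_op <- function(consumed, produced, kind = "dcj") {
  norm <- function(els) {
    els <- lapply(els, function(e) sort(as.integer(e)))
    lens <- lengths(els)
    if (any(lens < 1L | lens > 2L))
      stop("operation elements must be telomeres (1 extremity) or adjacencies (2)")
    els
  }
  consumed <- norm(consumed); produced <- norm(produced)
  ec <- sort(unlist(consumed)); ep <- sort(unlist(produced))
  if (!identical(ec, ep))
    stop("consumed and produced elements must cover the same extremities")
  if (anyDuplicated(ec))
    stop("an extremity may appear in at most one consumed element")
  structure(list(kind = kind, consumed = consumed, produced = produced),
            class = "dcj_op")
}

format_element <- function(e) paste(ext_label(e), collapse = "-")

#' @export
print.dcj_op <- function(x, ...) {
  cat(sprintf("DCJ op [%s]: {%s} -> {%s}\n", x$kind,
              paste(vapply(x$consumed, format_element, character(1L)),
                    collapse = ", "),
              paste(vapply(x$produced, format_element, character(1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a DCJ operation to a genome
#'
#' @param g A validated `genome`.
#' @param op A [dcj_op()]; its consumed adjacencies/telomeres must be present
#'   in `g`.
#' @return The rearranged `genome` (canonical chromosome representation; at
#'   DCJ distance at most 1 from `g`).
#' @examples
#' op <- dcj_op(consumed = list(c(extremity(1, "h"), extremity(2, "t")),
#'                              c(extremity(2, "h"), extremity(3, "t"))),
#'              produced = list(c(extremity(1, "h"), extremity(2, "h")),
#'                              c(extremity(2, "t"), extremity(3, "t"))),
#'              kind = "reversal")
#' apply_dcj(genome("A", c(1, 2, 3)), op)  # 1 -2 3
#' @export
apply_dcj <- function(g, op) {
  stopifnot(inherits(op, "dcj_op"))
  u <- marker_universe(list(g))
  stop_unless_valid(list(g))
  p <- partner_vector(g, u)
  for (el in op$consumed) {
    e <- ext_id_to_index(el, u)
    if (length(e) == 2L) {
      if (p[e[1L]] != e[2L])
        stop("adjacency ", format_element(el), " not present in genome '",
             g$label, "'")
      p[e] <- 0L
    } else {
      if (p[e] != 0L)
        stop("extremity ", format_element(el), " is not a telomere in genome '",
             g$label, "'")
    }
  }
  for (el in op$produced) {
    e <- ext_id_to_index(el, u)
    if (length(e) == 2L) {
      p[e[1L]] <- e[2L]; p[e[2L]] <- e[1L]
    }
  }
  genome_from_partners(p, u, g$label)
}

#' Optimal DCJ sorting scenario
#'
#' Extracts an ordered list of DCJ operations of length `dcj_distance(a, b)`
#' whose replay on `a` yields a genome equal to `b`.  Target adjacencies are
#' processed in lexicographic order of their extremity codes, so the scenario
#' is deterministic.
#'
#' @param a,b `genome` objects with identical marker content.
#' @return List of [dcj_op()] objects (empty when the genomes are equal).
#' @examples
#' sorting_scenario(genome("A", c(1, 2, 3)), genome("B", c(1, -2, 3)))
#' @export
sorting_scenario <- function(a, b) {
  rep <- validate_genome_set(list(a, b))
  if (!rep$ok)
    stop("genomes do not share a marker universe:\n",
         paste(rep$messages, collapse = "\n"))
  u <- rep$universe
  sort_partners(partner_vector(a, u), partner_vector(b, u), u)
}

# Partner-vector core of scenario extraction; kinds label the emitted ops.
sort_partners <- function(pa, pb, u, kind_join = "join", kind_cut = "cut") {
  ops <- list()
  record <- function(consumed, produced, kind) {
    ops[[length(ops) + 1L]] <<- dcj_op(
      lapply(consumed, ext_index_to_id, universe = u),
      lapply(produced, ext_index_to_id, universe = u),
      kind = kind)
  }
  # join stage: realise every target adjacency, lexicographically
  tgt <- which(pb > 0L & pb > seq_along(pb))
  for (e in tgt) {
    f <- pb[e]
    if (pa[e] == f) next
    uu <- pa[e]; vv <- pa[f]
    consumed <- list(if (uu > 0L) c(e, uu) else e,
                     if (vv > 0L) c(f, vv) else f)
    produced <- list(c(e, f))
    pa[e] <- f; pa[f] <- e
    if (uu > 0L && vv > 0L) {
      pa[uu] <- vv; pa[vv] <- uu
      produced <- c(produced, list(c(uu, vv)))
    } else if (uu > 0L) {
      pa[uu] <- 0L; produced <- c(produced, list(uu))
    } else if (vv > 0L) {
      pa[vv] <- 0L; produced <- c(produced, list(vv))
    }
    record(consumed, produced, kind_join)
  }
  # cut stage: break adjacencies whose extremities are telomeres in b
  for (e in which(pb == 0L)) {
    if (pa[e] > 0L) {
      f <- pa[e]
      pa[e] <- 0L; pa[f] <- 0L
      record(list(c(e, f)), list(e, f), kind_cut)
    }
  }
  stopifnot(identical(pa, pb))
  ops
}
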