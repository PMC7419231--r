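#' @useDynLib dcjmedian, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm pchisq quantile rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Signed block-order genomes.
#
# A chromosome is an ordered vector of signed integer marker (block) ids; a
# genome is a labelled list of chromosomes.  All rearrangement arithmetic
# needs only order, sign and topology (linear/circular) -- base-pair
# coordinates live in block tables, not here.
# ---------------------------------------------------------------------------

#' Construct a chromosome
#'
#' @param markers Integer vector of signed, non-zero marker ids; the sign
#'   encodes orientation.
#' @param name Chromosome name.
#' @param circular Logical; circular chromosomes close the terminal adjacency.
#' @return An object of class `chromosome`.
#' @export
new_chromosome <- function(markers, name = "chr1", circular = FALSE) {
  markers <- as.integer(markers)
  if (length(markers) == 0L)
    stop("a chromosome must contain at least one marker")
  if (anyNA(markers) || any(markers == 0L))
    stop("marker ids must be non-zero integers (sign = orientation)")
  structure(list(name = as.character(name)[1L],
                 markers = markers,
                 circular = isTRUE(circular)),
            class = "chromosome")
}

#' Construct a genome from marker vectors
#'
#' Convenience constructor: `genome("A", c(1, 2, 3), c(4, -5))` builds a
#' two-chromosome genome.  A single list of vectors (or of `chromosome`
#' objects) is also accepted.
#'
#' @param label Genome label.
#' @param ... Signed marker vectors or `chromosome` objects, one per
#'   chromosome; alternatively a single list of them.
#' @param circular Default topology for chromosomes given as bare vectors.
#' @return An object of class `genome`.
#' @examples
#' g <- genome("A", c(1, 2, 3), c(4, -5))
#' @export
genome <- function(label, ..., circular = FALSE) {
  chrs <- list(...)
  if (length(chrs) == 1L && is.list(chrs[[1L]]) &&
      !inherits(chrs[[1L]], "chromosome"))
    chrs <- chrs[[1L]]
  out <- vector("list", length(chrs))
  for (i in seq_along(chrs)) {
    ci <- chrs[[i]]
    out[[i]] <- if (inherits(ci, "chromosome")) ci else
      new_chromosome(ci, name = paste0("chr", i), circular = circular)
  }
  new_genome(out, label)
}

#' Construct a genome from chromosome objects
#'
#' @param chromosomes Non-empty list of `chromosome` objects.
#' @param label Genome label.
#' @return An object of class `genome`.
#' @export
new_genome <- function(chromosomes, label) {
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    stop("a genome must contain at least one chromosome")
  if (!all(vapply(chromosomes, inherits, logical(1L), "chromosome")))
    stop("all elements must be chromosome objects")
  nms <- vapply(chromosomes, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate chromosome names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(label = as.character(label)[1L], chromosomes = chromosomes),
            class = "genome")
}

#' Marker ids present in a genome (unsigned, in genome order)
#' @param g A `genome`.
#' @return Integer vector of absolute marker ids, one per occurrence.
#' @export
marker_ids <- function(g) {
  abs(unlist(lapply(g$chromosomes, `[[`, "markers"), use.names = FALSE))
}

#' Shared marker universe of a genome set
#' @param genomes List of `genome` objects.
#' @return Sorted integer vector of all marker ids seen in any genome.
#' @export
marker_universe <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  sort(unique(unlist(lapply(genomes, marker_ids), use.names = FALSE)))
}

#' Validate a genome set for rearrangement analysis
#'
#' Every DCJ computation requires equal marker content: each genome must
#' contain every marker of the shared universe exactly once.
#'
#' @param genomes List of `genome` objects (length >= 1).
#' @return A `validation_report`: list with `ok`, `duplicated_ids`,
#'   `missing_ids` (named by genome) and `messages`.
#' @examples
#' validate_genome_set(list(genome("A", c(1, 2, 3)), genome("B", c(3, 1, 2))))
#' @export
validate_genome_set <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  if (length(genomes) < 1L) stop("need at least one genome")
  universe <- marker_universe(genomes)
  dup <- list(); mis <- list(); msgs <- character(0)
  for (g in genomes) {
    ids <- marker_ids(g)
    d <- sort(unique(ids[duplicated(ids)]))
    m <- setdiff(universe, ids)
    if (length(d)) {
      dup[[g$label]] <- d
      msgs <- c(msgs, sprintf("genome '%s': duplicated marker ids: %s",
                              g$label, paste(d, collapse = ", ")))
    }
    if (length(m)) {
      mis[[g$label]] <- m
      msgs <- c(msgs, sprintf("genome '%s': missing marker ids: %s",
                              g$label, paste(m, collapse = ", ")))
    }
  }
  structure(list(ok = length(dup) == 0L && length(mis) == 0L,
                 duplicated_ids = dup, missing_ids = mis,
                 messages = msgs, universe = universe),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "Genome set OK" else "Genome set INVALID",
      sprintf(" (%d markers in universe)\n", length(x$universe)))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

stop_unless_valid <- function(genomes) {
  rep <- validate_genome_set(genomes)
  if (!rep$ok)
    stop("invalid genome set:\n", paste(rep$messages, collapse = "\n"))
  invisible(rep)
}

#' Test two genomes for equality up to representation
#'
#' Equality is defined on adjacency/telomere sets, so it is invariant to
#' chromosome order, chromosome names, and flipping a whole chromosome
#' (reverse the marker list and negate all signs).
#'
#' @param a,b `genome` objects.
#' @return Logical scalar.
#' @export
genomes_equal <- function(a, b) {
  ua <- marker_universe(list(a)); ub <- marker_universe(list(b))
  if (!identical(ua, ub)) return(FALSE)
  identical(partner_vector(a, ua), partner_vector(b, ua))
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("%s%s: %s\n", x$name, if (x$circular) " (circular)" else "",
              paste(x$markers, collapse = " ")))
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d chromosomes, %d markers\n", x$label,
              length(x$chromosomes), length(marker_ids(x))))
  for (chr in x$chromosomes) print(chr)
  invisible(x)
}
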