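# ---------------------------------------------------------------------------
# Synteny blocks from a three-genome orthologue ("syntelog") table: sparse
# dynamic-programming chaining of collinear anchors per chromosome pair
# (DAGChainer-style), intersection of the two reference-anchored chain
# partitions into shared blocks, signed block-order genomes, and ancestral
# chromosome painting.
# ---------------------------------------------------------------------------

#' Chaining parameters
#'
#' @param max_gap_genes Maximum number of intervening genes tolerated, in
#'   either genome, between consecutive anchors of a chain.  The default of
#'   10 accommodates the gene losses left by heavy post-polyploid
#'   fractionation (see the package vignette).
#' @param min_anchors Minimum anchors per chain/block (>= 2).
#' @param max_gap_bp Optional cap on the base-pair gap between consecutive
#'   anchors.
#' @param gap_penalty Score penalty per skipped gene in the chain DP.
#' @return A `chain_params` list.
#' @export
chain_params <- function(max_gap_genes = 10L, min_anchors = 3L,
                         max_gap_bp = NULL, gap_penalty = 0.05) {
  stopifnot(min_anchors >= 2L, max_gap_genes >= 0L,
            is.null(max_gap_bp) || max_gap_bp >= 0)
  structure(list(max_gap_genes = as.integer(max_gap_genes),
                 min_anchors = as.integer(min_anchors),
                 max_gap_bp = max_gap_bp, gap_penalty = gap_penalty),
            class = "chain_params")
}

check_syntelog_table <- function(table) {
  need <- c("family_id", "genome", "chromosome", "start_bp", "end_bp",
            "strand")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("syntelog table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$start_bp > table$end_bp))
    stop("start_bp must not exceed end_bp")
  if (!all(table$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!"order_index" %in% names(table)) {
    table <- table[order(table$genome, table$chromosome, table$start_bp), ,
                   drop = FALSE]
    table$order_index <- stats::ave(
      seq_len(nrow(table)), table$genome, table$chromosome,
      FUN = seq_along)
  }
  table
}

# families with exactly one row in each of the given genomes
single_copy_families <- function(table, genomes) {
  sub <- table[table$genome %in% genomes, , drop = FALSE]
  cnt <- table(sub$family_id, sub$genome)
  ok <- rownames(cnt)[apply(cnt == 1L, 1L, all)]
  list(families = ok,
       dropped = setdiff(unique(sub$family_id), ok))
}

# best chain (score, indices) among anchors sorted by ia; orientation fixes
# the required direction of ib
chain_dp <- function(ia, ib, ga, gb, orientation, params) {
  m <- length(ia)
  score <- rep(1, m); prev <- rep(0L, m)
  for (i in seq_len(m)[-1L]) {
    js <- seq_len(i - 1L)
    da <- ia[i] - ia[js] - 1L
    db <- if (orientation > 0) ib[i] - ib[js] - 1L else ib[js] - ib[i] - 1L
    okg <- da >= 0L & da <= params$max_gap_genes &
           db >= 0L & db <= params$max_gap_genes
    if (!is.null(params$max_gap_bp))
      okg <- okg & (ga[i] - ga[js] <= params$max_gap_bp) &
                   (abs(gb[i] - gb[js]) <= params$max_gap_bp)
    if (any(okg)) {
      cand <- score[js] - params$gap_penalty * (da + db)
      cand[!okg] <- -Inf
      jbest <- which.max(cand)
      if (cand[jbest] > 0) {
        score[i] <- 1 + cand[jbest]
        prev[i] <- jbest
      }
    }
  }
  ibest <- which.max(score)
  path <- integer(0); i <- ibest
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  list(score = score[ibest], path = path)
}

#' Chain collinear anchors between two genomes
#'
#' Greedy best-chain extraction over a sparse dynamic programme on anchor
#' pairs, run per chromosome pair and per orientation: each chain is a run of
#' anchors strictly monotone in both genomes' gene order (increasing or, for
#' `-` chains, decreasing in genome B), with at most `max_gap_genes`
#' intervening genes tolerated between consecutive anchors and a score of
#' anchors minus a per-gap penalty.  Each anchor joins at most one chain.
#'
#' @param table Syntelog table (`family_id`, `genome`, `chromosome`,
#'   `start_bp`, `end_bp`, `strand`; `order_index` is derived from
#'   coordinates when absent).
#' @param genome_a,genome_b Genome labels present in the table.
#' @param params A [chain_params()].
#' @return `data.frame` with one row per chained anchor: `chain_id`,
#'   `orientation`, `family_id`, per-genome chromosome and order index.
#' @export
chain_pairwise <- function(table, genome_a, genome_b, params = chain_params()) {
  table <- check_syntelog_table(table)
  for (g in c(genome_a, genome_b))
    if (!g %in% table$genome) stop("unknown genome label '", g, "'")
  fams <- single_copy_families(table, c(genome_a, genome_b))$families
  ta <- table[table$genome == genome_a & table$family_id %in% fams, ,
              drop = FALSE]
  tb <- table[table$genome == genome_b & table$family_id %in% fams, ,
              drop = FALSE]
  ord <- match(ta$family_id, tb$family_id)
  anchors <- data.frame(
    family_id = ta$family_id,
    chrom_a = ta$chromosome, idx_a = ta$order_index, bp_a = ta$start_bp,
    strand_a = ta$strand,
    chrom_b = tb$chromosome[ord], idx_b = tb$order_index[ord],
    bp_b = tb$start_bp[ord], strand_b = tb$strand[ord],
    stringsAsFactors = FALSE)
  out <- list(); chain_id <- 0L
  for (ca in sort(unique(anchors$chrom_a))) {
    for (cb in sort(unique(anchors$chrom_b[anchors$chrom_a == ca]))) {
      pool <- anchors[anchors$chrom_a == ca & anchors$chrom_b == cb, ,
                      drop = FALSE]
      pool <- pool[order(pool$idx_a), , drop = FALSE]
      repeat {
        if (nrow(pool) < params$min_anchors) break
        best <- NULL
        for (o in c(1L, -1L)) {
          r <- chain_dp(pool$idx_a, pool$idx_b, pool$bp_a, pool$bp_b, o,
                        params)
          if (is.null(best) || r$score > best$score)
            best <- c(r, orientation = o)
        }
        if (length(best$path) < params$min_anchors) break
        chain_id <- chain_id + 1L
        hit <- pool[best$path, , drop = FALSE]
        hit$chain_id <- chain_id
        hit$orientation <- if (best$orientation > 0) "+" else "-"
        out[[length(out) + 1L]] <- hit
        pool <- pool[-best$path, , drop = FALSE]
      }
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(0), chain_id = integer(0),
                      orientation = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chain_id, res$idx_a),
      c("chain_id", "orientation", "family_id", "chrom_a", "idx_a", "bp_a",
        "strand_a", "chrom_b", "idx_b", "bp_b", "strand_b")]
}

#' Build shared synteny blocks across three genomes
#'
#' Anchors are families with exactly one copy in each of the three genomes
#' (unresolved paralogues are dropped and counted).  The first genome label
#' (alphabetically) serves as reference; the table is chained reference vs
#' each other genome, and blocks are maximal runs of reference-consecutive
#' anchors lying in the same chain of both partitions -- i.e. collinear in
#' all three genomes.  Per-genome block orientation is the majority strand
#' agreement with the reference.
#'
#' @param table Syntelog table with exactly three genome labels.
#' @param params A [chain_params()].
#' @return A `block_set`: `blocks` (long data.frame: `block_id`, `genome`,
#'   `chromosome`, `start_bp`, `end_bp`, `orientation`, `n_anchors`),
#'   `members` (family ids per block), `universe_size`, `ref_genome`,
#'   `dropped_families`.
#' @export
build_blocks <- function(table, params = chain_params()) {
  table <- check_syntelog_table(table)
  labs <- sort(unique(table$genome))
  if (length(labs) != 3L)
    stop("need exactly three genomes, got ", length(labs), ": ",
         paste(labs, collapse = ", "))
  sc <- single_copy_families(table, labs)
  tab <- table[table$family_id %in% sc$families, , drop = FALSE]
  ref <- labs[1L]
  ch2 <- chain_pairwise(tab, ref, labs[2L], params)
  ch3 <- chain_pairwise(tab, ref, labs[3L], params)
  fams <- intersect(ch2$family_id, ch3$family_id)
  if (!length(fams))
    stop("no three-way collinear anchors found")
  tref <- tab[tab$genome == ref & tab$family_id %in% fams, , drop = FALSE]
  tref <- tref[order(tref$chromosome, tref$order_index), , drop = FALSE]
  c2 <- ch2$chain_id[match(tref$family_id, ch2$family_id)]
  c3 <- ch3$chain_id[match(tref$family_id, ch3$family_id)]
  grp <- cumsum(c(TRUE, c2[-1L] != c2[-length(c2)] |
                        c3[-1L] != c3[-length(c3)]))
  blocks <- list(); members <- list(); bid <- 0L
  for (g in unique(grp)) {
    fam <- tref$family_id[grp == g]
    if (length(fam) < params$min_anchors) next
    bid <- bid + 1L
    members[[as.character(bid)]] <- fam
    for (lab in labs) {
      rows <- tab[tab$genome == lab & tab$family_id %in% fam, , drop = FALSE]
      ori <- if (lab == ref) "+" else {
        rref <- tab[tab$genome == ref & tab$family_id %in% fam, , drop = FALSE]
        agree <- rows$strand[match(rref$family_id, rows$family_id)] ==
          rref$strand
        if (mean(agree) >= 0.5) "+" else "-"
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = bid, genome = lab,
        chromosome = rows$chromosome[1L],
        start_bp = min(rows$start_bp), end_bp = max(rows$end_bp),
        orientation = ori, n_anchors = length(fam),
        stringsAsFactors = FALSE)
    }
  }
  if (bid == 0L) stop("no block met the min_anchors threshold")
  structure(list(blocks = do.call(rbind, blocks), members = members,
                 universe_size = bid, ref_genome = ref,
                 dropped_families = sc$dropped, params = params),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("Block set: %d blocks across %s (reference %s); %d families dropped as non-1:1:1\n",
              x$universe_size,
              paste(unique(x$blocks$genome), collapse = "/"),
              x$ref_genome, length(x$dropped_families)))
  invisible(x)
}

#' Convert a block set to signed block-order genomes
#'
#' Per genome, blocks are sorted by chromosome and start coordinate and
#' emitted as signed markers (sign = orientation relative to the reference).
#'
#' @param bs A `block_set` whose blocks are placed in all three genomes.
#' @return Named list of three validated `genome` objects.
#' @export
blocks_to_genomes <- function(bs) {
  stopifnot(inherits(bs, "block_set"))
  labs <- sort(unique(bs$blocks$genome))
  out <- list()
  for (lab in labs) {
    sub <- bs$blocks[bs$blocks$genome == lab, , drop = FALSE]
    missing <- setdiff(seq_len(bs$universe_size), sub$block_id)
    if (length(missing))
      stop("blocks missing in genome '", lab, "': ",
           paste(missing, collapse = ", "))
    sub <- sub[order(sub$chromosome, sub$start_bp), , drop = FALSE]
    chrs <- list()
    for (cn in unique(sub$chromosome)) {
      rows <- sub[sub$chromosome == cn, , drop = FALSE]
      mk <- rows$block_id * ifelse(rows$orientation == "+", 1L, -1L)
      chrs[[length(chrs) + 1L]] <- new_chromosome(mk, name = cn)
    }
    out[[lab]] <- new_genome(chrs, lab)
  }
  stop_unless_valid(out)
  out
}

#' Paint extant blocks by ancestral chromosome
#'
#' Assigns every per-genome block placement the chromosome of the median
#' (ancestral) genome carrying its block id -- the mapping behind
#' ancestral-karyotype "painting" figures.
#'
#' @param bs A `block_set`.
#' @param median A `genome` whose marker universe equals the block ids.
#' @return `data.frame` (`genome`, `chromosome`, `start_bp`, `end_bp`,
#'   `block_id`, `orientation`, `ancestral_chromosome`), one row per
#'   per-genome placement.
#' @export
paint_ancestral <- function(bs, median) {
  stopifnot(inherits(bs, "block_set"))
  u <- marker_universe(list(median))
  if (!identical(u, sort(unique(bs$blocks$block_id))))
    stop("median marker universe does not match the block ids")
  anc <- character(max(u))
  for (chr in median$chromosomes)
    anc[abs(chr$markers)] <- chr$name
  out <- bs$blocks[, c("genome", "chromosome", "start_bp", "end_bp",
                       "block_id", "orientation")]
  out$ancestral_chromosome <- anc[out$block_id]
  out[order(out$genome, out$chromosome, out$start_bp), , drop = FALSE]
}

#' Write a painting table as BED-like text
#'
#' Columns: chrom, 0-based start, end, block id, score 0, strand, ancestral
#' chromosome; one file section per genome is distinguished by the name
#' prefix `genome:chromosome`.
#'
#' @param painting Output of [paint_ancestral()].
#' @param path Output path.
#' @export
write_painting_bed <- function(painting, path) {
  bed <- data.frame(chrom = paste(painting$genome, painting$chromosome,
                                  sep = ":"),
                    start = painting$start_bp - 1L,
                    end = painting$end_bp,
                    name = paste0("block_", painting$block_id),
                    score = 0L,
                    strand = painting$orientation,
                    ancestral_chromosome = painting$ancestral_chromosome)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
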