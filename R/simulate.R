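# ---------------------------------------------------------------------------
# Ground-truthed simulation of rearrangement histories: a random ancestor of
# signed blocks on linear chromosomes, three descendants produced by sampled
# rearrangement events (reversal, translocation, fusion, fission;
# transposition applied as two DCJs), block-level fractionation into a
# syntelog table, and ln(Ks) mixture samples.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

derive_seed <- function(seed, k) as.integer((seed + k * 7919) %% 2147483647L)

#' Simulation configuration
#'
#' Defaults mirror the study conditions the package is built around: an
#' ancestor of 50 blocks on 8 linear chromosomes; two short and one long
#' branch (5/5/15 events) mimicking the asymmetric outgroup lineage;
#' subgenome-style retention rates of 70/49/42 per cent; mostly
#' intrachromosomal inversions.
#'
#' @param n_blocks Number of ancestral blocks (markers).
#' @param n_chromosomes Number of ancestral linear chromosomes.
#' @param branch_ops Integer vector of three rearrangement-event counts.
#' @param op_weights Named sampling weights for `reversal`, `translocation`,
#'   `fusion`, `fission`, `transposition`; normalised internally.
#' @param retention Per-genome probability that a gene survives
#'   fractionation.
#' @param genes_per_block Gene families per ancestral block.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_blocks = 50L, n_chromosomes = 8L,
                       branch_ops = c(5L, 5L, 15L),
                       op_weights = c(reversal = 0.6, translocation = 0.2,
                                      fusion = 0.05, fission = 0.05,
                                      transposition = 0.1),
                       retention = c(0.70, 0.49, 0.42),
                       genes_per_block = 60L,
                       seed = 1L) {
  stopifnot(n_blocks >= 1L, n_chromosomes >= 1L,
            n_chromosomes <= n_blocks,
            length(branch_ops) == 3L, all(branch_ops >= 0L),
            length(retention) == 3L, all(retention > 0), all(retention <= 1),
            genes_per_block >= 2L)
  kinds <- c("reversal", "translocation", "fusion", "fission", "transposition")
  if (!all(names(op_weights) %in% kinds) || any(op_weights < 0) ||
      sum(op_weights) <= 0)
    stop("op_weights must be non-negative weights over ", paste(kinds, collapse = "/"))
  w <- setNames(numeric(length(kinds)), kinds)
  w[names(op_weights)] <- op_weights
  structure(list(n_blocks = as.integer(n_blocks),
                 n_chromosomes = as.integer(n_chromosomes),
                 branch_ops = as.integer(branch_ops),
                 op_weights = w / sum(w),
                 retention = retention,
                 genes_per_block = as.integer(genes_per_block),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random ancestral genome
#'
#' @param cfg A [sim_config()].
#' @return A `genome` labelled `"ancestor"` with `n_blocks` randomly signed
#'   markers in random order over `n_chromosomes` linear chromosomes.
#' @export
simulate_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_blocks; k <- cfg$n_chromosomes
    perm <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
    cuts <- if (k > 1L) sort(sample.int(n - 1L, k - 1L)) else integer(0)
    bounds <- c(0L, cuts, n)
    chrs <- lapply(seq_len(k), function(i)
      new_chromosome(perm[(bounds[i] + 1L):bounds[i + 1L]],
                     name = paste0("A", i)))
    new_genome(chrs, "ancestor")
  })
}

# -- structural proposals on a working chromosome list ----------------------
# work: list of list(markers=, circular=); linear only are eligible for
# translocation cuts; proposals return the new list or NULL if inapplicable.

propose_reversal <- function(work) {
  sizes <- lengths(lapply(work, `[[`, "markers"))
  w <- sizes * (sizes + 1) / 2
  k <- sample.int(length(work), 1L, prob = w)
  m <- sizes[k]
  i <- sample.int(m, 1L, prob = m:1)
  j <- if (i == m) m else i + sample.int(m - i + 1L, 1L) - 1L
  if (i == 1L && j == m) return(NULL)  # whole-chromosome flip is a no-op
  mk <- work[[k]]$markers
  mk[i:j] <- -rev(mk[i:j])
  work[[k]]$markers <- mk
  attr(work, "params") <- list(chrom = k, from = i, to = j)
  work
}

propose_translocation <- function(work) {
  lin <- which(!vapply(work, `[[`, logical(1L), "circular"))
  if (length(lin) < 2L) return(NULL)
  ks <- sample(lin, 2L)
  A <- work[[ks[1L]]]$markers; B <- work[[ks[2L]]]$markers
  i <- sample.int(length(A) + 1L, 1L) - 1L
  j <- sample.int(length(B) + 1L, 1L) - 1L
  variant <- sample.int(2L, 1L)
  if (variant == 1L) {
    n1 <- c(A[seq_len(i)], B[seq_len(length(B) - j) + j])
    n2 <- c(B[seq_len(j)], A[seq_len(length(A) - i) + i])
  } else {
    n1 <- c(A[seq_len(i)], -rev(B[seq_len(j)]))
    n2 <- c(-rev(A[seq_len(length(A) - i) + i]), B[seq_len(length(B) - j) + j])
  }
  if (!length(n1) || !length(n2)) return(NULL)
  work[[ks[1L]]]$markers <- n1
  work[[ks[2L]]]$markers <- n2
  attr(work, "params") <- list(chroms = ks, cut_a = i, cut_b = j,
                               variant = variant)
  work
}

propose_fusion <- function(work) {
  lin <- which(!vapply(work, `[[`, logical(1L), "circular"))
  if (length(lin) < 2L) return(NULL)
  ks <- sample(lin, 2L)
  A <- work[[ks[1L]]]$markers; B <- work[[ks[2L]]]$markers
  combo <- sample.int(4L, 1L)
  joined <- switch(combo,
                   c(A, B), c(A, -rev(B)), c(-rev(A), B), c(-rev(A), -rev(B)))
  work[[ks[1L]]]$markers <- joined
  work[[ks[2L]]] <- NULL
  attr(work, "params") <- list(chroms = ks, combo = combo)
  work
}

propose_fission <- function(work) {
  sizes <- lengths(lapply(work, `[[`, "markers"))
  elig <- which(sizes >= 2L & !vapply(work, `[[`, logical(1L), "circular"))
  if (!length(elig)) return(NULL)
  k <- if (length(elig) == 1L) elig else
    sample(elig, 1L, prob = sizes[elig] - 1L)
  m <- sizes[k]
  i <- sample.int(m - 1L, 1L)
  mk <- work[[k]]$markers
  work[[k]]$markers <- mk[seq_len(i)]
  work[[length(work) + 1L]] <- list(markers = mk[(i + 1L):m], circular = FALSE)
  attr(work, "params") <- list(chrom = k, at = i)
  work
}

# transposition = excision of a segment plus reinsertion elsewhere (two DCJs)
propose_transposition <- function(work) {
  sizes <- lengths(lapply(work, `[[`, "markers"))
  if (sum(sizes) < 2L) return(NULL)
  k <- sample.int(length(work), 1L, prob = sizes)
  m <- sizes[k]
  i <- sample.int(m, 1L, prob = m:1)
  j <- if (i == m) m else i + sample.int(m - i + 1L, 1L) - 1L
  seg <- work[[k]]$markers[i:j]
  rest <- work[[k]]$markers[-(i:j)]
  work2 <- work
  if (length(rest)) work2[[k]]$markers <- rest else {
    if (length(work2) == 1L) return(NULL)  # nowhere to reinsert
    work2[[k]] <- NULL
  }
  tgt <- sample.int(length(work2), 1L)
  mt <- length(work2[[tgt]]$markers)
  pos <- sample.int(mt + 1L, 1L) - 1L
  flip <- sample(c(FALSE, TRUE), 1L)
  if (flip) seg <- -rev(seg)
  work2[[tgt]]$markers <- append(work2[[tgt]]$markers, seg, after = pos)
  attr(work2, "params") <- list(chrom = k, from = i, to = j, target = tgt,
                                at = pos, flip = flip)
  work2
}

work_from_genome <- function(g)
  lapply(g$chromosomes, function(chr)
    list(markers = chr$markers, circular = chr$circular))

genome_from_work <- function(work, label)
  new_genome(lapply(seq_along(work), function(i)
    new_chromosome(work[[i]]$markers, name = paste0("chr", i),
                   circular = work[[i]]$circular)), label)

#' Evolve a genome by random rearrangement events
#'
#' Samples `n_ops` events from `weights`; an inapplicable or no-op proposal
#' (e.g. a whole-chromosome flip, or a fission on a single-marker genome) is
#' resampled and counted.  Each logged event carries the DCJ operations (one,
#' or two for a transposition) realising it, so the log replays exactly with
#' [replay_ops()].
#'
#' @param g Starting `genome`.
#' @param n_ops Number of events.
#' @param weights Named event weights (see [sim_config()]).
#' @param seed Integer seed.
#' @return List with `genome`, `op_log` (length `n_ops`; each entry has
#'   `kind`, `params`, `ops`, `dcj_cost`) and `n_resampled`.
#' @export
evolve_genome <- function(g, n_ops, weights = sim_config()$op_weights,
                          seed = 1L) {
  stopifnot(n_ops >= 0L)
  u <- marker_universe(list(g))
  stop_unless_valid(list(g))
  with_seed(seed, {
    work <- work_from_genome(g)
    p_cur <- partner_vector(genome_from_work(work, g$label), u)
    op_log <- vector("list", n_ops)
    n_resampled <- 0L
    kinds <- names(weights)
    for (t in seq_len(n_ops)) {
      repeat {
        kind <- sample(kinds, 1L, prob = weights)
        cand <- switch(kind,
                       reversal = propose_reversal(work),
                       translocation = propose_translocation(work),
                       fusion = propose_fusion(work),
                       fission = propose_fission(work),
                       transposition = propose_transposition(work))
        if (!is.null(cand)) {
          p_new <- partner_vector(genome_from_work(cand, g$label), u)
          if (!identical(p_new, p_cur)) break
        }
        n_resampled <- n_resampled + 1L
        if (n_resampled > 1000L * max(n_ops, 1L))
          stop("could not sample an applicable operation")
      }
      ops <- event_dcj_ops(p_cur, p_new, u, kind)
      op_log[[t]] <- list(kind = kind, params = attr(cand, "params"),
                          ops = ops, dcj_cost = length(ops))
      attr(cand, "params") <- NULL
      work <- cand
      p_cur <- p_new
    }
    list(genome = genome_from_work(work, g$label), op_log = op_log,
         n_resampled = n_resampled)
  })
}

# Decompose the partner-vector change of one event into single DCJs via an
# optimal sorting scenario (one op for the primitive events, two for a
# transposition).
event_dcj_ops <- function(p_from, p_to, universe, kind)
  sort_partners(p_from, p_to, universe, kind_join = kind, kind_cut = kind)

#' Replay a logged operation sequence
#'
#' Applies, in order, every DCJ operation of every event in `op_log` via
#' [apply_dcj()].
#'
#' @param g Starting `genome`.
#' @param op_log Event list as produced by [evolve_genome()].
#' @return The resulting `genome`.
#' @export
replay_ops <- function(g, op_log) {
  for (entry in op_log)
    for (op in entry$ops)
      g <- apply_dcj(g, op)
  g
}

#' Simulate an ancestor and three descendant genomes
#'
#' The ancestor evolves independently along three branches with
#' `cfg$branch_ops` event counts (default 5/5/15: two close ingroup genomes
#' and one rearrangement-rich outgroup lineage).
#'
#' @param cfg A [sim_config()].
#' @return A `truth_set`: list with `ancestor`, `leaves` (named list `A`,
#'   `B`, `C`), `op_logs`, `branch_ops` and `config`.
#' @export
simulate_triple <- function(cfg = sim_config()) {
  anc <- simulate_ancestor(cfg)
  labels <- c("A", "B", "C")
  leaves <- list(); logs <- list()
  for (i in 1:3) {
    ev <- evolve_genome(anc, cfg$branch_ops[i], cfg$op_weights,
                        seed = derive_seed(cfg$seed, 10L + i))
    gi <- ev$genome; gi$label <- labels[i]
    leaves[[labels[i]]] <- gi
    logs[[labels[i]]] <- ev$op_log
  }
  structure(list(ancestor = anc, leaves = leaves, op_logs = logs,
                 branch_ops = cfg$branch_ops, config = cfg),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Simulated triple: %d blocks, %d ancestral chromosomes, branch events %s\n",
              x$config$n_blocks, length(x$ancestor$chromosomes),
              paste(x$branch_ops, collapse = "/")))
  invisible(x)
}

#' Expand a simulated triple into a fractionated syntelog table
#'
#' Each block carries `genes_per_block` gene families in block order; each
#' leaf genome retains a family independently with its retention rate, with
#' at least two families per block forced so no block becomes unrecoverable.
#' Coordinates are synthesised on a fixed grid (1 kb genes, 0.5 kb spacing);
#' strands and within-block gene order follow block orientation.
#'
#' @param ts A `truth_set` from [simulate_triple()].
#' @param cfg The [sim_config()] used (defaults to `ts$config`).
#' @return A `data.frame` with columns `family_id`, `genome`, `chromosome`,
#'   `start_bp`, `end_bp`, `strand`, `order_index`, plus provenance columns
#'   `true_block` and `gene_rank`; attribute `n_forced` counts families kept
#'   only by the two-per-block floor.
#' @export
simulate_syntelog_table <- function(ts, cfg = ts$config) {
  stopifnot(inherits(ts, "truth_set"))
  gpb <- cfg$genes_per_block
  gene_len <- 1000L; gene_gap <- 500L
  rows <- list(); n_forced <- 0L
  with_seed(derive_seed(cfg$seed, 99L), {
    for (i in seq_along(ts$leaves)) {
      g <- ts$leaves[[i]]
      r <- cfg$retention[i]
      for (chr in g$chromosomes) {
        genes_b <- integer(0); ranks <- integer(0); strands <- character(0)
        for (mk in chr$markers) {
          keep <- which(runif(gpb) < r)
          if (length(keep) < 2L) {
            extra <- sample(setdiff(seq_len(gpb), keep), 2L - length(keep))
            n_forced <- n_forced + length(extra)
            keep <- sort(c(keep, extra))
          }
          if (mk > 0L) {
            ranks <- c(ranks, keep)
            strands <- c(strands, rep("+", length(keep)))
          } else {
            ranks <- c(ranks, rev(keep))
            strands <- c(strands, rep("-", length(keep)))
          }
          genes_b <- c(genes_b, rep(abs(mk), length(keep)))
        }
        m <- length(genes_b)
        starts <- (seq_len(m) - 1L) * (gene_len + gene_gap) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = sprintf("f%d_%d", genes_b, ranks),
          genome = g$label, chromosome = chr$name,
          start_bp = starts, end_bp = starts + gene_len - 1L,
          strand = strands, order_index = seq_len(m),
          true_block = genes_b, gene_rank = ranks,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_forced") <- n_forced
  out
}

#' Draw a Ks sample from a lognormal (Gaussian-on-ln-scale) mixture
#'
#' @param components Data frame (or list coercible to one) with columns
#'   `weight`, `mean_lnks`, `sd`.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A [ks_sample()] of `n` positive Ks values.
#' @export
sample_ks <- function(components, n, seed = 1L) {
  cmp <- as.data.frame(components)
  stopifnot(all(c("weight", "mean_lnks", "sd") %in% names(cmp)))
  if (any(cmp$sd <= 0)) stop("component sd must be positive")
  if (abs(sum(cmp$weight) - 1) > 1e-9) stop("component weights must sum to 1")
  with_seed(seed, {
    z <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
    ks_sample(exp(rnorm(n, cmp$mean_lnks[z], cmp$sd[z])),
              pair_label = "simulated")
  })
}

# -- recovery evaluation ----------------------------------------------------

# adjacency keys of signed sequences (id coding); tolerant of repeated ids
seq_adj_keys <- function(seqs) {
  keys <- character(0)
  for (s in seqs) {
    if (length(s) < 2L) next
    rext <- ifelse(s > 0L, 2L * abs(s), 2L * abs(s) - 1L)
    lext <- ifelse(s > 0L, 2L * abs(s) - 1L, 2L * abs(s))
    a <- rext[-length(s)]; b <- lext[-1L]
    keys <- c(keys, paste(pmin(a, b), pmax(a, b)))
  }
  keys
}

#' Evaluate block recovery against simulation truth
#'
#' Maps each recovered block back to the true blocks of its member families
#' and asks which true block adjacencies (oriented neighbour relations in
#' each leaf genome) survive in the recovered arrangement.
#'
#' @param bs A `block_set` built from a simulated syntelog table.
#' @param table The simulated table (with its `true_block`/`gene_rank`
#'   provenance columns).
#' @param ts The generating `truth_set`.
#' @return List with `adjacency_recovery` (pooled fraction), `per_genome`
#'   fractions, `n_true_blocks` and `n_recovered_blocks`.
#' @export
block_recovery_stats <- function(bs, table, ts) {
  stopifnot(inherits(bs, "block_set"), inherits(ts, "truth_set"))
  per <- numeric(0); hit <- 0L; tot <- 0L
  for (lab in names(ts$leaves)) {
    true_seqs <- lapply(ts$leaves[[lab]]$chromosomes, `[[`, "markers")
    true_keys <- unique(seq_adj_keys(true_seqs))
    pl <- bs$blocks[bs$blocks$genome == lab, , drop = FALSE]
    pl <- pl[order(pl$chromosome, pl$start_bp), , drop = FALSE]
    rec_seqs <- list()
    for (cn in unique(pl$chromosome)) {
      rows <- pl[pl$chromosome == cn, , drop = FALSE]
      sq <- integer(0)
      for (bid in rows$block_id) {
        fams <- bs$members[[as.character(bid)]]
        sub <- table[table$genome == lab & table$family_id %in% fams, ,
                     drop = FALSE]
        sub <- sub[order(sub$order_index), , drop = FALSE]
        rl <- rle(sub$true_block)
        pos <- cumsum(rl$lengths)
        sgn <- ifelse(sub$strand[pos] == "+", 1L, -1L)
        sq <- c(sq, rl$values * sgn)
      }
      rec_seqs[[cn]] <- sq
    }
    rec_keys <- unique(seq_adj_keys(rec_seqs))
    per[lab] <- if (length(true_keys))
      mean(true_keys %in% rec_keys) else NA_real_
    hit <- hit + sum(true_keys %in% rec_keys)
    tot <- tot + length(true_keys)
  }
  list(adjacency_recovery = hit / tot, per_genome = per,
       n_true_blocks = ts$config$n_blocks,
       n_recovered_blocks = bs$universe_size)
}
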