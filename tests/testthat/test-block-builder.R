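# helper: build a syntelog table from per-genome family orders (one
# chromosome per genome unless families are given as a named list of
# chromosome vectors)
toy_table <- function(orders, strands = NULL) {
  rows <- list()
  for (g in names(orders)) {
    fam <- orders[[g]]
    st <- if (is.null(strands[[g]])) rep("+", length(fam)) else strands[[g]]
    starts <- (seq_along(fam) - 1L) * 1500L + 1L
    rows[[g]] <- data.frame(family_id = paste0("f", fam), genome = g,
                            chromosome = "c1", start_bp = starts,
                            end_bp = starts + 999L, strand = st,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("chaining recovers collinear runs in both orientations", {
  ch <- chain_pairwise(toy_table(list(A = 1:10, B = 1:10)), "A", "B",
                       chain_params(min_anchors = 2))
  expect_identical(length(unique(ch$chain_id)), 1L)
  expect_identical(nrow(ch), 10L)
  expect_identical(unique(ch$orientation), "+")

  rev_tab <- toy_table(list(A = 1:10, B = 10:1), list(B = rep("-", 10)))
  ch2 <- chain_pairwise(rev_tab, "A", "B", chain_params(min_anchors = 2))
  expect_identical(nrow(ch2), 10L)
  expect_identical(unique(ch2$orientation), "-")

  expect_error(chain_pairwise(rev_tab, "A", "Z"), "unknown genome")
})

test_that("a transposed outlier is left unchained under a tight gap cap", {
  tab <- toy_table(list(A = 1:10, B = c(1:4, 9, 5:8, 10)))
  ch <- chain_pairwise(tab, "A", "B",
                       chain_params(min_anchors = 2, max_gap_genes = 2))
  expect_identical(max(table(ch$chain_id)), 9L)
  expect_false("f9" %in% ch$family_id)
})

test_that("chaining is invariant to coordinate shifts and chromosome names", {
  tab <- toy_table(list(A = 1:10, B = c(1:4, 9, 5:8, 10)))
  shifted <- tab
  shifted$start_bp <- shifted$start_bp + 1e6L
  shifted$end_bp <- shifted$end_bp + 1e6L
  shifted$chromosome <- "scaffold_42"
  p <- chain_params(min_anchors = 2, max_gap_genes = 2)
  a <- chain_pairwise(tab, "A", "B", p)
  b <- chain_pairwise(shifted, "A", "B", p)
  expect_identical(a$family_id, b$family_id)
  expect_identical(a$chain_id, b$chain_id)
})

test_that("build_blocks finds whole-genome and inversion block structure", {
  tab <- toy_table(list(A = 1:20, B = 1:20, C = 1:20))
  bs <- build_blocks(tab, chain_params(min_anchors = 2))
  expect_identical(bs$universe_size, 1L)
  expect_identical(sort(unlist(bs$members, use.names = FALSE)),
                   sort(paste0("f", 1:20)))

  inv <- c(1:7, 12:8, 13:20)
  st <- c(rep("+", 7), rep("-", 5), rep("+", 8))
  tab2 <- toy_table(list(A = 1:20, B = 1:20, C = inv), list(C = st))
  bs2 <- build_blocks(tab2, chain_params(min_anchors = 2, max_gap_genes = 3))
  expect_identical(bs2$universe_size, 3L)
  gs <- blocks_to_genomes(bs2)
  expect_true(validate_genome_set(gs)$ok)
  expect_identical(dcj_distance(gs$A, gs$B), 0L)
  expect_identical(dcj_distance(gs$A, gs$C), 1L)

  expect_error(build_blocks(toy_table(list(A = 1:5, B = 1:5))), "three genomes")
})

test_that("families with extra copies are dropped and counted", {
  tab <- toy_table(list(A = 1:10, B = 1:10, C = 1:10))
  dup <- tab[tab$genome == "A" & tab$family_id == "f5", ]
  dup$start_bp <- dup$start_bp + 40000L; dup$end_bp <- dup$end_bp + 40000L
  bs <- build_blocks(rbind(tab, dup), chain_params(min_anchors = 2))
  expect_true("f5" %in% bs$dropped_families)
  expect_false("f5" %in% unlist(bs$members))
})

test_that("blocks map to genomes whose distances match the simulated events", {
  for (s in 1:3) {
    cfg <- sim_config(n_blocks = 40, branch_ops = c(3L, 3L, 3L),
                      retention = c(1, 1, 1), genes_per_block = 8L, seed = s)
    ts <- simulate_triple(cfg)
    tab <- simulate_syntelog_table(ts)
    bs <- build_blocks(tab, chain_params(min_anchors = 2, max_gap_genes = 5))
    gs <- blocks_to_genomes(bs)
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      d_true <- dcj_distance(ts$leaves[[pair[1L]]], ts$leaves[[pair[2L]]])
      d_rec <- dcj_distance(gs[[pair[1L]]], gs[[pair[2L]]])
      expect_lte(d_rec, d_true + 1L)
    }
  }
})

test_that("painting assigns every placement its ancestral chromosome", {
  cfg <- sim_config(n_blocks = 30, seed = 8)
  ts <- simulate_triple(cfg)
  tab <- simulate_syntelog_table(ts)
  bs <- build_blocks(tab)
  gs <- blocks_to_genomes(bs)
  med <- solve_median(gs$A, gs$B, gs$C, mode = "heuristic")
  painting <- paint_ancestral(bs, med$median)
  expect_identical(nrow(painting), nrow(bs$blocks))
  expect_false(anyNA(painting$ancestral_chromosome))
  expect_identical(sort(unique(painting$ancestral_chromosome)),
                   sort(vapply(med$median$chromosomes, `[[`, character(1L),
                               "name")))
  # single-chromosome median paints everything one colour
  u <- sort(unique(bs$blocks$block_id))
  one <- genome("m", sample(u) * sample(c(-1L, 1L), length(u), TRUE))
  p1 <- paint_ancestral(bs, one)
  expect_identical(unique(p1$ancestral_chromosome), "chr1")
  expect_error(paint_ancestral(bs, genome("m", seq_len(max(u) + 1L))),
               "universe")
})

test_that("blocks within a genome are non-overlapping and families unique", {
  cfg <- sim_config(n_blocks = 40, seed = 21)
  ts <- simulate_triple(cfg)
  bs <- build_blocks(simulate_syntelog_table(ts))
  fams <- unlist(bs$members, use.names = FALSE)
  expect_identical(anyDuplicated(fams), 0L)
  for (lab in unique(bs$blocks$genome)) {
    sub <- bs$blocks[bs$blocks$genome == lab, ]
    for (cn in unique(sub$chromosome)) {
      rows <- sub[sub$chromosome == cn, ]
      rows <- rows[order(rows$start_bp), ]
      if (nrow(rows) > 1L)
        expect_true(all(rows$start_bp[-1L] > rows$end_bp[-nrow(rows)]))
    }
  }
})
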