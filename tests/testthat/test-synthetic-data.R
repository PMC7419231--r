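test_that("simulated ancestors respect the configuration and the seed", {
  g <- simulate_ancestor(sim_config(n_blocks = 9, n_chromosomes = 9, seed = 1))
  expect_length(g$chromosomes, 9L)
  expect_true(all(lengths(lapply(g$chromosomes, `[[`, "markers")) == 1L))
  expect_true(validate_genome_set(list(g))$ok)

  a <- simulate_ancestor(sim_config(seed = 7))
  b <- simulate_ancestor(sim_config(seed = 7))
  expect_identical(a, b)
  expect_false(genomes_equal(a, simulate_ancestor(sim_config(seed = 8))))
  expect_error(sim_config(n_blocks = 3, n_chromosomes = 5))
})

test_that("evolution logs replay exactly and zero events change nothing", {
  g <- simulate_ancestor(sim_config(seed = 2))
  ev0 <- evolve_genome(g, 0L, seed = 1)
  expect_length(ev0$op_log, 0L)
  expect_true(genomes_equal(ev0$genome, g))

  w_rev <- c(reversal = 1, translocation = 0, fusion = 0, fission = 0,
             transposition = 0)
  ev1 <- evolve_genome(g, 1L, w_rev, seed = 3)
  expect_identical(dcj_distance(g, ev1$genome), 1L)
  expect_identical(ev1$op_log[[1L]]$kind, "reversal")

  for (s in 1:5) {
    ev <- evolve_genome(g, 8L, seed = s)
    expect_length(ev$op_log, 8L)
    expect_true(genomes_equal(replay_ops(g, ev$op_log), ev$genome))
    cost <- sum(vapply(ev$op_log, `[[`, integer(1L), "dcj_cost"))
    expect_lte(dcj_distance(g, ev$genome), cost)
  }
})

test_that("transpositions cost at most two DCJs", {
  w <- c(reversal = 0, translocation = 0, fusion = 0, fission = 0,
         transposition = 1)
  g <- simulate_ancestor(sim_config(seed = 5))
  for (s in 1:10) {
    ev <- evolve_genome(g, 1L, w, seed = s)
    expect_lte(dcj_distance(g, ev$genome), 2L)
    expect_lte(ev$op_log[[1L]]$dcj_cost, 2L)
  }
})

test_that("simulated triples satisfy the truth-set invariants", {
  ts <- simulate_triple(sim_config(branch_ops = c(0L, 0L, 0L), seed = 4))
  for (l in ts$leaves) expect_true(genomes_equal(l, ts$ancestor))

  ts2 <- simulate_triple(sim_config(seed = 4))
  expect_identical(ts2, simulate_triple(sim_config(seed = 4)))
  d <- c(dcj_distance(ts2$leaves$A, ts2$leaves$B),
         dcj_distance(ts2$leaves$B, ts2$leaves$C),
         dcj_distance(ts2$leaves$A, ts2$leaves$C))
  expect_lte(d[1L], d[2L] + d[3L])
  expect_lte(d[2L], d[1L] + d[3L])
  expect_lte(d[3L], d[1L] + d[2L])
  for (l in names(ts2$leaves))
    expect_true(genomes_equal(replay_ops(ts2$ancestor, ts2$op_logs[[l]]),
                              ts2$leaves[[l]]))
})

test_that("fractionated tables have binomially plausible per-genome sizes", {
  cfg <- sim_config(n_blocks = 40, genes_per_block = 10, seed = 5)
  ts <- simulate_triple(cfg)
  tab <- simulate_syntelog_table(ts)
  counts <- table(tab$genome)
  expected <- 400 * cfg$retention
  # binomial 99.9% bounds, loosened by the forced two-per-block floor
  for (i in 1:3) {
    sdv <- sqrt(400 * cfg$retention[i] * (1 - cfg$retention[i]))
    expect_lt(abs(counts[i] - expected[i]), 4 * sdv + 8)
  }
  # full retention keeps every family everywhere
  full <- sim_config(n_blocks = 10, genes_per_block = 5,
                     retention = c(1, 1, 1), seed = 6)
  tsf <- simulate_triple(full)
  tabf <- simulate_syntelog_table(tsf)
  expect_identical(as.integer(table(tabf$genome)), rep(50L, 3L))
  expect_identical(attr(tabf, "n_forced"), 0L)
})

test_that("order and strand in the table mirror block orientation", {
  cfg <- sim_config(n_blocks = 6, n_chromosomes = 2, genes_per_block = 5,
                    retention = c(1, 1, 1), branch_ops = c(0L, 1L, 0L),
                    op_weights = c(reversal = 1, translocation = 0, fusion = 0,
                                   fission = 0, transposition = 0), seed = 11)
  ts <- simulate_triple(cfg)
  tab <- simulate_syntelog_table(ts)
  for (lab in names(ts$leaves)) {
    g <- ts$leaves[[lab]]
    for (chr in g$chromosomes) {
      rows <- tab[tab$genome == lab & tab$chromosome == chr$name, ]
      rows <- rows[order(rows$order_index), ]
      expect_identical(rle(rows$true_block)$values, abs(chr$markers))
      expect_identical(unique(rows$strand[rows$true_block %in%
                                            abs(chr$markers[chr$markers < 0])]),
                       if (any(chr$markers < 0)) "-" else character(0))
    }
  }
})

test_that("ln(Ks) samples are positive, seeded and match their components", {
  s <- sample_ks(data.frame(weight = 1, mean_lnks = -1, sd = 0.01),
                 2000, seed = 3)
  expect_true(all(s$values > 0))
  expect_lt(abs(mean(log(s$values)) + 1), 0.01)
  expect_identical(s, sample_ks(data.frame(weight = 1, mean_lnks = -1,
                                           sd = 0.01), 2000, seed = 3))
  expect_error(sample_ks(data.frame(weight = 1, mean_lnks = -1, sd = 0), 10),
               "sd")
  expect_error(sample_ks(data.frame(weight = c(.6, .6),
                                    mean_lnks = c(-1, -2), sd = c(.1, .1)),
                         10), "sum to 1")
})
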