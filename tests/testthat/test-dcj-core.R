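test_that("adjacency sets follow the chromosome structure", {
  a <- adjacencies(genome("A", c(1, 2, 3)))
  expect_identical(nrow(a$adjacencies), 2L)
  expect_identical(a$telomeres, c(extremity(1, "t"), extremity(3, "h")))
  expect_identical(a$adjacencies[1L, ],
                   c(ext1 = extremity(1, "h"), ext2 = extremity(2, "t")))

  single <- adjacencies(genome("A", 1))
  expect_identical(nrow(single$adjacencies), 0L)
  expect_length(single$telomeres, 2L)

  circ <- adjacencies(genome("A", new_chromosome(c(1, 2), circular = TRUE)))
  expect_identical(nrow(circ$adjacencies), 2L)
  expect_length(circ$telomeres, 0L)

  # linear chromosome with m markers: m - 1 adjacencies, 2 telomeres
  set.seed(2)
  for (i in 1:5) {
    g <- rand_genome(9, "G")
    a <- adjacencies(g)
    k <- length(g$chromosomes)
    expect_identical(nrow(a$adjacencies), 9L - k)
    expect_identical(length(a$telomeres), 2L * k)
  }
})

test_that("adjacency graph decomposition matches the hand examples", {
  g <- build_adjacency_graph(genome("A", c(1, 2, 3)), genome("B", c(1, 2, 3)))
  expect_identical(g$n_cycles + g$n_odd_paths %/% 2L, g$n_markers)
  expect_identical(g$n_odd_paths %% 2L, 0L)

  g2 <- build_adjacency_graph(genome("A", c(1, 2)), genome("B", c(1, -2)))
  expect_identical(g2$n_markers - g2$n_cycles - g2$n_odd_paths %/% 2L, 1L)

  g3 <- build_adjacency_graph(genome("A", 1:4), genome("B", c(1, 3, 2, 4)))
  expect_identical(g3$n_markers - g3$n_cycles - g3$n_odd_paths %/% 2L, 2L)

  expect_error(build_adjacency_graph(genome("A", 1:3), genome("B", 1:4)),
               "universe")
})

test_that("dcj_distance reproduces the textbook cases", {
  a <- genome("A", c(1, 2, 3))
  expect_identical(dcj_distance(a, a), 0L)
  expect_identical(dcj_distance(a, genome("B", c(1, -2, 3))), 1L)
  expect_identical(dcj_distance(genome("A", 1:4), genome("B", c(1, 3, 2, 4))), 2L)
  expect_identical(dcj_distance(a, genome("B", c(-3, -2, -1))), 0L)
})

test_that("dcj_distance agrees with the BFS oracle on random pairs", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(2:6, 1L)
    a <- rand_genome(n, "A"); b <- rand_genome(n, "B")
    expect_identical(dcj_distance(a, b), oracle_distance(a, b))
  }
})

test_that("distance is a metric on random genomes", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:30, 1L)
    a <- rand_genome(n, "A"); b <- rand_genome(n, "B"); c <- rand_genome(n, "C")
    dab <- dcj_distance(a, b)
    expect_identical(dab, dcj_distance(b, a))
    expect_identical(dcj_distance(a, a), 0L)
    expect_lte(dcj_distance(a, c), dab + dcj_distance(b, c))
    expect_identical(g_odd <- build_adjacency_graph(a, b)$n_odd_paths %% 2L, 0L)
  }
})

test_that("R component walker and compiled counter agree", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:20, 1L)
    a <- rand_genome(n, "A"); b <- rand_genome(n, "B")
    g <- build_adjacency_graph(a, b)
    u <- marker_universe(list(a, b))
    cnt <- dcjmedian:::ag_counts_cpp(dcjmedian:::partner_vector(a, u),
                                     dcjmedian:::partner_vector(b, u))
    expect_identical(c(g$n_cycles, g$n_odd_paths, g$n_even_paths),
                     c(cnt[1L], cnt[2L], cnt[3L]))
    # components partition all extremities
    expect_identical(sort(unlist(lapply(g$components, `[[`, "extremities"))),
                     sort(c(2L * u, 2L * u - 1L)))
  }
})

test_that("apply_dcj performs cuts and joins and respects preconditions", {
  rev_op <- dcj_op(consumed = list(c(extremity(1, "h"), extremity(2, "t")),
                                   c(extremity(2, "h"), extremity(3, "t"))),
                   produced = list(c(extremity(1, "h"), extremity(2, "h")),
                                   c(extremity(2, "t"), extremity(3, "t"))),
                   kind = "reversal")
  out <- apply_dcj(genome("A", c(1, 2, 3)), rev_op)
  expect_true(genomes_equal(out, genome("A", c(1, -2, 3))))

  fission <- dcj_op(consumed = list(c(extremity(1, "h"), extremity(2, "t"))),
                    produced = list(extremity(1, "h"), extremity(2, "t")),
                    kind = "fission")
  split <- apply_dcj(genome("A", c(1, 2)), fission)
  expect_length(split$chromosomes, 2L)
  expect_identical(dcj_distance(split, genome("A", c(1, 2))), 1L)

  expect_error(apply_dcj(genome("A", c(1, -2, 3)), rev_op), "not present")

  # fusion then fission stays within distance 2 of the start
  set.seed(4)
  for (i in 1:10) {
    g <- rand_genome(8, "G", n_chrom = 2L)
    w1 <- c(reversal = 0, translocation = 0, fusion = 1, fission = 0,
            transposition = 0)
    w2 <- c(reversal = 0, translocation = 0, fusion = 0, fission = 1,
            transposition = 0)
    g1 <- evolve_genome(g, 1L, w1, seed = i)$genome
    g2 <- evolve_genome(g1, 1L, w2, seed = i + 100L)$genome
    expect_lte(dcj_distance(g, g2), 2L)
  }
})

test_that("sorting scenarios are optimal, deterministic and replayable", {
  expect_length(sorting_scenario(genome("A", 1:3), genome("B", 1:3)), 0L)
  sc <- sorting_scenario(genome("A", 1:3), genome("B", c(1, -2, 3)))
  expect_length(sc, 1L)

  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:6, 1L)
    pr <- rand_pair(n, sample(0:3, 1L), seed = i * 13L)
    sc <- sorting_scenario(pr$a, pr$b)
    expect_identical(length(sc), as.integer(oracle_distance(pr$a, pr$b)))
    g <- pr$a
    for (op in sc) g <- apply_dcj(g, op)
    expect_true(genomes_equal(g, pr$b))
    expect_identical(length(sorting_scenario(pr$a, pr$b)), length(sc))
  }
})

test_that("k rearrangement events never exceed k DCJs of distance", {
  w <- c(reversal = 0.7, translocation = 0.3, fusion = 0, fission = 0,
         transposition = 0)
  eq <- 0L
  for (s in 1:100) {
    g <- simulate_ancestor(sim_config(n_blocks = 40, n_chromosomes = 6,
                                      seed = s))
    ev <- evolve_genome(g, 5L, w, seed = s + 500L)
    d <- dcj_distance(g, ev$genome)
    expect_lte(d, 5L)
    eq <- eq + (d == 5L)
  }
  # well below saturation (k = n/8) the events are almost always additive
  expect_gte(eq, 95L)
})
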