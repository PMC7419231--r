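test_that("single- and two-component ln(Ks) mixtures are recovered", {
  s1 <- sample_ks(data.frame(weight = 1, mean_lnks = -1, sd = 0.3),
                  5000, seed = 42)
  f1 <- fit_lnks_mixture(s1, k_max = 3, seed = 42)
  expect_identical(f1$k, 1L)
  expect_lt(abs(f1$means[1L] + 1), 0.05)
  expect_true(f1$monotone)
  expect_identical(unname(which.min(f1$bic_trace)), f1$k)

  s2 <- sample_ks(data.frame(weight = c(0.5, 0.5), mean_lnks = c(-2, -0.5),
                             sd = c(0.25, 0.25)), 5000, seed = 43)
  f2 <- fit_lnks_mixture(s2, k_max = 3, seed = 43)
  expect_identical(f2$k, 2L)
  expect_true(all(abs(f2$means - c(-2, -0.5)) < 0.07))
  expect_lt(abs(sum(f2$weights) - 1), 1e-9)
  expect_true(all(f2$sds > 0))

  # refit with the same seed is identical
  expect_identical(f2, fit_lnks_mixture(s2, k_max = 3, seed = 43))
})

test_that("the Ks filter and sample-size preconditions are enforced", {
  expect_error(ks_sample(c(0.1, -0.2)), "positive")
  tiny <- ks_sample(rep(1e-4, 100))
  expect_error(fit_lnks_mixture(tiny), "no Ks values remain")
  few <- ks_sample(exp(rnorm(30)))
  expect_error(fit_lnks_mixture(few), "at least 50")
  mixed <- ks_sample(c(rep(1e-4, 50), exp(rnorm(100, -1, 0.2))))
  f <- fit_lnks_mixture(mixed, k_max = 2, seed = 1)
  expect_identical(f$n_removed, 50L)
  expect_identical(f$n, 100L)
})

test_that("chi-square fit check accepts the true model and rejects a wrong one", {
  smp <- sample_ks(data.frame(weight = 1, mean_lnks = -1, sd = 0.3),
                   2000, seed = 7)
  f <- fit_lnks_mixture(smp, k_max = 2, seed = 7)
  g <- chi2_goodness(f, smp)
  expect_gt(g$dof, 0L)
  expect_gte(g$p.value, 0)
  expect_lte(g$p.value, 1)
  expect_gt(g$p.value, 0.001)

  far <- sample_ks(data.frame(weight = c(0.5, 0.5), mean_lnks = c(-3, -0.5),
                              sd = c(0.2, 0.2)), 2000, seed = 8)
  f1 <- fit_lnks_mixture(far, k_max = 1, seed = 8)
  expect_lt(chi2_goodness(f1, far)$p.value, 0.001)
})

test_that("chi-square p-values are roughly calibrated under the null", {
  rej <- logical(100)
  for (s in seq_len(100)) {
    smp <- sample_ks(data.frame(weight = 1, mean_lnks = -1, sd = 0.3),
                     1000, seed = s)
    f <- fit_lnks_mixture(smp, k_max = 1, seed = s)
    rej[s] <- chi2_goodness(f, smp)$p.value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("mixture fits agree with an independent EM implementation", {
  s2 <- sample_ks(data.frame(weight = c(0.4, 0.6), mean_lnks = c(-2.2, -0.8),
                             sd = c(0.3, 0.25)), 4000, seed = 9)
  f <- fit_lnks_mixture(s2, k_max = 2, seed = 9)
  x <- log(s2$values[s2$values > 0.001])
  suppressPackageStartupMessages(library(mclust))
  m <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f$means), sort(as.numeric(m$parameters$mean)),
               tolerance = 0.02)
  expect_equal(f$loglik, m$loglik, tolerance = 1e-3)
})

test_that("peaks convert to divergence times linearly in Ks", {
  fit <- structure(list(k = 1L, means = log(0.30), sds = 0.2, weights = 1),
                   class = "ks_mixture_fit")
  expect_equal(peak_to_time(fit, 1.5e-8), 10)
  fit2 <- fit; fit2$means <- log(0.60)
  expect_equal(peak_to_time(fit2, 1.5e-8), 20)
  expect_error(peak_to_time(fit, 0), "positive")
  expect_error(peak_to_time(fit), "clock_rate")
})

test_that("ancestor placement solves the clock equation and exports newick", {
  pl <- place_ancestor(c(rapa = 26, oleracea = 28, nigra = 70), "nigra")
  expect_equal(pl$root_offset, 21.5)
  expect_equal(pl$root_offset_fraction, 21.5 / 70)
  expect_true(all(abs(pl$leaf_depths - 48.5) < 1e-9))

  sym <- place_ancestor(c(a = 10, b = 10, c = 10), "c")
  expect_equal(sym$root_offset, 0)

  tr <- ape::read.tree(text = pl$newick)
  expect_setequal(tr$tip.label, c("rapa", "oleracea", "nigra"))
  depths <- ape::node.depth.edgelength(tr)[seq_len(3L)]
  expect_true(max(depths) - min(depths) < 1e-9)

  expect_warning(place_ancestor(c(a = 1, b = 30, out = 4), "out"), "clamped")
  expect_error(place_ancestor(c(a = 1, b = 2, c = 3), "zebra"), "outgroup")
})
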