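# ---------------------------------------------------------------------------
# Divergence dating: Gaussian mixtures on ln(Ks) fitted by EM with BIC model
# choice and a chi-square fit check; peak-to-time conversion under a
# synonymous molecular clock; ultrametric placement of the ancestor on the
# median-to-outgroup path.
# ---------------------------------------------------------------------------

#' Construct a Ks sample
#'
#' @param values Positive Ks values (synonymous substitutions per synonymous
#'   site), one per syntelog pair.
#' @param pair_label Label of the genome pair the values compare.
#' @return A `ks_sample`.
#' @export
ks_sample <- function(values, pair_label = "pair") {
  values <- as.numeric(values)
  if (anyNA(values) || any(values <= 0))
    stop("Ks values must be positive and non-missing")
  structure(list(values = values, pair_label = as.character(pair_label)[1L]),
            class = "ks_sample")
}

#' Read Ks values from a file
#'
#' Accepts one value per line, or a TSV with a `ks` column (and optional
#' `pair_label` column used for the sample label).
#'
#' @param path File path.
#' @return A `ks_sample`.
#' @export
read_ks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("[A-Za-z]", first)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!"ks" %in% names(tab)) stop("TSV Ks input needs a 'ks' column")
    lab <- if ("pair_label" %in% names(tab)) tab$pair_label[1L] else
      basename(path)
    ks_sample(tab$ks, lab)
  } else {
    ks_sample(as.numeric(readLines(path)), basename(path))
  }
}

filter_lnks <- function(sample, min_ks = 0.001) {
  v <- sample$values
  keep <- v > min_ks
  list(x = log(v[keep]), n_removed = sum(!keep))
}

# EM for a k-component univariate Gaussian mixture; deterministic given the
# caller's RNG state.  Returns NULL on degenerate collapse.
em_gaussian <- function(x, mu, sdv, w, tol = 1e-8, max_iter = 1000L) {
  n <- length(x); k <- length(mu)
  sd_floor <- 1e-6 * stats::sd(x)
  ll_trace <- numeric(max_iter); ll_old <- -Inf; ll <- -Inf; nit <- 0L
  dens <- matrix(0, n, k)
  inv_sqrt2pi <- 1 / sqrt(2 * pi)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      z <- (x - mu[j]) / sdv[j]
      dens[, j] <- w[j] * inv_sqrt2pi / sdv[j] * exp(-0.5 * z * z)
    }
    tot <- .rowSums(dens, n, k)
    if (any(tot == 0) || anyNA(tot)) return(NULL)
    ll <- sum(log(tot))
    nit <- it; ll_trace[it] <- ll
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    resp <- dens / tot
    nk <- .colSums(resp, n, k)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- .colSums(resp * x, n, k) / nk
    sdv <- pmax(sqrt(.colSums(resp * (outer(x, mu, `-`))^2, n, k) / nk),
                sd_floor)
  }
  ll_trace <- ll_trace[seq_len(nit)]
  list(mu = mu, sd = sdv, w = w, loglik = ll, trace = ll_trace,
       monotone = all(diff(ll_trace) >= -1e-6 * (1 + abs(ll_trace[-1L]))))
}

#' Fit a Gaussian mixture to ln(Ks) values with BIC selection
#'
#' Values at or below `min_ks` are removed, the remainder log-transformed,
#' and mixtures with 1..`k_max` components fitted by EM (quantile-based
#' initial means, pooled sd, uniform weights; 10 seed-jittered restarts per
#' k; tolerance 1e-8 on the log-likelihood).  The number of components
#' minimising `BIC = (3k - 1) ln(n) - 2 loglik` is returned.
#'
#' @param sample A [ks_sample()] or numeric vector of Ks values.
#' @param k_max Largest number of components to consider.
#' @param seed Integer seed; refits with the same seed are identical.
#' @param min_ks Retention threshold on the Ks scale (default 0.001).
#' @return A `ks_mixture_fit`: `k`, `means`, `sds`, `weights` (components
#'   sorted by mean), `loglik`, `bic`, `bic_trace`, `chosen_by`, `n`,
#'   `n_removed`, `monotone`.
#' @export
fit_lnks_mixture <- function(sample, k_max = 4L, seed = 1L, min_ks = 0.001) {
  if (!inherits(sample, "ks_sample")) sample <- ks_sample(sample)
  stopifnot(k_max >= 1L)
  flt <- filter_lnks(sample, min_ks)
  x <- flt$x
  if (length(x) == 0L) stop("no Ks values remain after the > ", min_ks,
                            " filter")
  if (length(x) < 50L)
    stop("need at least 50 retained Ks values, got ", length(x))
  n <- length(x)
  sx <- stats::sd(x)
  fits <- vector("list", k_max)
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      if (k == 1L) {
        # single component: the MLE is closed-form
        mu <- mean(x); sdv <- sqrt(mean((x - mu)^2))
        fits[[1L]] <- list(mu = mu, sd = sdv, w = 1,
                           loglik = sum(dnorm(x, mu, sdv, log = TRUE)),
                           trace = numeric(0), monotone = TRUE)
        next
      }
      # short-run/long-run restart scheme: 10 seed-jittered starts are run
      # for a handful of iterations and the most promising one to full
      # convergence (relative tolerance 1e-8)
      best0 <- NULL; init <- NULL
      for (r in seq_len(10L)) {
        mu0 <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
        if (r > 1L) mu0 <- mu0 + rnorm(k, 0, sx / 4)
        f <- em_gaussian(x, mu0, rep(sx, k), rep(1 / k, k),
                         tol = 1e-6, max_iter = 40L)
        if (!is.null(f) && (is.null(best0) || f$loglik > best0))
          { best0 <- f$loglik; init <- f }
      }
      fits[[k]] <- if (is.null(init)) NULL else
        em_gaussian(x, init$mu, init$sd, init$w)
    }
  })
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("all EM fits collapsed")
  bic <- vapply(seq_len(k_max), function(k)
    if (ok[k]) (3 * k - 1) * log(n) - 2 * fits[[k]]$loglik else Inf,
    numeric(1L))
  kbest <- which.min(bic)
  f <- fits[[kbest]]
  ord <- order(f$mu)
  structure(list(k = kbest, means = f$mu[ord], sds = f$sd[ord],
                 weights = f$w[ord], loglik = f$loglik, bic = bic[kbest],
                 bic_trace = setNames(bic, paste0("k", seq_len(k_max))),
                 chosen_by = "BIC", n = n, n_removed = flt$n_removed,
                 monotone = f$monotone, min_ks = min_ks,
                 pair_label = sample$pair_label),
            class = "ks_mixture_fit")
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat(sprintf("ln(Ks) Gaussian mixture for '%s': k = %d (BIC), n = %d (%d filtered)\n",
              x$pair_label, x$k, x$n, x$n_removed))
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, mean %.3f (Ks peak %.4f), sd %.3f\n",
                j, x$weights[j], x$means[j], exp(x$means[j]), x$sds[j]))
  invisible(x)
}

mixture_cdf <- function(fit, q) {
  rowSums(vapply(seq_len(fit$k), function(j)
    fit$weights[j] * pnorm(q, fit$means[j], fit$sds[j]),
    numeric(length(q))))
}

#' Chi-square goodness-of-fit check of a ln(Ks) mixture
#'
#' Bins the log-transformed sample, merges bins with expected counts below
#' 5, and compares observed to model-expected counts; degrees of freedom are
#' bins minus one minus the `3k - 1` free mixture parameters.
#'
#' @param fit A `ks_mixture_fit` produced from `sample`.
#' @param sample The [ks_sample()] the fit was computed on.
#' @param n_bins Initial number of equal-width bins.
#' @return List with `statistic`, `dof`, `p.value`, `n_bins_used`.
#' @export
chi2_goodness <- function(fit, sample, n_bins = 30L) {
  stopifnot(inherits(fit, "ks_mixture_fit"))
  if (!inherits(sample, "ks_sample")) sample <- ks_sample(sample)
  x <- filter_lnks(sample, fit$min_ks)$x
  n <- length(x)
  if (n != fit$n)
    warning("sample size differs from the fitted sample")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  inner <- breaks[-c(1L, length(breaks))]
  obs <- tabulate(findInterval(x, inner) + 1L, nbins = n_bins)
  cdf <- c(0, mixture_cdf(fit, inner), 1)
  expd <- n * diff(cdf)
  # merge adjacent bins until every expected count is >= 5
  while (length(expd) > 1L && any(expd < 5)) {
    i <- which(expd < 5)[1L]
    j <- if (i == length(expd)) i - 1L else i + 1L
    k0 <- min(i, j)
    expd[k0] <- expd[i] + expd[j]; expd <- expd[-max(i, j)]
    obs[k0] <- obs[i] + obs[j]; obs <- obs[-max(i, j)]
  }
  if (length(expd) < 3L)
    stop("fewer than 3 bins with adequate expected counts")
  dof <- length(expd) - 1L - (3L * fit$k - 1L)
  if (dof < 1L)
    stop("non-positive degrees of freedom: too few usable bins for k = ",
         fit$k)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, dof = dof,
       p.value = pchisq(stat, dof, lower.tail = FALSE),
       n_bins_used = length(expd))
}

#' Convert ln(Ks) mixture peaks to divergence times
#'
#' Under a synonymous molecular clock, a component with mean `m` on the
#' ln(Ks) scale dates a divergence at `exp(m) / (2 r)` years for clock rate
#' `r` (substitutions per synonymous site per year); times are reported in
#' Ma.  There is no default rate: lineage-specific rates differ several-fold
#' across plants, so the rate must be supplied explicitly.
#'
#' @param fit A `ks_mixture_fit`.
#' @param clock_rate Substitutions per synonymous site per year (> 0).
#' @return Numeric vector of divergence times in Ma, one per component.
#' @examples
#' # a Ks peak at 0.30 with r = 1.5e-8 dates to 10 Ma
#' @export
peak_to_time <- function(fit, clock_rate) {
  if (missing(clock_rate) || is.null(clock_rate))
    stop("no clock_rate supplied: provide substitutions/site/year explicitly")
  if (!is.numeric(clock_rate) || length(clock_rate) != 1L || clock_rate <= 0)
    stop("clock_rate must be a single positive number")
  exp(fit$means) / (2 * clock_rate) / 1e6
}

#' Place an ultrametric ancestor on the median-to-outgroup path
#'
#' Given the three median-to-leaf distances, the root is placed on the edge
#' from the median towards the outgroup at offset `x` solving
#' `d_out - x = x + mean(d_in1, d_in2)`, which equalises root-to-leaf depths
#' under a clock; the two ingroup branches are equalised to their mean.
#'
#' @param result A `median_result`, or a named numeric vector of three
#'   per-leaf distances.
#' @param outgroup_leaf Label of the outgroup leaf.
#' @return An `ancestor_placement`: `per_leaf_distances`, `root_offset`,
#'   `root_offset_fraction` (of the median-outgroup distance), `leaf_depths`,
#'   `newick`, `clamped`.
#' @examples
#' place_ancestor(c(rapa = 26, oleracea = 28, nigra = 70), "nigra")
#' @export
place_ancestor <- function(result, outgroup_leaf) {
  per <- if (inherits(result, "median_result")) result$per_leaf else result
  if (length(per) != 3L || is.null(names(per)))
    stop("need three named per-leaf distances")
  if (!outgroup_leaf %in% names(per))
    stop("outgroup label '", outgroup_leaf, "' not among: ",
         paste(names(per), collapse = ", "))
  d_out <- unname(per[[outgroup_leaf]])
  d_in <- per[setdiff(names(per), outgroup_leaf)]
  x <- (d_out - mean(d_in)) / 2
  clamped <- FALSE
  if (x < 0 || x > d_out) {
    warning("clock-free distances: root offset ", signif(x, 4),
            " clamped into [0, ", d_out, "]")
    x <- min(max(x, 0), d_out)
    clamped <- TRUE
  }
  depth <- d_out - x
  eq <- depth - x  # equalised ingroup branch length (= mean(d_in) unclamped)
  nwk <- sprintf("((%s:%.9g,%s:%.9g)median:%.9g,%s:%.9g)root;",
                 names(d_in)[1L], eq, names(d_in)[2L], eq, x,
                 outgroup_leaf, depth)
  structure(list(per_leaf_distances = per,
                 root_offset = x,
                 root_offset_fraction = if (d_out > 0) x / d_out else NA_real_,
                 ingroup_equalized = mean(d_in),
                 leaf_depths = setNames(rep(depth, 3L),
                                        c(names(d_in), outgroup_leaf)),
                 outgroup = outgroup_leaf,
                 newick = nwk, clamped = clamped),
            class = "ancestor_placement")
}

#' @export
print.ancestor_placement <- function(x, ...) {
  cat(sprintf("Ancestor placement: root %.3g/%d (%.1f%%) of the way from the median to '%s'\n",
              x$root_offset, x$per_leaf_distances[[x$outgroup]],
              100 * x$root_offset_fraction, x$outgroup))
  cat("  ", x$newick, "\n", sep = "")
  invisible(x)
}
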