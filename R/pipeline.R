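# ---------------------------------------------------------------------------
# End-to-end orchestration: blocks -> distances -> median -> painting ->
# placement -> Ks mixture fitting, from one configuration, with persisted
# intermediates and a machine-readable report.
# ---------------------------------------------------------------------------

#' Build a pipeline configuration
#'
#' Exactly one of `syntelogs` (orthologue table TSV) or `grimm` (signed
#' block-order file) must be given as the rearrangement input.
#'
#' @param syntelogs Optional path to a syntelog TSV.
#' @param grimm Optional path to a GRIMM-like three-genome file.
#' @param ks_files Optional named character vector of Ks input files.
#' @param chain [chain_params()] for block building.
#' @param median_mode `"exact"` or `"heuristic"`.
#' @param median_budget Node budget for the exact median search.
#' @param outgroup Optional outgroup label for ancestor placement.
#' @param clock_rate Optional substitutions/site/year for peak dating.
#' @param k_max Components considered in the Ks mixture fits.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(syntelogs = NULL, grimm = NULL, ks_files = NULL,
                       chain = chain_params(), median_mode = "exact",
                       median_budget = 1e6, outgroup = NULL,
                       clock_rate = NULL, k_max = 4L, seed = 1L,
                       out_dir = tempfile("dcjrun")) {
  if (is.null(syntelogs) == is.null(grimm))
    stop("give exactly one of 'syntelogs' or 'grimm' as input")
  structure(list(syntelogs = syntelogs, grimm = grimm, ks_files = ks_files,
                 chain = chain, median_mode = median_mode,
                 median_budget = median_budget, outgroup = outgroup,
                 clock_rate = clock_rate, k_max = as.integer(k_max),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `chain` may be a
#' mapping with `max_gap_genes`, `min_anchors`, `max_gap_bp`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  chain <- if (is.null(y$chain)) chain_params() else
    do.call(chain_params, y$chain)
  run_config(syntelogs = y$syntelogs, grimm = y$grimm,
             ks_files = unlist(y$ks_files),
             chain = chain,
             median_mode = y$median_mode %||% "exact",
             median_budget = y$median_budget %||% 1e6,
             outgroup = y$outgroup, clock_rate = y$clock_rate,
             k_max = y$k_max %||% 4L, seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("dcjrun"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: block building (if a syntelog table is the
#' input), pairwise DCJ distances and median bounds, median solve, ancestral
#' painting, ultrametric placement (if an outgroup is configured), and Ks
#' mixture fits (if Ks files are configured).  All intermediates are written
#' to `cfg$out_dir` (`blocks.tsv`, `genomes.grimm`, `median.grimm`,
#' `median.json`, `painting.bed`, `tree.nwk`, `ksfit.json`, `report.json`);
#' a rerun with the same config and seed is identical.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return A `run_report` list (also serialised to `report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  report <- list(parameters = list(
    median_mode = cfg$median_mode, median_budget = cfg$median_budget,
    chain = unclass(cfg$chain), outgroup = cfg$outgroup,
    clock_rate = cfg$clock_rate, k_max = cfg$k_max, seed = cfg$seed))

  bs <- NULL
  if (!is.null(cfg$syntelogs)) {
    genomes <- stage("blocks", {
      tab <- check_syntelog_table(read.delim(cfg$syntelogs,
                                             stringsAsFactors = FALSE))
      bs <- build_blocks(tab, cfg$chain)
      write.table(bs$blocks, out("blocks.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      blocks_to_genomes(bs)
    })
    report$block_count <- bs$universe_size
    report$dropped_families <- length(bs$dropped_families)
  } else {
    genomes <- stage("read_genomes", read_genomes(cfg$grimm, "grimm"))
    if (length(genomes) != 3L)
      stop("pipeline stage 'read_genomes' failed: need exactly 3 genomes, got ",
           length(genomes), call. = FALSE)
  }
  write_genomes(genomes, out("genomes.grimm"), "grimm")
  labs <- vapply(genomes, `[[`, character(1L), "label")

  dist_tab <- stage("distances", {
    pairs <- utils::combn(3L, 2L)
    data.frame(genome_a = labs[pairs[1L, ]], genome_b = labs[pairs[2L, ]],
               dcj_distance = apply(pairs, 2L, function(p)
                 dcj_distance(genomes[[p[1L]]], genomes[[p[2L]]])))
  })
  report$pairwise_distances <- dist_tab
  b <- median_bounds(dist_tab$dcj_distance)
  report$bounds <- as.list(b)

  med <- stage("median", solve_median(genomes[[1L]], genomes[[2L]],
                                      genomes[[3L]], mode = cfg$median_mode,
                                      budget = cfg$median_budget))
  write_genomes(med$median, out("median.grimm"), "grimm")
  report$median <- list(total = med$total, per_leaf = as.list(med$per_leaf),
                        lower = med$lower, upper = med$upper,
                        optimal = med$optimal, status = med$status,
                        nodes_explored = med$nodes_explored,
                        n_chromosomes = length(med$median$chromosomes))
  jsonlite::write_json(report$median, out("median.json"), auto_unbox = TRUE,
                       digits = NA)
  report$ancestral_chromosomes <- length(med$median$chromosomes)

  if (!is.null(bs)) {
    stage("painting", {
      painting <- paint_ancestral(bs, med$median)
      write_painting_bed(painting, out("painting.bed"))
      report$painting_rows <- nrow(painting)
    })
  }

  if (!is.null(cfg$outgroup)) {
    if (!cfg$outgroup %in% labs) {
      warning("outgroup '", cfg$outgroup,
              "' not among genome labels; placement skipped")
    } else {
      pl <- stage("placement", place_ancestor(med, cfg$outgroup))
      writeLines(pl$newick, out("tree.nwk"))
      report$placement <- list(root_offset = pl$root_offset,
                               fraction = pl$root_offset_fraction,
                               outgroup = pl$outgroup,
                               newick = pl$newick)
    }
  }

  if (!is.null(cfg$ks_files) && length(cfg$ks_files)) {
    fits <- stage("ksfit", {
      lapply(cfg$ks_files, function(f) {
        fit <- fit_lnks_mixture(read_ks(f), k_max = cfg$k_max,
                                seed = cfg$seed)
        out_fit <- list(k = fit$k, means = fit$means, sds = fit$sds,
                        weights = fit$weights, bic_trace = fit$bic_trace,
                        n = fit$n)
        if (!is.null(cfg$clock_rate))
          out_fit$times_ma <- peak_to_time(fit, cfg$clock_rate)
        out_fit
      })
    })
    jsonlite::write_json(fits, out("ksfit.json"), auto_unbox = TRUE,
                         digits = NA)
    report$ks_fits <- fits
  }

  report$versions <- list(
    dcjmedian = as.character(utils::packageVersion("dcjmedian")),
    r = R.version.string)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  structure(c(report, list(out_dir = cfg$out_dir)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat("  pairwise DCJ distances:\n")
  print(x$pairwise_distances)
  cat(sprintf("  median total %d (bounds %d..%d), %d ancestral chromosomes\n",
              x$median$total, x$bounds$lower, x$bounds$upper,
              x$ancestral_chromosomes))
  if (!is.null(x$block_count))
    cat(sprintf("  %d synteny blocks\n", x$block_count))
  if (!is.null(x$placement))
    cat(sprintf("  root offset %.3g (fraction %.3f) towards '%s'\n",
                x$placement$root_offset, x$placement$fraction,
                x$placement$outgroup))
  cat("  outputs in ", x$out_dir, "\n", sep = "")
  invisible(x)
}
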