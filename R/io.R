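# ---------------------------------------------------------------------------
# Genome readers/writers.
#
# GRIMM-like dialect: ">label" headers, one chromosome per line of
# whitespace-separated signed integers, terminated by "$" (linear) or "@"
# (circular).
#
# TSV dialect: header row with columns genome, chromosome, index, block_id,
# strand (+/-); index is 1-based within its chromosome.
# ---------------------------------------------------------------------------

#' Read signed block-order genomes
#'
#' @param path Path to an existing file.
#' @param format `"grimm"` or `"tsv"` (see package vignette for the
#'   dialects).
#' @return Named list of `genome` objects.
#' @export
read_genomes <- function(path, format = c("grimm", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "grimm") read_grimm(path) else read_genomes_tsv(path)
}

read_grimm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  genomes <- list()
  label <- NULL; chrs <- list(); pending <- integer(0)
  flush_genome <- function() {
    if (is.null(label)) return(invisible())
    if (length(pending))
      stop("genome '", label, "': chromosome without '$' or '@' terminator")
    if (!length(chrs)) stop("genome '", label, "' has no chromosomes")
    if (label %in% names(genomes))
      stop("duplicate genome label '", label, "'")
    genomes[[label]] <<- new_genome(chrs, label)
    chrs <<- list(); pending <<- integer(0)
  }
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_genome()
      label <- trimws(sub("^>", "", line))
      if (!nzchar(label)) stop("line ", ln, ": empty genome label")
      next
    }
    if (is.null(label)) stop("line ", ln, ": markers before any '>' header")
    for (tok in strsplit(line, "[[:space:]]+")[[1L]]) {
      if (tok %in% c("$", "@")) {
        if (!length(pending))
          stop("line ", ln, ": empty chromosome before '", tok, "'")
        chrs[[length(chrs) + 1L]] <-
          new_chromosome(pending, name = paste0("chr", length(chrs) + 1L),
                         circular = tok == "@")
        pending <- integer(0)
      } else {
        val <- suppressWarnings(as.integer(tok))
        if (is.na(val) || val == 0L)
          stop("line ", ln, ": malformed marker token '", tok, "'")
        pending <- c(pending, val)
      }
    }
  }
  flush_genome()
  if (!length(genomes)) stop("no genomes found in ", path)
  genomes
}

read_genomes_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "chromosome", "index", "block_id", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("TSV genome file missing columns: ", paste(miss, collapse = ", "))
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand column must contain only '+' or '-'")
  genomes <- list()
  for (lab in unique(tab$genome)) {
    sub <- tab[tab$genome == lab, , drop = FALSE]
    chrs <- list()
    for (cn in unique(sub$chromosome)) {
      rows <- sub[sub$chromosome == cn, , drop = FALSE]
      rows <- rows[order(rows$index), , drop = FALSE]
      if (!identical(as.integer(rows$index), seq_len(nrow(rows))))
        stop("genome '", lab, "', chromosome '", cn,
             "': index must be 1-based and consecutive")
      mk <- as.integer(rows$block_id) * ifelse(rows$strand == "+", 1L, -1L)
      chrs[[length(chrs) + 1L]] <- new_chromosome(mk, name = as.character(cn))
    }
    genomes[[lab]] <- new_genome(chrs, lab)
  }
  genomes
}

#' Write signed block-order genomes
#'
#' Output is deterministic (genomes ordered by label, chromosomes kept in
#' genome order) and re-readable by [read_genomes()].
#'
#' @param genomes List of validated `genome` objects (or a single genome).
#' @param path Output path.
#' @param format `"grimm"` or `"tsv"`.
#' @export
write_genomes <- function(genomes, path, format = c("grimm", "tsv")) {
  format <- match.arg(format)
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  if (!length(genomes)) stop("refusing to write an empty genome list")
  labs <- vapply(genomes, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) stop("duplicate genome labels")
  genomes <- genomes[order(labs)]
  for (g in genomes)
    if (!length(g$chromosomes)) stop("genome '", g$label, "' is empty")
  if (format == "grimm") {
    out <- character(0)
    for (g in genomes) {
      out <- c(out, paste0(">", g$label))
      for (chr in g$chromosomes)
        out <- c(out, paste(c(chr$markers, if (chr$circular) "@" else "$"),
                            collapse = " "))
    }
    writeLines(out, path)
  } else {
    rows <- list()
    for (g in genomes) {
      if (any(vapply(g$chromosomes, `[[`, logical(1L), "circular")))
        stop("the TSV dialect carries linear chromosomes only")
      for (chr in g$chromosomes)
        rows[[length(rows) + 1L]] <- data.frame(
          genome = g$label, chromosome = chr$name,
          index = seq_along(chr$markers),
          block_id = abs(chr$markers),
          strand = ifelse(chr$markers > 0L, "+", "-"),
          stringsAsFactors = FALSE)
    }
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
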