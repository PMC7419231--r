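# random genome generators used across the suite

rand_genome <- function(n, label = "G", n_chrom = NULL) {
  perm <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
  k <- if (is.null(n_chrom)) sample.int(max(1L, n %/% 2L), 1L) else n_chrom
  cuts <- if (k > 1L) sort(sample.int(n - 1L, k - 1L)) else integer(0)
  b <- c(0L, cuts, n)
  genome(label, lapply(seq_len(k), function(i) perm[(b[i] + 1L):b[i + 1L]]))
}

# a pair at most k DCJ events apart (reversal/translocation mix)
rand_pair <- function(n, k, seed) {
  set.seed(seed)
  a <- rand_genome(n, "A")
  w <- c(reversal = 0.7, translocation = 0.3, fusion = 0, fission = 0,
         transposition = 0)
  b <- evolve_genome(a, k, w, seed = seed + 1000L)$genome
  b$label <- "B"
  list(a = a, b = b)
}
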