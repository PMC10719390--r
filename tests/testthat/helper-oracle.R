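# Naive enumeration oracle for canonical k-mer counting and set algebra,
# independent of the package kernels (pure string manipulation).

options(zwks.quiet = TRUE)

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

naive_canonical <- function(kmer) {
  rc <- naive_revcomp(kmer)
  if (kmer <= rc) kmer else rc
}

# named numeric vector: canonical k-mer -> count, lexicographically sorted
naive_count <- function(seqs, k) {
  out <- character(0)
  for (s in toupper(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      out <- c(out, naive_canonical(w))
    }
  }
  if (length(out) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(out)
  v <- as.numeric(tab)
  names(v) <- names(tab)
  v[order(names(v))]
}

kset_as_vec <- function(s) stats::setNames(s$count, s$kmer)

naive_union_sum <- function(vecs) {
  keys <- sort(unique(unlist(lapply(vecs, names))))
  out <- stats::setNames(numeric(length(keys)), keys)
  for (v in vecs) out[names(v)] <- out[names(v)] + v
  out
}

naive_intersect_all <- function(vecs) {
  keys <- Reduce(intersect, lapply(vecs, names))
  keys <- sort(keys)
  out <- stats::setNames(numeric(length(keys)), keys)
  for (v in vecs) out <- out + v[keys]
  names(out) <- keys
  out
}

naive_difference <- function(a, b) a[!(names(a) %in% names(b))]

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small, fast simulator configuration for unit tests
tiny_sim <- function(seed = 1L, ...) {
  args <- list(seed = seed, autosome_lengths = c(20000L, 20000L),
               z_length = 20000L, n_females = 2L, n_males = 2L,
               short_coverage = 12, long_coverage = 6,
               long_read_mean = 4000, long_read_sd = 1500)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
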