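#' Canonical k-mer sets
#'
#' A `zwks_kmerset` is an exact multiset of canonical k-mers: every stored
#' k-mer is the lexicographic minimum of itself and its reverse complement,
#' counts are >= 1, and entries are kept in lexicographic order. It is the
#' unit of all sex-specific k-mer set algebra: counting per individual,
#' frequency filtering, union-sum across a panel, intersection across all
#' individuals of one sex and difference against the other sex.
#'
#' @param k k-mer length.
#' @param kmer character vector of canonical k-mers (sorted).
#' @param count numeric vector of positive counts.
#' @return an object of class `zwks_kmerset` with elements `k`, `kmer`,
#'   `count`.
#' @keywords internal
new_kmerset <- function(k, kmer = character(), count = numeric()) {
  stopifnot(length(kmer) == length(count))
  structure(list(k = as.integer(k), kmer = kmer, count = as.numeric(count)),
            class = "zwks_kmerset")
}

check_same_k <- function(sets) {
  ks <- vapply(sets, function(s) s$k, integer(1))
  if (length(unique(ks)) > 1L)
    stop("k-mer sets have mixed k: ", paste(unique(ks), collapse = ", "))
  ks[1]
}

#' Count canonical k-mers
#'
#' Exact strand-canonical k-mer counting over a set of sequences. Windows
#' containing any non-ACGT character are skipped. Counting both a sequence
#' and its reverse complement yields identical sets (canonical closure).
#'
#' @param x sequences: character vector, `DNAStringSet`, or path(s) to
#'   FASTA/FASTQ files (gzip transparent).
#' @param k k-mer length, between 3 and 31 (default 17, the panel screening
#'   length; capping at 31 lets a k-mer pack into one 64-bit code).
#' @return a [new_kmerset()] object.
#' @examples
#' count_kmers("ACGTACGT", k = 3)
#' @export
count_kmers <- function(x, k = 17L) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 31L)
    stop("k must be an integer in [3, 31], got ", k)
  seqs <- as_seq_character(x)
  res <- cpp_count_kmers(seqs, k)
  new_kmerset(k, res$kmer, res$count)
}

#' Filter a k-mer set by minimum count
#'
#' Keeps exactly the entries with count >= `t` (counts preserved). With the
#' default panel threshold t = 5 this removes low-frequency k-mers that are
#' dominated by sequencing error.
#'
#' @param s a `zwks_kmerset`.
#' @param t minimum count to keep (>= 1).
#' @return filtered `zwks_kmerset`.
#' @export
filter_min_count <- function(s, t = 5) {
  stopifnot(inherits(s, "zwks_kmerset"), t >= 1)
  keep <- s$count >= t
  new_kmerset(s$k, s$kmer[keep], s$count[keep])
}

#' Union of k-mer sets with summed counts
#'
#' @param sets list of `zwks_kmerset` objects sharing one k.
#' @return `zwks_kmerset` whose keys are the union and whose counts are the
#'   sums of the input counts.
#' @export
kmer_union_sum <- function(sets) {
  if (inherits(sets, "zwks_kmerset")) sets <- list(sets)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "zwks_kmerset")))
  k <- check_same_k(sets)
  keys <- sort(unique(unlist(lapply(sets, `[[`, "kmer"))))
  counts <- numeric(length(keys))
  for (s in sets) {
    idx <- match(s$kmer, keys)
    counts[idx] <- counts[idx] + s$count
  }
  new_kmerset(k, keys, counts)
}

#' Intersection of k-mer sets (keys in every set, counts summed)
#'
#' @param sets list of `zwks_kmerset` objects sharing one k.
#' @return `zwks_kmerset` restricted to keys present in every input; counts
#'   are summed across inputs.
#' @export
kmer_intersect_all <- function(sets) {
  if (inherits(sets, "zwks_kmerset")) sets <- list(sets)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "zwks_kmerset")))
  k <- check_same_k(sets)
  keys <- Reduce(intersect, lapply(sets, `[[`, "kmer"))
  keys <- sort(keys)
  counts <- numeric(length(keys))
  for (s in sets) {
    idx <- match(keys, s$kmer)
    counts <- counts + s$count[idx]
  }
  new_kmerset(k, keys, counts)
}

#' Difference of k-mer sets
#'
#' Entries of `a` whose key is absent from `b`, with counts taken from `a`.
#'
#' @param a,b `zwks_kmerset` objects with the same k.
#' @return `zwks_kmerset`.
#' @export
kmer_difference <- function(a, b) {
  stopifnot(inherits(a, "zwks_kmerset"), inherits(b, "zwks_kmerset"))
  check_same_k(list(a, b))
  keep <- !(a$kmer %in% b$kmer)
  new_kmerset(a$k, a$kmer[keep], a$count[keep])
}

#' Write a k-mer set as TSV
#'
#' On-disk format: a header line `#zwks-kmerset k=<k>` followed by
#' TAB-separated `KMER<TAB>COUNT` rows, canonical uppercase and
#' lexicographically sorted. The round trip through [read_kmerset()] is
#' bit-exact.
#'
#' @param s a `zwks_kmerset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmerset <- function(s, path) {
  stopifnot(inherits(s, "zwks_kmerset"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("#zwks-kmerset k=%d", s$k), con, sep = "\n")
  if (length(s$kmer))
    writeLines(paste0(s$kmer, "\t",
                      format(s$count, scientific = FALSE, trim = TRUE)),
               con, sep = "\n")
  invisible(path)
}

#' Read a k-mer set TSV written by [write_kmerset()]
#'
#' @param path input path.
#' @return a `zwks_kmerset`.
#' @export
read_kmerset <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#zwks-kmerset k=([0-9]+)$", header))[[1]]
  if (length(m) != 2L) stop("not a zwks k-mer set file: ", path)
  k <- as.integer(m[2])
  tab <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("kmer", "count"), quote = "",
                           comment.char = "")
  if (nrow(tab) == 0L) return(new_kmerset(k))
  new_kmerset(k, tab$kmer, tab$count)
}

#' @export
print.zwks_kmerset <- function(x, ...) {
  cat(sprintf("zwks_kmerset: %d canonical %d-mers, total count %s\n",
              length(x$kmer), x$k,
              format(sum(x$count), big.mark = ",", scientific = FALSE)))
  if (length(x$kmer)) {
    n <- min(5L, length(x$kmer))
    cat(paste0("  ", x$kmer[seq_len(n)], " x", x$count[seq_len(n)],
               collapse = "\n"), "\n")
    if (length(x$kmer) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.zwks_kmerset <- function(x) length(x$kmer)
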