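#' Paint a k-mer set along an assembly
#'
#' For every window of every assembly sequence, counts the k-mer start
#' positions whose canonical k-mer belongs to the painted set. Painting the
#' female-specific k-mer set over an assembly localizes its source
#' chromosome: on a differentiated ZW pair essentially all hits fall on W.
#'
#' @param assembly named character vector, `DNAStringSet` or FASTA path.
#' @param painted a `zwks_kmerset`.
#' @param window window size in bp (must be >= k; default 1000).
#' @return data frame of class `zwks_paint_track`: `chrom`, `start`, `end`,
#'   `n_hits`; per-chromosome totals and densities in
#'   `attr(, "chrom_totals")`.
#' @export
paint_kmers <- function(assembly, painted, window = 1000L) {
  stopifnot(inherits(painted, "zwks_kmerset"))
  window <- as.integer(window)
  if (window < painted$k) stop("window must be >= k")
  seqs <- as_seq_character(assembly, "assembly")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  hits <- cpp_window_hits(unname(seqs), painted$kmer, painted$k, window)
  out <- list()
  for (i in seq_along(seqs)) {
    wb <- window_breaks(nchar(seqs[[i]]), window)
    out[[i]] <- data.frame(chrom = names(seqs)[i], start = wb$start,
                           end = wb$end, n_hits = hits[[i]],
                           stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  totals <- tapply(track$n_hits, track$chrom, sum)[names(seqs)]
  attr(track, "chrom_totals") <- totals
  attr(track, "chrom_density") <- totals / nchar(seqs)
  attr(track, "k") <- painted$k
  class(track) <- c("zwks_paint_track", "data.frame")
  track
}

#' @export
summary.zwks_paint_track <- function(object, ...) {
  tot <- attr(object, "chrom_totals")
  cat("zwks paint track: painted k-mer positions per chromosome\n")
  for (cn in names(tot))
    cat(sprintf("  %-8s %s (%.4g per kb)\n", cn,
                format(tot[[cn]], big.mark = ","),
                1000 * attr(object, "chrom_density")[[cn]]))
  invisible(tot)
}

#' MinHash sketch identity between two sequences
#'
#' Builds bottom-`sketch_size` MinHash sketches over the distinct canonical
#' k-mers of each input (fixed splitmix64 hash, reproducible across runs),
#' estimates the Jaccard index j as the fraction of the merged bottom
#' sketch shared by both, and converts it to a per-base identity with the
#' Mash relation identity = 1 + ln(2j / (1 + j)) / k (floored at 0). An
#' alignment-free substitute for whole-chromosome alignment identity, used
#' here to find the Z candidate: the reference chromosome with maximal
#' identity to a recovered W.
#'
#' @param seq_a,seq_b sequences (character/`DNAStringSet`/FASTA path; a
#'   multi-sequence input is treated as one k-mer pool).
#' @param k k-mer length (default 17).
#' @param sketch_size sketch size s (>= 100; default 1000).
#' @return list of class `zwks_sketch_identity`: `j`, `identity`, `shared`,
#'   `sketch_size` (the merged bottom sketch size actually used), and
#'   `zero_overlap` flag.
#' @export
sketch_identity <- function(seq_a, seq_b, k = 17L, sketch_size = 1000L) {
  k <- as.integer(k)
  sketch_size <- as.integer(sketch_size)
  if (sketch_size < 100L) stop("sketch_size must be >= 100")
  a <- as_seq_character(seq_a, "seq_a")
  b <- as_seq_character(seq_b, "seq_b")
  if (any(nchar(a) < k) || any(nchar(b) < k))
    stop("sequences must be at least k bases long")
  sa <- cpp_minhash_sketch(unname(a), k, sketch_size)
  sb <- cpp_minhash_sketch(unname(b), k, sketch_size)
  merged <- sort(unique(c(sa, sb)))
  s <- min(sketch_size, length(merged))
  bottom <- merged[seq_len(s)]
  shared <- sum(bottom %in% sa & bottom %in% sb)
  j <- shared / s
  zero <- shared == 0L
  identity <- mash_identity(j, k)
  structure(list(j = j, identity = identity, shared = shared,
                 sketch_size = s, zero_overlap = zero),
            class = "zwks_sketch_identity")
}

# Mash relation between a Jaccard estimate and per-base identity
mash_identity <- function(j, k) {
  if (j <= 0) return(0)
  max(0, 1 + log(2 * j / (1 + j)) / k)
}

#' @export
print.zwks_sketch_identity <- function(x, ...) {
  cat(sprintf("MinHash identity: %.4f (j = %.4f, %d/%d shared%s)\n",
              x$identity, x$j, x$shared, x$sketch_size,
              if (x$zero_overlap) ", no overlap" else ""))
  invisible(x)
}

#' Sketch identity of a query against every target chromosome
#'
#' @param query query sequence (e.g. a recovered W).
#' @param targets named character vector / `DNAStringSet` / FASTA path of
#'   candidate chromosomes.
#' @inheritParams sketch_identity
#' @return data frame `chrom`, `j`, `identity`, `shared`, `sketch_size`,
#'   sorted by decreasing identity (best Z candidate first).
#' @export
identity_scan <- function(query, targets, k = 17L, sketch_size = 1000L) {
  tg <- as_seq_character(targets, "targets")
  if (is.null(names(tg))) names(tg) <- paste0("seq", seq_along(tg))
  rows <- lapply(names(tg), function(cn) {
    si <- sketch_identity(query, tg[[cn]], k = k, sketch_size = sketch_size)
    data.frame(chrom = cn, j = si$j, identity = si$identity,
               shared = si$shared, sketch_size = si$sketch_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$identity), , drop = FALSE]
}

#' K-mer based assembly consensus accuracy (QV)
#'
#' Counts assembly k-mer positions (T, with multiplicity by default) and
#' the subset b whose canonical k-mer is absent from the read k-mer set;
#' such k-mers are taken as assembly errors. The per-base error is
#' E = 1 - (1 - b/T)^(1/k), QV = -10 log10(E) (infinite when b = 0) and
#' accuracy% = 100 (1 - E).
#'
#' @param assembly sequences (character/`DNAStringSet`/FASTA path).
#' @param read_kmers non-empty `zwks_kmerset` counted from reads.
#' @param k k-mer length (default: `read_kmers$k`).
#' @param distinct count distinct k-mers instead of positions.
#' @return list of class `zwks_qv`: `T`, `b`, `E`, `QV`, `accuracy_pct`.
#' @export
qv_estimate <- function(assembly, read_kmers, k = read_kmers$k,
                        distinct = FALSE) {
  stopifnot(inherits(read_kmers, "zwks_kmerset"))
  if (length(read_kmers) == 0L) stop("read k-mer set is empty")
  if (k != read_kmers$k) stop("k mismatch with read_kmers")
  seqs <- as_seq_character(assembly, "assembly")
  st <- cpp_presence_stats(unname(seqs), read_kmers$kmer, k, distinct)
  total <- st[1]
  if (total == 0) stop("assembly contains no valid k-mer positions")
  b <- total - st[2]
  qv_from_counts(total, b, k)
}

#' QV arithmetic from k-mer totals
#'
#' @param total total assembly k-mer positions T.
#' @param b assembly-only (read-unsupported) k-mer positions.
#' @param k k-mer length.
#' @return list of class `zwks_qv`: `T`, `b`, `E`, `QV`, `accuracy_pct`.
#' @export
qv_from_counts <- function(total, b, k) {
  stopifnot(total > 0, b >= 0, b <= total)
  E <- 1 - (1 - b / total)^(1 / k)
  structure(list(T = total, b = b, E = E,
                 QV = if (b == 0) Inf else -10 * log10(E),
                 accuracy_pct = 100 * (1 - E)),
            class = "zwks_qv")
}

#' @export
print.zwks_qv <- function(x, ...) {
  cat(sprintf("k-mer QV: T=%s, b=%s, E=%.4g, QV=%.2f, accuracy %.4f%%\n",
              format(x$T, big.mark = ",", scientific = FALSE),
              format(x$b, big.mark = ",", scientific = FALSE),
              x$E, x$QV, x$accuracy_pct))
  invisible(x)
}

#' Base accuracy from homozygous SNP count
#'
#' Homozygous variants called from reads of the sequenced individual
#' against its own assembly indicate consensus base errors; the implied
#' accuracy is 100 (1 - n / L) percent.
#'
#' @param n_hom_snps number of homozygous SNPs.
#' @param genome_length assembly length in bp (> 0).
#' @return accuracy percentage.
#' @examples
#' hom_snp_accuracy(7215, 543540000)
#' @export
hom_snp_accuracy <- function(n_hom_snps, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (n_hom_snps < 0 || n_hom_snps > genome_length)
    stop("n_hom_snps must lie in [0, genome_length]")
  100 * (1 - n_hom_snps / genome_length)
}
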