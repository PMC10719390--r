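#' Parameters for sex-specific k-mer derivation and read screening
#'
#' @param k k-mer length (default 17).
#' @param min_count_female per-female minimum k-mer frequency (default 5):
#'   each female set is filtered to counts >= this before intersection,
#'   removing sequencing-error k-mers.
#' @param min_count_male minimum male count that disqualifies a k-mer
#'   (default 1: any occurrence in any male removes it; raising it tolerates
#'   sequencing-error k-mers in males).
#' @param min_hits_per_read minimum number of specific-k-mer hits for a read
#'   to be kept (default 1: a read merely containing a female-specific k-mer
#'   is kept).
#' @param distinct count distinct matching k-mers per read instead of
#'   positional occurrences (default FALSE: a k-mer occurring twice counts
#'   twice, robust on a repeat-expanded W).
#' @return an object of class `zwks_screen_params`.
#' @export
screen_params <- function(k = 17L, min_count_female = 5L, min_count_male = 1L,
                          min_hits_per_read = 1L, distinct = FALSE) {
  p <- list(k = as.integer(k), min_count_female = as.integer(min_count_female),
            min_count_male = as.integer(min_count_male),
            min_hits_per_read = as.integer(min_hits_per_read),
            distinct = isTRUE(distinct))
  if (any(unlist(p[1:4]) < 1L)) stop("all screen parameters must be >= 1")
  structure(p, class = "zwks_screen_params")
}

#' Derive sex-specific k-mers from female and male panels
#'
#' The five-step panel procedure: (1) count k-mers per individual (done
#' upstream), (2) filter each female set to counts >= `min_count_female`,
#' (3) intersect the filtered female sets (k-mers present in every female),
#' (4) union-sum the male sets (filtered at `min_count_male`), (5) subtract
#' the male union. The result is the set of k-mers present in all females
#' and absent from all males - W-linked k-mers in a ZW system.
#'
#' @param female_sets,male_sets lists of `zwks_kmerset` (one per
#'   individual), all with the same k.
#' @param params a [screen_params()].
#' @return a `zwks_kmerset` of sex-specific k-mers.
#' @export
derive_sex_specific_kmers <- function(female_sets, male_sets,
                                      params = screen_params()) {
  if (inherits(female_sets, "zwks_kmerset")) female_sets <- list(female_sets)
  if (inherits(male_sets, "zwks_kmerset")) male_sets <- list(male_sets)
  if (length(female_sets) < 1L || length(male_sets) < 1L)
    stop("need at least one k-mer set per sex")
  k <- check_same_k(c(female_sets, male_sets))
  if (k != params$k)
    stop("k-mer sets have k=", k, " but params$k=", params$k)
  fem <- lapply(female_sets, filter_min_count, t = params$min_count_female)
  core <- kmer_intersect_all(fem)
  males <- kmer_union_sum(lapply(male_sets, filter_min_count,
                                 t = params$min_count_male))
  kmer_difference(core, males)
}

#' Screen reads for sex-specific k-mer content
#'
#' Counts, for every read, the number of k-mer positions whose canonical
#' k-mer belongs to `spec`, and keeps reads with at least
#' `min_hits_per_read` hits. With `pair_mode = "either"`, mates named
#' `<id>/1` and `<id>/2` are kept or dropped together: the pair is kept if
#' either mate passes (used when screening paired proximity-ligation
#' libraries).
#'
#' @param reads character vector of read sequences (named by read id), a
#'   `zwks_reads` individual entry, or a FASTQ path.
#' @param spec non-empty `zwks_kmerset` of specific k-mers.
#' @param params a [screen_params()].
#' @param ids read ids (defaults to names of `reads` or FASTQ ids).
#' @param pair_mode `"independent"` (default) or `"either"`.
#' @param out_fastq optional path: kept reads are written as FASTQ in input
#'   order, preserving ids (and qualities when the input was a FASTQ file).
#' @return an object of class `zwks_partition`: data frame with columns
#'   `read_id`, `n_hits`, `kept`, plus the parameters as attributes.
#' @export
screen_reads <- function(reads, spec, params = screen_params(), ids = NULL,
                         pair_mode = c("independent", "either"),
                         out_fastq = NULL) {
  stopifnot(inherits(spec, "zwks_kmerset"))
  pair_mode <- match.arg(pair_mode)
  if (length(spec) == 0L)
    stop("specific k-mer set is empty: nothing to screen against")
  if (spec$k != params$k)
    stop("spec has k=", spec$k, " but params$k=", params$k)
  quals <- NULL
  if (is.list(reads) && !is.null(reads$seqs)) {
    ids <- if (is.null(ids)) reads$ids else ids
    reads <- reads$seqs
  } else if (is.character(reads) && length(reads) == 1L && is_seq_file(reads)) {
    fq <- Biostrings::readQualityScaledDNAStringSet(reads)
    quals <- as.character(Biostrings::quality(fq))
    ids <- sub("\\s.*$", "", names(fq))
    reads <- as.character(fq)
  }
  if (is.null(ids) && !is.null(names(reads))) ids <- names(reads)
  seqs <- unname(toupper(as.character(reads)))
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  hits <- cpp_kmer_hits(seqs, spec$kmer, params$k, params$distinct)
  kept <- hits >= params$min_hits_per_read
  if (pair_mode == "either") {
    base <- sub("/[12]$", "", ids)
    pair_pass <- tapply(kept, base, any)
    kept <- as.logical(pair_pass[base])
  }
  if (!is.null(out_fastq)) {
    if (is.null(quals)) {
      write_fastq(seqs[kept], ids[kept], out_fastq)
    } else {
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs[kept]),
        Biostrings::PhredQuality(quals[kept]))
      names(x) <- ids[kept]
      Biostrings::writeQualityScaledXStringSet(
        x, out_fastq, compress = grepl("\\.gz$", out_fastq))
    }
  }
  out <- data.frame(read_id = ids, n_hits = hits, kept = kept,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("zwks_partition", "data.frame")
  out
}

#' Evaluate a read partition against simulator truth
#'
#' Treats reads whose truth origin is `target_chrom` as positives:
#' precision = |kept and target-origin| / |kept|, recall = |kept and
#' target-origin| / |target-origin|. Reports exact counts and a
#' per-chromosome confusion table.
#'
#' @param partition a `zwks_partition` from [screen_reads()].
#' @param truth truth data frame (from [simulate_reads()]) with `read_id`
#'   and `chromosome`.
#' @param target_chrom origin chromosome counted as positive (default "W").
#' @return list with `precision`, `recall`, `f1`, `n_kept`, `n_rest`,
#'   `n_target`, `tp`, and `confusion` (origin x kept counts). An empty kept
#'   set yields precision `NaN` with a warning.
#' @export
evaluate_partition <- function(partition, truth, target_chrom = "W") {
  stopifnot(is.data.frame(partition), is.data.frame(truth))
  idx <- match(partition$read_id, truth$read_id)
  if (anyNA(idx)) {
    missing <- partition$read_id[is.na(idx)]
    stop("reads without truth records: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" ... (%d total)", length(missing)))
  }
  origin <- truth$chromosome[idx]
  kept <- partition$kept
  is_target <- origin == target_chrom
  tp <- sum(kept & is_target)
  precision <- if (sum(kept) == 0L) {
    warning("empty kept set: precision undefined (NaN)")
    NaN
  } else tp / sum(kept)
  recall <- if (sum(is_target) == 0L) NaN else tp / sum(is_target)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_kept = sum(kept), n_rest = sum(!kept), n_target = sum(is_target),
       tp = tp,
       confusion = table(origin = origin, kept = kept))
}
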