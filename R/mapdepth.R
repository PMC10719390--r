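#' Build a unique-anchor reference index
#'
#' Indexes every canonical k-mer that occurs exactly once in the reference
#' (counting both strands as one canonical occurrence) with its chromosome,
#' 0-based position and strand. Repeated k-mers are excluded, so reads from
#' repeat-only regions stay unplaced - a lightweight stand-in for aligner
#' mapping-quality filtering.
#'
#' @param reference named character vector, `DNAStringSet`, or FASTA path.
#' @param k anchor length, in [11, 31] (default 17).
#' @return an object of class `zwks_index`: external pointer plus `k`,
#'   `chrom_names`, `chrom_len`, `n_unique`, `n_positions`.
#' @export
build_index <- function(reference, k = 17L) {
  k <- as.integer(k)
  if (is.na(k) || k < 11L || k > 31L) stop("k must be in [11, 31]")
  seqs <- as_seq_character(reference, "reference")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(nchar(seqs) < k))
    stop("reference sequence(s) shorter than k: ",
         paste(names(seqs)[nchar(seqs) < k], collapse = ", "))
  ptr <- cpp_build_index(unname(seqs), k)
  st <- cpp_index_stats(ptr)
  structure(list(ptr = ptr, k = k, chrom_names = names(seqs),
                 chrom_len = stats::setNames(as.integer(st$chrom_len),
                                             names(seqs)),
                 n_unique = st$n_unique, n_positions = st$n_positions),
            class = "zwks_index")
}

#' @export
print.zwks_index <- function(x, ...) {
  cat(sprintf("zwks_index: k=%d, %d chromosome(s), %s bp; %s unique anchors of %s positions\n",
              x$k, length(x$chrom_names),
              format(sum(as.numeric(x$chrom_len)), big.mark = ","),
              format(x$n_unique, big.mark = ",", scientific = FALSE),
              format(x$n_positions, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Place reads by unique-anchor voting
#'
#' Each anchor k-mer of a read that is unique in the reference votes for an
#' implied (chromosome, read start, strand); the read is placed at the
#' plurality vote if it is supported by at least `min_anchors` anchors and
#' more than half of all anchor votes, and left unplaced otherwise.
#' Deterministic; substitution errors only cost individual anchors.
#'
#' @param reads character vector of sequences (named by id), a `zwks_reads`
#'   individual entry, or FASTQ path.
#' @param index a [build_index()] result.
#' @param min_anchors minimum supporting anchors (default 3).
#' @param ids optional read ids.
#' @return data frame: `read_id`, `len`, `chrom` (NA if unplaced), `start`
#'   (0-based), `strand` ("+"/"-"), `n_anchors`, `n_votes`, `placed`.
#' @export
place_reads <- function(reads, index, min_anchors = 3L, ids = NULL) {
  stopifnot(inherits(index, "zwks_index"))
  if (is.list(reads) && !is.null(reads$seqs)) {
    ids <- if (is.null(ids)) reads$ids else ids
    reads <- reads$seqs
  } else if (is.character(reads) && length(reads) == 1L && is_seq_file(reads)) {
    s <- read_seqs(reads)
    ids <- if (is.null(ids)) names(s) else ids
    reads <- s
  }
  if (is.null(ids) && !is.null(names(reads))) ids <- names(reads)
  seqs <- unname(toupper(as.character(reads)))
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  res <- cpp_place_reads(index$ptr, seqs, as.integer(min_anchors))
  data.frame(read_id = ids, len = nchar(seqs),
             chrom = index$chrom_names[res$chrom],
             start = res$start,
             strand = c("-", NA, "+")[res$strand + 2L],
             n_anchors = res$n_anchors, n_votes = res$n_votes,
             placed = !is.na(res$chrom), stringsAsFactors = FALSE)
}

# per-base depth for one chromosome from clipped read intervals
base_depth <- function(starts0, ends0, L) {
  s <- pmax(pmin(starts0, L), 0L)
  e <- pmax(pmin(ends0, L), 0L)
  d <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
  cumsum(d)[seq_len(L)]
}

window_breaks <- function(L, window) {
  starts <- seq.int(0L, L - 1L, by = window)
  data.frame(start = starts, end = pmin(starts + window, L))
}

# per-window mean per-base depth for a set of placements over all chromosomes
group_window_depth <- function(placements, chrom_len, window) {
  out <- list()
  for (i in seq_along(chrom_len)) {
    cn <- names(chrom_len)[i]
    L <- chrom_len[[i]]
    p <- placements[placements$placed & placements$chrom == cn, , drop = FALSE]
    depth <- if (nrow(p)) base_depth(p$start, p$start + p$len, L)
      else numeric(L)
    wb <- window_breaks(L, window)
    cs <- cumsum(c(0, depth))
    wsum <- cs[wb$end + 1L] - cs[wb$start + 1L]
    out[[cn]] <- data.frame(chrom = cn, start = wb$start, end = wb$end,
                            depth = wsum / (wb$end - wb$start),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Windowed log2 male/female depth-ratio track
#'
#' Places of each sex group are converted to per-window mean per-base depth,
#' each group is normalized by the median depth of its autosomal windows,
#' and the per-window statistic log2(M/F) of the normalized depths is
#' reported. On a fully differentiated Z (males ZZ, females ZW) the expected
#' value on Z windows is 1; with an undifferentiated W (reads from W also
#' place on Z) it is 0. Windows where either group has zero normalized depth
#' are reported as missing (NA), not +/-Inf.
#'
#' @param male_placements,female_placements pooled [place_reads()] frames
#'   for each sex group (rbind over individuals).
#' @param index the `zwks_index` used for placement (provides chromosome
#'   lengths).
#' @param window window size in bp (default 1000; 0-based half-open windows,
#'   terminal windows may be short).
#' @param autosomes chromosome names used for normalization (default: all
#'   except "Z" and "W").
#' @return a data frame of class `zwks_depth_track`: `chrom`, `start`,
#'   `end`, `M`, `F`, `norm_M`, `norm_F`, `log2_ratio`; per-chromosome mean
#'   log2 ratios in `attr(, "chrom_means")`.
#' @export
depth_log2_ratio <- function(male_placements, female_placements, index,
                             window = 1000L, autosomes = NULL) {
  stopifnot(inherits(index, "zwks_index"))
  if (nrow(male_placements) == 0L || nrow(female_placements) == 0L)
    stop("both sex groups must contribute placements")
  if (is.null(autosomes))
    autosomes <- setdiff(index$chrom_names, c("Z", "W"))
  if (length(autosomes) == 0L)
    stop("no autosomal chromosomes available for normalization")
  m <- group_window_depth(male_placements, index$chrom_len, window)
  f <- group_window_depth(female_placements, index$chrom_len, window)
  auto <- m$chrom %in% autosomes
  med_m <- stats::median(m$depth[auto])
  med_f <- stats::median(f$depth[auto])
  if (!is.finite(med_m) || !is.finite(med_f) || med_m == 0 || med_f == 0)
    stop("autosomal median depth is zero; cannot normalize")
  track <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                      M = m$depth, F = f$depth,
                      norm_M = m$depth / med_m, norm_F = f$depth / med_f,
                      stringsAsFactors = FALSE)
  ok <- track$norm_M > 0 & track$norm_F > 0
  track$log2_ratio <- ifelse(ok, log2(track$norm_M / track$norm_F), NA_real_)
  cm <- tapply(track$log2_ratio, track$chrom, mean, na.rm = TRUE)
  attr(track, "chrom_means") <- cm[index$chrom_names[index$chrom_names %in%
                                                       names(cm)]]
  attr(track, "autosomes") <- autosomes
  attr(track, "window") <- window
  attr(track, "group_medians") <- c(M = med_m, F = med_f)
  class(track) <- c("zwks_depth_track", "data.frame")
  track
}

#' @export
summary.zwks_depth_track <- function(object, ...) {
  cat("zwks depth track: per-chromosome mean log2(M/F)\n")
  cm <- attr(object, "chrom_means")
  for (cn in names(cm)) cat(sprintf("  %-8s %+.3f\n", cn, cm[[cn]]))
  invisible(attr(object, "chrom_means"))
}

#' Write a depth track as TSV
#' @param track a `zwks_depth_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate, place and summarize a male/female depth-ratio experiment
#'
#' Convenience wrapper for the coverage diagnostic: simulates a population
#' from `config`, places every individual's short reads on the male
#' reference with the unique-anchor mapper, pools placements by sex and
#' returns the windowed log2(M/F) track with its per-chromosome means. On a
#' fully differentiated ZW pair the Z mean is expected near 1; with W
#' identical to Z it is expected near 0 everywhere.
#'
#' @param config a [sim_config()].
#' @param k anchor k-mer length (default 17).
#' @param window window size in bp (default 1000).
#' @param min_anchors placement support threshold (default 3).
#' @return list: `track` (a `zwks_depth_track`), `chrom_means`, `mean_z`,
#'   `mean_autosome`, `mean_all` (mean per-window log2 ratio over Z windows,
#'   autosomal windows, and all windows).
#' @export
depth_ratio_experiment <- function(config, k = 17L, window = 1000L,
                                   min_anchors = 3L) {
  genome <- simulate_individuals(simulate_genome(config))
  short <- simulate_reads(genome, config, kind = "short")
  index <- build_index(genome$reference, k = k)
  sexes <- vapply(genome$individuals, `[[`, "", "sex")
  pls <- lapply(names(genome$individuals), function(id)
    place_reads(short$reads[[id]], index, min_anchors = min_anchors))
  names(pls) <- names(genome$individuals)
  track <- depth_log2_ratio(do.call(rbind, pls[sexes == "M"]),
                            do.call(rbind, pls[sexes == "F"]),
                            index, window = window)
  auto <- attr(track, "autosomes")
  list(track = track,
       chrom_means = attr(track, "chrom_means"),
       mean_z = mean(track$log2_ratio[track$chrom == "Z"], na.rm = TRUE),
       mean_autosome = mean(track$log2_ratio[track$chrom %in% auto],
                            na.rm = TRUE),
       mean_all = mean(track$log2_ratio, na.rm = TRUE))
}

#' Count heterozygous sites from a naive pileup
#'
#' Piles up placed substitution-only reads of one sample column by column; a
#' column is heterozygous when its depth is at least `min_depth` and the
#' second most frequent base has allele fraction within
#' `[min_allele_frac, 1 - min_allele_frac]`. This is a deliberately simple
#' diagnostic caller, not a reimplementation of a production variant caller.
#'
#' @param placements [place_reads()] frame for one sample.
#' @param reads the matching read sequences (character vector aligned with
#'   `placements` rows, or `zwks_reads` individual entry).
#' @param index the `zwks_index` (chromosome names/lengths).
#' @param min_depth minimum column depth (default 5).
#' @param min_allele_frac minimum minor-allele fraction (default 0.3).
#' @param sample sample id stamped on the output (default NA).
#' @return data frame `sample`, `chrom`, `n_het` with attribute
#'   `provenance = "pileup"`.
#' @export
call_het_sites <- function(placements, reads, index, min_depth = 5L,
                           min_allele_frac = 0.3, sample = NA_character_) {
  stopifnot(inherits(index, "zwks_index"))
  if (is.list(reads) && !is.null(reads$seqs)) reads <- reads$seqs
  seqs <- toupper(as.character(reads))
  stopifnot(length(seqs) == nrow(placements))
  chrom_id <- match(placements$chrom, index$chrom_names)
  strand <- ifelse(is.na(placements$strand), 0L,
                   ifelse(placements$strand == "+", 1L, -1L))
  res <- cpp_pileup_het(chrom_id, placements$start, strand, seqs,
                        unname(index$chrom_len), as.integer(min_depth),
                        min_allele_frac)
  out <- data.frame(sample = sample, chrom = index$chrom_names,
                    n_het = res$n_het, stringsAsFactors = FALSE)
  attr(out, "provenance") <- "pileup"
  out
}

#' Count heterozygous genotypes per sample and chromosome from a VCF
#'
#' Parses GT fields (VCF v4.2) and counts, per sample and chromosome,
#' genotypes whose two called alleles differ; missing genotypes are
#' skipped.
#'
#' @param vcf path to a VCF file.
#' @param samples sample names to count (default: all in the file).
#' @return data frame `sample`, `chrom`, `n_het` with attribute
#'   `provenance = "vcf"`.
#' @export
count_het_from_vcf <- function(vcf, samples = NULL) {
  v <- VariantAnnotation::readVcf(vcf)
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(samples)) samples <- colnames(gt)
  absent <- setdiff(samples, colnames(gt))
  if (length(absent))
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "))
  chrom <- as.character(GenomeInfoDb::seqnames(
    SummarizedExperiment::rowRanges(v)))
  is_het <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a)
      length(a) == 2L && !any(a == ".") && a[1] != a[2], logical(1))
  }
  out <- list()
  for (s in samples) {
    het <- is_het(gt[, s])
    tab <- tapply(het, chrom, sum)
    out[[s]] <- data.frame(sample = s, chrom = names(tab),
                           n_het = as.integer(tab), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "provenance") <- "vcf"
  res
}

#' Base-coverage and placement-rate summary
#'
#' @param placements [place_reads()] frame (pooled over samples as needed).
#' @param index the `zwks_index`.
#' @param min_depth coverage threshold (default 5).
#' @return list: `frac_covered` (fraction of reference bases with placed
#'   depth >= `min_depth`), `frac_placed` (fraction of reads placed),
#'   `mean_depth`.
#' @export
coverage_stats <- function(placements, index, min_depth = 5L) {
  stopifnot(inherits(index, "zwks_index"))
  total_bases <- sum(as.numeric(index$chrom_len))
  covered <- 0
  placed_bases <- 0
  for (cn in index$chrom_names) {
    L <- index$chrom_len[[cn]]
    p <- placements[placements$placed & placements$chrom == cn, , drop = FALSE]
    if (nrow(p) == 0L) next
    d <- base_depth(p$start, p$start + p$len, L)
    covered <- covered + sum(d >= min_depth)
    placed_bases <- placed_bases + sum(as.numeric(d))
  }
  list(frac_covered = covered / total_bases,
       frac_placed = if (nrow(placements)) mean(placements$placed) else NaN,
       mean_depth = placed_bases / total_bases)
}
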