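#' Configuration for the synthetic ZW simulator
#'
#' Defines the study conditions emulated by the simulator: a male reference
#' (autosomes + Z), a female W derived from Z, diploid ZZ males and ZW
#' females carrying population heterozygous sites, and short paired /
#' HiFi-like long reads with per-read truth labels.
#'
#' @param seed integer seed; all simulator randomness flows from it through
#'   fixed per-stage offsets.
#' @param autosome_lengths integer vector of autosome lengths (bp).
#' @param z_length Z chromosome length (bp).
#' @param zw_divergence Z-to-W substitution rate per site (default 0.04,
#'   giving ~96% Z-W identity, the nascent-W regime).
#' @param w_repeat_fraction fraction of the W occupied by inserted repeat
#'   copies (default 0.1, a repeat expansion on W only).
#' @param repeat_unit_length length of the single repeat unit (bp).
#' @param w_mode `"diverged"` (W = Z + substitutions + repeat insertions;
#'   `zw_divergence = 0` and `w_repeat_fraction = 0` give W identical to Z)
#'   or `"random"` (fully differentiated W: an independent random sequence
#'   guaranteed to share no canonical `screen_k`-mer with the reference).
#' @param screen_k k used only to enforce k-mer disjointness in
#'   `w_mode = "random"` (default 17).
#' @param n_females,n_males number of diploid individuals per sex (>= 1).
#' @param pop_het_rate heterozygous substitutions per site per individual
#'   planted on paired chromosomes (each hemizygous copy gets half the rate
#'   as homozygous differences).
#' @param short_read_length short-read length (bp); fragments are
#'   `2 * short_read_length` with a mate sequenced inward from each end.
#' @param short_coverage diploid short-read depth per individual (x).
#' @param long_read_mean,long_read_sd mean and sd (bp, natural scale) of the
#'   lognormal long-read length distribution, truncated to [1 kb, 50 kb];
#'   default mean 15 kb mimics a ~20 kb size-selected HiFi library.
#' @param long_coverage diploid long-read depth (x).
#' @param short_error,long_error substitution error rates per base
#'   (substitutions only; no indels, so placed reads stay gap-free).
#' @return an object of class `zwks_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       autosome_lengths = c(300000L, 300000L),
                       z_length = 300000L,
                       zw_divergence = 0.04,
                       w_repeat_fraction = 0.1,
                       repeat_unit_length = 5000L,
                       w_mode = c("diverged", "random"),
                       screen_k = 17L,
                       n_females = 5L,
                       n_males = 5L,
                       pop_het_rate = 1e-3,
                       short_read_length = 150L,
                       short_coverage = 20,
                       long_read_mean = 15000,
                       long_read_sd = 5000,
                       long_coverage = 15,
                       short_error = 1e-3,
                       long_error = 2e-3) {
  w_mode <- match.arg(w_mode)
  cfg <- list(seed = as.integer(seed),
              autosome_lengths = as.integer(autosome_lengths),
              z_length = as.integer(z_length),
              zw_divergence = zw_divergence,
              w_repeat_fraction = w_repeat_fraction,
              repeat_unit_length = as.integer(repeat_unit_length),
              w_mode = w_mode, screen_k = as.integer(screen_k),
              n_females = as.integer(n_females), n_males = as.integer(n_males),
              pop_het_rate = pop_het_rate,
              short_read_length = as.integer(short_read_length),
              short_coverage = short_coverage,
              long_read_mean = long_read_mean, long_read_sd = long_read_sd,
              long_coverage = long_coverage,
              short_error = short_error, long_error = long_error)
  rates <- c(zw_divergence = cfg$zw_divergence,
             w_repeat_fraction = cfg$w_repeat_fraction,
             pop_het_rate = cfg$pop_het_rate,
             short_error = cfg$short_error, long_error = cfg$long_error)
  if (any(rates < 0 | rates >= 1))
    stop("rates and fractions must lie in [0, 1): offending ",
         paste(names(rates)[rates < 0 | rates >= 1], collapse = ", "))
  if (any(c(cfg$autosome_lengths, cfg$z_length) <= 2L * cfg$screen_k))
    stop("all chromosome lengths must exceed 2*k")
  if (cfg$n_females < 1L || cfg$n_males < 1L)
    stop("need at least one individual per sex")
  if (cfg$short_read_length < cfg$screen_k)
    stop("short_read_length must be >= screen_k")
  structure(cfg, class = "zwks_sim_config")
}

#' @export
print.zwks_sim_config <- function(x, ...) {
  cat("zwks simulation config\n")
  cat(sprintf("  genome: %d autosome(s) (%s bp) + Z (%d bp), W mode %s\n",
              length(x$autosome_lengths),
              paste(x$autosome_lengths, collapse = ","), x$z_length, x$w_mode))
  cat(sprintf("  Z-W divergence %.4g, W repeat fraction %.3g (unit %d bp)\n",
              x$zw_divergence, x$w_repeat_fraction, x$repeat_unit_length))
  cat(sprintf("  panel: %dF / %dM, het rate %.3g\n", x$n_females, x$n_males,
              x$pop_het_rate))
  cat(sprintf("  reads: short %dbp @%gx (err %.3g); long lognormal mean %g @%gx (err %.3g)\n",
              x$short_read_length, x$short_coverage, x$short_error,
              x$long_read_mean, x$long_coverage, x$long_error))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases of `seq` at 1-based `pos` with random different bases;
# returns list(seq, ref, alt)
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0L)
    return(list(seq = seq, ref = character(), alt = character()))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- chars[pos]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  chars[pos] <- alt
  list(seq = paste(chars, collapse = ""), ref = ref, alt = alt)
}

# insert `unit` at 0-based gap positions `at` (0 = before first base)
insert_copies <- function(seq, unit, at) {
  if (length(at) == 0L) return(seq)
  at <- sort(at)
  n <- nchar(seq)
  starts <- c(1L, at + 1L)
  ends <- c(at, n)
  pieces <- substring(seq, starts, ends)
  out <- character(2L * length(pieces) - 1L)
  out[seq(1L, length(out), by = 2L)] <- pieces
  out[seq(2L, length(out), by = 2L)] <- unit
  paste(out, collapse = "")
}

#' Simulate a male reference genome and a W chromosome
#'
#' Generates random autosomes and a Z chromosome (the male reference) and
#' derives a W. In `"diverged"` mode the W is the Z with point substitutions
#' at rate `zw_divergence` (every planted site is recorded) plus tandem or
#' dispersed copies of a single random repeat unit totalling
#' `w_repeat_fraction * z_length` bases, emulating a repeat expansion on a
#' nascent W. In `"random"` mode the W is an independent sequence sharing no
#' canonical `screen_k`-mer with the reference (the fully differentiated
#' regime). Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `zwks_genome`: `reference` (named character,
#'   autosomes + Z), `w_sequence`, `zw_sites` (data frame of planted Z-W
#'   substitutions in Z coordinates), `w_repeat` (unit, copies, insertion
#'   points) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "zwks_sim_config"))
  with_seed(config$seed + 101L, {
    ref <- c(
      stats::setNames(vapply(config$autosome_lengths, random_dna, character(1)),
                      paste0("A", seq_along(config$autosome_lengths))),
      Z = random_dna(config$z_length)
    )
    zw_sites <- data.frame(pos = integer(), z_base = character(),
                           w_base = character(), stringsAsFactors = FALSE)
    w_repeat <- list(unit = "", n_copies = 0L, insert_at = integer())
    if (config$w_mode == "random") {
      # a random W still shares a few k-mers with the reference by chance;
      # repair each collision by a point substitution mid-window until the
      # W is strictly k-mer disjoint
      k <- config$screen_k
      ref_k <- count_kmers(unname(ref), k = k)
      w <- random_dna(config$z_length)
      for (i in 1:100) {
        wk <- count_kmers(w, k = k)
        shared <- wk$kmer[wk$kmer %in% ref_k$kmer]
        if (length(shared) == 0L) break
        if (i == 100) stop("could not generate a k-mer-disjoint W")
        flags <- cpp_window_hits(w, shared, k, 1L)[[1]]
        at <- which(flags > 0L) + k %/% 2L
        w <- substitute_bases(w, unique(at))$seq
      }
    } else {
      z <- ref[["Z"]]
      n_sub <- stats::rbinom(1L, config$z_length, config$zw_divergence)
      pos <- sort(sample.int(config$z_length, n_sub))
      sub <- substitute_bases(z, pos)
      w <- sub$seq
      zw_sites <- data.frame(pos = pos, z_base = sub$ref, w_base = sub$alt,
                             stringsAsFactors = FALSE)
      if (config$w_repeat_fraction > 0) {
        n_copies <- as.integer(round(config$w_repeat_fraction *
                                       config$z_length /
                                       config$repeat_unit_length))
        if (n_copies > 0L) {
          unit <- random_dna(config$repeat_unit_length)
          at <- sample.int(nchar(w) + 1L, n_copies, replace = TRUE) - 1L
          w <- insert_copies(w, unit, at)
          w_repeat <- list(unit = unit, n_copies = n_copies, insert_at = at)
        }
      }
    }
    structure(list(reference = ref, w_sequence = w, zw_sites = zw_sites,
                   w_repeat = w_repeat, individuals = NULL, config = config),
              class = "zwks_genome")
  })
}

#' @export
print.zwks_genome <- function(x, ...) {
  cat(sprintf("zwks_genome: %d reference chromosome(s) (%s bp) + W (%d bp)\n",
              length(x$reference),
              format(sum(nchar(x$reference)), big.mark = ","),
              nchar(x$w_sequence)))
  cat(sprintf("  planted Z-W substitutions: %d; W repeat copies: %d\n",
              nrow(x$zw_sites), x$w_repeat$n_copies))
  if (!is.null(x$individuals))
    cat(sprintf("  individuals: %d female, %d male\n",
                sum(vapply(x$individuals, `[[`, "", "sex") == "F"),
                sum(vapply(x$individuals, `[[`, "", "sex") == "M")))
  invisible(x)
}

# plant het sites on a chromosome pair; returns list(h1, h2, sites)
plant_pair_hets <- function(seq, rate, chrom, individual) {
  L <- nchar(seq)
  n <- stats::rbinom(1L, L, rate)
  empty <- data.frame(individual = character(), chromosome = character(),
                      haplotype = integer(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(h1 = seq, h2 = seq, sites = empty))
  pos <- sort(sample.int(L, n))
  hap <- sample(1:2, n, replace = TRUE)
  h1 <- substitute_bases(seq, pos[hap == 1L])
  h2 <- substitute_bases(seq, pos[hap == 2L])
  sites <- data.frame(individual = individual, chromosome = chrom,
                      haplotype = hap[order(hap)], pos = c(pos[hap == 1L],
                                                           pos[hap == 2L]),
                      ref = c(h1$ref, h2$ref), alt = c(h1$alt, h2$alt),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$pos), , drop = FALSE]
  list(h1 = h1$seq, h2 = h2$seq, sites = sites)
}

#' Simulate diploid individuals with planted heterozygous sites
#'
#' Creates `n_females` ZW females and `n_males` ZZ males. Every paired
#' chromosome (autosome pairs; the male Z pair) receives heterozygous
#' substitutions at `pop_het_rate` per site, each on one randomly chosen
#' haplotype; hemizygous copies (female Z and W) receive homozygous
#' substitutions at half that rate, recorded separately. All planted sites
#' are returned as a truth ledger.
#'
#' @param genome a `zwks_genome` from [simulate_genome()].
#' @param config the [sim_config()] used to build it.
#' @return the genome with `individuals` populated (each a list of `id`,
#'   `sex`, `haplotypes` = named character vector `<chrom>_<copy>`), plus a
#'   `truth` element of class `zwks_truth` holding `het_sites`,
#'   `hemi_sites`, `zw_sites` and (after read simulation) `reads`.
#' @export
simulate_individuals <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "zwks_genome"))
  with_seed(config$seed + 202L, {
    ids <- c(paste0("F", seq_len(config$n_females)),
             paste0("M", seq_len(config$n_males)))
    sexes <- rep(c("F", "M"), c(config$n_females, config$n_males))
    het_all <- list()
    hemi_all <- list()
    individuals <- vector("list", length(ids))
    names(individuals) <- ids
    for (i in seq_along(ids)) {
      id <- ids[i]
      haps <- character(0)
      for (chrom in names(genome$reference)[names(genome$reference) != "Z"]) {
        p <- plant_pair_hets(genome$reference[[chrom]], config$pop_het_rate,
                             chrom, id)
        haps[paste0(chrom, "_1")] <- p$h1
        haps[paste0(chrom, "_2")] <- p$h2
        het_all[[length(het_all) + 1L]] <- p$sites
      }
      if (sexes[i] == "M") {
        p <- plant_pair_hets(genome$reference[["Z"]], config$pop_het_rate,
                             "Z", id)
        haps["Z_1"] <- p$h1
        haps["Z_2"] <- p$h2
        het_all[[length(het_all) + 1L]] <- p$sites
      } else {
        for (sc in c("Z", "W")) {
          seq0 <- if (sc == "Z") genome$reference[["Z"]] else genome$w_sequence
          L <- nchar(seq0)
          n <- stats::rbinom(1L, L, config$pop_het_rate / 2)
          pos <- sort(sample.int(L, n))
          sub <- substitute_bases(seq0, pos)
          haps[paste0(sc, "_1")] <- sub$seq
          if (n > 0L)
            hemi_all[[length(hemi_all) + 1L]] <-
              data.frame(individual = id, chromosome = sc, haplotype = 1L,
                         pos = pos, ref = sub$ref, alt = sub$alt,
                         stringsAsFactors = FALSE)
        }
      }
      individuals[[i]] <- list(id = id, sex = sexes[i], haplotypes = haps)
    }
    empty <- data.frame(individual = character(), chromosome = character(),
                        haplotype = integer(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    genome$individuals <- individuals
    genome$truth <- structure(
      list(het_sites = if (length(het_all)) do.call(rbind, het_all) else empty,
           hemi_sites = if (length(hemi_all)) do.call(rbind, hemi_all) else empty,
           zw_sites = genome$zw_sites,
           reads = NULL),
      class = "zwks_truth")
    genome
  })
}

# inject substitution errors at `rate` per base across a read vector
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(as.numeric(lens))
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE, prob = lens)
  pos <- ceiling(stats::runif(n_err) * lens[idx])
  by_read <- split(pos, idx)
  for (nm in names(by_read)) {
    i <- as.integer(nm)
    p <- unique(by_read[[nm]])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    chars[p] <- vapply(chars[p], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
      USE.NAMES = FALSE)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate short paired or HiFi-like long reads with truth labels
#'
#' Short mode draws fragments of `2 * short_read_length` uniformly from each
#' haplotype copy at depth `short_coverage / 2` per copy and sequences one
#' mate inward from each fragment end (ids suffixed `/1`, `/2`). Long mode
#' draws read lengths from a lognormal (mean `long_read_mean`, sd
#' `long_read_sd`, truncated to [1 kb, 50 kb]) at depth `long_coverage / 2`
#' per copy. Substitution errors are injected at the per-kind rate; every
#' read gets one truth record (individual, origin chromosome, haplotype,
#' 0-based half-open coordinates, strand). Deterministic given the seed.
#'
#' @param genome a `zwks_genome` with individuals (see
#'   [simulate_individuals()]).
#' @param config the [sim_config()].
#' @param kind `"short"` or `"long"`.
#' @param individuals ids to simulate (default: all for short; for long
#'   reads the single sequenced female `F1` mirrors a one-individual HiFi
#'   library).
#' @param out_dir if non-NULL, writes one FASTQ per individual
#'   (`<id>_<kind>.fastq[.gz]`, constant Q30 qualities).
#' @param compress gzip the FASTQ files (default TRUE).
#' @return an object of class `zwks_reads`: `kind`, `reads` (named list per
#'   individual with `ids` and `seqs`), `truth` (data frame), `files`.
#' @export
simulate_reads <- function(genome, config = genome$config,
                           kind = c("short", "long"), individuals = NULL,
                           out_dir = NULL, compress = TRUE) {
  stopifnot(inherits(genome, "zwks_genome"))
  if (is.null(genome$individuals))
    stop("simulate_individuals() must run before simulate_reads()")
  kind <- match.arg(kind)
  if (is.null(individuals))
    individuals <- if (kind == "long") "F1" else names(genome$individuals)
  stopifnot(all(individuals %in% names(genome$individuals)))
  cov <- if (kind == "short") config$short_coverage else config$long_coverage
  err <- if (kind == "short") config$short_error else config$long_error
  if (cov <= 0) {
    warning("zero coverage requested; emitting no reads")
  }
  seed_off <- if (kind == "short") 303L else 404L
  with_seed(config$seed + seed_off, {
    out_reads <- list()
    truth_list <- list()
    files <- character(0)
    for (id in individuals) {
      ind <- genome$individuals[[id]]
      ids_i <- character(0)
      seqs_i <- character(0)
      tr <- list()
      serial <- 0L
      for (h in names(ind$haplotypes)) {
        seq <- ind$haplotypes[[h]]
        L <- nchar(seq)
        chrom <- sub("_[0-9]+$", "", h)
        copy <- as.integer(sub("^.*_", "", h))
        if (kind == "short") {
          rl <- config$short_read_length
          flen <- 2L * rl
          if (L < flen) next
          n_frag <- as.integer(round((cov / 2) * L / flen))
          if (n_frag == 0L) next
          s <- sample.int(L - flen + 1L, n_frag, replace = TRUE)
          fwd <- sample(c(TRUE, FALSE), n_frag, replace = TRUE)
          r1 <- ifelse(fwd, substring(seq, s, s + rl - 1L),
                       revcomp(substring(seq, s + flen - rl, s + flen - 1L)))
          r2 <- ifelse(fwd, revcomp(substring(seq, s + flen - rl, s + flen - 1L)),
                       substring(seq, s, s + rl - 1L))
          base <- sprintf("%s_s%06d", id, serial + seq_len(n_frag))
          serial <- serial + n_frag
          ids_i <- c(ids_i, paste0(base, "/1"), paste0(base, "/2"))
          seqs_i <- c(seqs_i, r1, r2)
          st1 <- ifelse(fwd, s, s + flen - rl)
          st2 <- ifelse(fwd, s + flen - rl, s)
          tr[[length(tr) + 1L]] <- data.frame(
            read_id = c(paste0(base, "/1"), paste0(base, "/2")),
            individual = id, chromosome = chrom, haplotype = copy,
            start = c(st1, st2) - 1L, end = c(st1, st2) + rl - 1L,
            strand = c(ifelse(fwd, "+", "-"), ifelse(fwd, "-", "+")),
            stringsAsFactors = FALSE)
        } else {
          target <- (cov / 2) * L
          if (target <= 0) next
          sdlog <- sqrt(log(1 + (config$long_read_sd / config$long_read_mean)^2))
          meanlog <- log(config$long_read_mean) - sdlog^2 / 2
          lens <- integer(0)
          while (sum(as.numeric(lens)) < target) {
            draw <- as.integer(round(stats::rlnorm(64L, meanlog, sdlog)))
            draw <- pmin(pmin(pmax(draw, 1000L), 50000L), L)
            lens <- c(lens, draw)
          }
          # keep reads up to (and including) the first one crossing the target
          lens <- lens[cumsum(as.numeric(lens)) - as.numeric(lens) < target]
          n <- length(lens)
          if (n == 0L) next
          s <- vapply(lens, function(l)
            sample.int(L - l + 1L, 1L), integer(1))
          fwd <- sample(c(TRUE, FALSE), n, replace = TRUE)
          rd <- substring(seq, s, s + lens - 1L)
          rd[!fwd] <- revcomp(rd[!fwd])
          rid <- sprintf("%s_l%06d", id, serial + seq_len(n))
          serial <- serial + n
          ids_i <- c(ids_i, rid)
          seqs_i <- c(seqs_i, rd)
          tr[[length(tr) + 1L]] <- data.frame(
            read_id = rid, individual = id, chromosome = chrom,
            haplotype = copy, start = s - 1L, end = s + lens - 1L,
            strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
        }
      }
      seqs_i <- inject_errors(seqs_i, err)
      out_reads[[id]] <- list(ids = ids_i, seqs = seqs_i)
      truth_list[[id]] <- if (length(tr)) do.call(rbind, tr) else NULL
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        f <- file.path(out_dir, paste0(id, "_", kind, ".fastq",
                                       if (compress) ".gz" else ""))
        write_fastq(seqs_i, ids_i, f, compress = compress)
        files <- c(files, f)
      }
    }
    truth <- do.call(rbind, truth_list[!vapply(truth_list, is.null, TRUE)])
    rownames(truth) <- NULL
    structure(list(kind = kind, reads = out_reads, truth = truth,
                   files = files),
              class = "zwks_reads")
  })
}

#' @export
print.zwks_reads <- function(x, ...) {
  n <- vapply(x$reads, function(r) length(r$ids), integer(1))
  cat(sprintf("zwks_reads (%s): %d individual(s), %s reads, %s bp\n",
              x$kind, length(x$reads),
              format(sum(n), big.mark = ","),
              format(sum(vapply(x$reads, function(r)
                sum(as.numeric(nchar(r$seqs))), numeric(1))),
                big.mark = ",")))
  invisible(x)
}

#' Write reads as FASTQ with constant Q30 qualities
#'
#' @param seqs,ids character vectors of equal length.
#' @param path output path; `.gz` written when `compress`.
#' @param compress gzip output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, ids, path, compress = grepl("\\.gz$", path)) {
  stopifnot(length(seqs) == length(ids))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(n) paste(rep("?", n), collapse = ""),
           character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(x, quals)
  Biostrings::writeQualityScaledXStringSet(q, path, compress = compress)
  invisible(path)
}

#' Write the reference (and W) as FASTA
#'
#' @param genome a `zwks_genome`.
#' @param ref_path path for the male reference FASTA.
#' @param w_path optional path for the W FASTA.
#' @return paths, invisibly.
#' @export
write_genome_fasta <- function(genome, ref_path, w_path = NULL) {
  x <- Biostrings::DNAStringSet(genome$reference)
  Biostrings::writeXStringSet(x, ref_path)
  if (!is.null(w_path)) {
    w <- Biostrings::DNAStringSet(stats::setNames(genome$w_sequence, "W"))
    Biostrings::writeXStringSet(w, w_path)
  }
  invisible(c(ref_path, w_path))
}

#' Write a read truth table as TSV
#'
#' Columns: read_id, individual, chromosome, haplotype, start (0-based),
#' end (half-open), strand.
#'
#' @param truth data frame as produced by [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write planted heterozygous sites as a multi-sample VCF
#'
#' Emits VCF v4.2 with GT-only genotype columns: `0/1` where an individual
#' carries a planted het site, `0/0` elsewhere. Sites are keyed to reference
#' coordinates, so only autosomal and male-Z het plantings appear (the
#' female hemizygous ledger is not genotypable as het).
#'
#' @param truth a `zwks_truth` (or genome `$truth`).
#' @param genome the `zwks_genome` (for contig lengths and sample ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_het_vcf <- function(truth, genome, path) {
  sites <- truth$het_sites
  samples <- names(genome$individuals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(genome$reference),
                       nchar(genome$reference)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(sites) > 0L) {
    key <- paste(sites$chromosome, sites$pos)
    for (kk in unique(key[order(match(sites$chromosome,
                                      names(genome$reference)), sites$pos)])) {
      rows <- sites[key == kk, , drop = FALSE]
      alts <- unique(rows$alt)
      gt <- rep("0/0", length(samples))
      names(gt) <- samples
      gt[rows$individual] <- paste0("0/", match(rows$alt, alts))
      writeLines(paste(c(rows$chromosome[1], rows$pos[1], ".", rows$ref[1],
                         paste(alts, collapse = ","), ".", "PASS", ".", "GT",
                         gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}
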