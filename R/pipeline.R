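#' Pipeline configuration
#'
#' Bundles the simulator block and all screening/mapping thresholds used by
#' [run_pipeline()].
#'
#' @param sim a [sim_config()] block.
#' @param k k-mer length used throughout (default 17).
#' @param min_count_female,min_count_male,min_hits_per_read see
#'   [screen_params()].
#' @param min_anchors unique-anchor placement support (default 3).
#' @param window depth/paint window in bp (default 1000).
#' @param min_depth,min_allele_frac het-caller thresholds.
#' @param sketch_size MinHash sketch size (default 1000).
#' @param qv_min_count read k-mers below this count are dropped before QV
#'   estimation (default 2, removes sequencing-error k-mers).
#' @param write_fastq also write simulated/kept reads as FASTQ artifacts
#'   (default FALSE; the truth tables and k-mer sets are always written).
#' @return an object of class `zwks_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), k = 17L,
                            min_count_female = 5L, min_count_male = 1L,
                            min_hits_per_read = 1L, min_anchors = 3L,
                            window = 1000L, min_depth = 5L,
                            min_allele_frac = 0.3, sketch_size = 1000L,
                            qv_min_count = 2L, write_fastq = FALSE) {
  stopifnot(inherits(sim, "zwks_sim_config"))
  structure(list(sim = sim, k = as.integer(k),
                 min_count_female = as.integer(min_count_female),
                 min_count_male = as.integer(min_count_male),
                 min_hits_per_read = as.integer(min_hits_per_read),
                 min_anchors = as.integer(min_anchors),
                 window = as.integer(window),
                 min_depth = as.integer(min_depth),
                 min_allele_frac = min_allele_frac,
                 sketch_size = as.integer(sketch_size),
                 qv_min_count = as.integer(qv_min_count),
                 write_fastq = isTRUE(write_fastq)),
            class = "zwks_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: top-level threshold keys plus a
#' `simulate:` mapping holding [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `zwks_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y[["simulate"]]
  y[["simulate"]] <- NULL
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate -> count -> sexmers -> screen -> evaluate -> paint ->
#' map/depth/het/coverage -> identity -> qv -> report, writing each stage's
#' artifact as a plain file under `out_dir`. With `resume = TRUE`, a stage
#' whose artifact files already exist is reloaded from disk instead of
#' recomputed; because every stage is deterministic given the seed,
#' deleting any artifact and re-running reproduces it identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @param resume reload existing stage artifacts (default TRUE).
#' @return an object of class `zwks_report` (see [write_report()]); also
#'   written to `out_dir/report.json` and `report.tsv`.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "zwks_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  sim <- cfg$sim
  art <- function(...) file.path(out_dir, ...)
  t0 <- Sys.time()

  # -- simulate (deterministic; artifacts are provenance copies) ----------
  zwks_log("info", "stage simulate: seed ", sim$seed, ", ", sim$n_females,
           "F/", sim$n_males, "M")
  genome <- simulate_individuals(simulate_genome(sim))
  write_genome_fasta(genome, art("reference.fa"), art("W.fa"))
  short <- simulate_reads(genome, sim, kind = "short",
                          out_dir = if (cfg$write_fastq) out_dir else NULL)
  long <- simulate_reads(genome, sim, kind = "long",
                         out_dir = if (cfg$write_fastq) out_dir else NULL)
  write_truth_tsv(rbind(short$truth, long$truth), art("truth_reads.tsv"))
  write_het_vcf(genome$truth, genome, art("het_sites.vcf"))

  # -- count: per-individual k-mer sets from short reads ------------------
  dir.create(art("kmers"), showWarnings = FALSE)
  ind_ids <- names(genome$individuals)
  ksets <- list()
  for (id in ind_ids) {
    f <- art("kmers", paste0(id, ".kmers.tsv"))
    if (resume && file.exists(f)) {
      ksets[[id]] <- read_kmerset(f)
    } else {
      zwks_log("info", "stage count: ", id)
      ksets[[id]] <- count_kmers(short$reads[[id]]$seqs, k = cfg$k)
      write_kmerset(ksets[[id]], f)
    }
  }
  sexes <- vapply(genome$individuals, `[[`, "", "sex")

  # -- sexmers ------------------------------------------------------------
  sp <- screen_params(k = cfg$k, min_count_female = cfg$min_count_female,
                      min_count_male = cfg$min_count_male,
                      min_hits_per_read = cfg$min_hits_per_read)
  f_spec <- art("specific.kmers.tsv")
  if (resume && file.exists(f_spec)) {
    spec <- read_kmerset(f_spec)
  } else {
    zwks_log("info", "stage sexmers")
    spec <- derive_sex_specific_kmers(ksets[sexes == "F"], ksets[sexes == "M"],
                                      sp)
    write_kmerset(spec, f_spec)
  }

  # -- screen female long reads -------------------------------------------
  f_part <- art("partition.tsv")
  long_reads <- long$reads[[1L]]
  if (resume && file.exists(f_part)) {
    partition <- utils::read.table(f_part, sep = "\t", header = TRUE,
                                   colClasses = c("character", "integer",
                                                  "logical"))
    class(partition) <- c("zwks_partition", "data.frame")
  } else {
    zwks_log("info", "stage screen: ", length(long_reads$ids), " long reads")
    partition <- if (length(spec)) {
      screen_reads(long_reads, spec, sp,
                   out_fastq = if (cfg$write_fastq) art("kept.fastq.gz"))
    } else {
      # degenerate undifferentiated case: nothing to screen against
      out <- data.frame(read_id = long_reads$ids,
                        n_hits = 0L, kept = FALSE, stringsAsFactors = FALSE)
      class(out) <- c("zwks_partition", "data.frame")
      out
    }
    utils::write.table(partition, f_part, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # -- evaluate against truth ---------------------------------------------
  ev <- tryCatch(
    withCallingHandlers(
      evaluate_partition(partition, long$truth, target_chrom = "W"),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)

  # -- paint specific k-mers over reference + W ---------------------------
  assembly <- c(genome$reference, W = genome$w_sequence)
  f_paint <- art("paint.tsv")
  if (resume && file.exists(f_paint)) {
    paint <- utils::read.table(f_paint, sep = "\t", header = TRUE)
    totals <- tapply(paint$n_hits, paint$chrom, sum)[names(assembly)]
  } else {
    zwks_log("info", "stage paint")
    paint <- if (length(spec)) paint_kmers(assembly, spec, cfg$window) else
      NULL
    totals <- if (is.null(paint))
      stats::setNames(rep(0, length(assembly)), names(assembly)) else
        attr(paint, "chrom_totals")
    if (!is.null(paint))
      utils::write.table(as.data.frame(paint), f_paint, sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  # -- place short reads, depth ratio, hets, coverage ---------------------
  zwks_log("info", "stage mapdepth: placing short reads")
  index <- build_index(genome$reference, k = cfg$k)
  placements <- lapply(ind_ids, function(id)
    place_reads(short$reads[[id]], index, min_anchors = cfg$min_anchors))
  names(placements) <- ind_ids
  males <- do.call(rbind, placements[sexes == "M"])
  females <- do.call(rbind, placements[sexes == "F"])
  track <- depth_log2_ratio(males, females, index, window = cfg$window)
  write_depth_track(track, art("depth_track.tsv"))
  chrom_means <- attr(track, "chrom_means")

  hets <- do.call(rbind, lapply(ind_ids, function(id)
    call_het_sites(placements[[id]], short$reads[[id]], index,
                   min_depth = cfg$min_depth,
                   min_allele_frac = cfg$min_allele_frac, sample = id)))
  utils::write.table(hets, art("hets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_z <- hets$n_het[hets$chrom == "Z" & hets$sample %in% ind_ids[sexes == "F"]]
  m_z <- hets$n_het[hets$chrom == "Z" & hets$sample %in% ind_ids[sexes == "M"]]
  het_p <- tryCatch(
    stats::wilcox.test(f_z, m_z, alternative = "greater", exact = FALSE)$p.value,
    error = function(e) NA_real_)
  cov <- coverage_stats(do.call(rbind, placements), index,
                        min_depth = cfg$min_depth)

  # -- identity: W against every reference chromosome ---------------------
  zwks_log("info", "stage identity")
  idscan <- identity_scan(genome$w_sequence, genome$reference, k = cfg$k,
                          sketch_size = cfg$sketch_size)
  utils::write.table(idscan, art("identity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- qv -----------------------------------------------------------------
  zwks_log("info", "stage qv")
  read_kmers <- filter_min_count(kmer_union_sum(ksets[sexes == "F"]),
                                 cfg$qv_min_count)
  qv <- qv_estimate(assembly, read_kmers, k = cfg$k)

  report <- structure(list(
    seed = sim$seed,
    params = list(k = cfg$k, min_count_female = cfg$min_count_female,
                  min_count_male = cfg$min_count_male,
                  min_hits_per_read = cfg$min_hits_per_read,
                  min_anchors = cfg$min_anchors, window = cfg$window,
                  min_depth = cfg$min_depth,
                  min_allele_frac = cfg$min_allele_frac,
                  sketch_size = cfg$sketch_size),
    n_specific_kmers = length(spec),
    partition = list(
      n_kept = sum(partition$kept), n_rest = sum(!partition$kept),
      precision = if (is.null(ev)) NA_real_ else ev$precision,
      recall = if (is.null(ev)) NA_real_ else ev$recall,
      f1 = if (is.null(ev)) NA_real_ else ev$f1),
    paint_totals = as.list(totals),
    depth_mean_log2 = as.list(chrom_means),
    hets = list(female_mean_z = mean(f_z), male_mean_z = mean(m_z),
                p_value = het_p),
    identity = list(best_chrom = idscan$chrom[1],
                    identity = idscan$identity[1], j = idscan$j[1]),
    qv = list(T = qv$T, b = qv$b, E = qv$E, QV = qv$QV,
              accuracy_pct = qv$accuracy_pct),
    coverage = cov,
    versions = list(zwks = as.character(utils::packageVersion("zwks")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")),
    class = "zwks_report")
  write_report(report, out_dir)
  report
}

#' Write a pipeline report as JSON and TSV
#'
#' The JSON schema is stable across runs: every documented key is present,
#' with unavailable values serialized as nulls; the TSV is a flat
#' `key<TAB>value` summary of the scalar fields.
#'
#' @param report a `zwks_report`.
#' @param out_dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "zwks_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fj <- file.path(out_dir, "report.json")
  x <- unclass(report)
  # JSON has no Inf: encode an infinite QV (zero error k-mers) as string
  if (is.infinite(x$qv$QV)) x$qv$QV <- "Inf"
  jsonlite::write_json(x, fj, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  ft <- file.path(out_dir, "report.tsv")
  flat <- unlist(x)
  utils::write.table(data.frame(key = names(flat), value = as.character(flat)),
                     ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fj, ft))
}

#' Read a report written by [write_report()]
#'
#' @param path path to `report.json`.
#' @return a `zwks_report` list.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$qv$QV, "Inf")) x$qv$QV <- Inf
  structure(x, class = "zwks_report")
}

#' @export
print.zwks_report <- function(x, ...) {
  cat("zwks pipeline report\n")
  cat(sprintf("  specific k-mers: %s\n",
              format(x$n_specific_kmers, big.mark = ",")))
  cat(sprintf("  partition: %d kept / %d rest (precision %.4g, recall %.4g)\n",
              x$partition$n_kept, x$partition$n_rest, x$partition$precision,
              x$partition$recall))
  dm <- unlist(x$depth_mean_log2)
  cat("  mean log2(M/F):", paste(sprintf("%s %+0.3f", names(dm), dm),
                                 collapse = ", "), "\n")
  cat(sprintf("  Z het counts: female mean %.1f vs male mean %.1f (p = %.3g)\n",
              x$hets$female_mean_z, x$hets$male_mean_z, x$hets$p_value))
  cat(sprintf("  best Z candidate: %s (identity %.4f)\n",
              x$identity$best_chrom, x$identity$identity))
  cat(sprintf("  QV %.2f (accuracy %.4f%%), %.4g%% bases covered >= min depth\n",
              if (is.character(x$qv$QV)) Inf else x$qv$QV,
              x$qv$accuracy_pct, 100 * x$coverage$frac_covered))
  invisible(x)
}
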