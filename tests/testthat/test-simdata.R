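test_that("zero divergence and zero repeat fraction give W identical to Z", {
  cfg <- tiny_sim(zw_divergence = 0, w_repeat_fraction = 0)
  g <- simulate_genome(cfg)
  expect_identical(g$w_sequence, g$reference[["Z"]])
  expect_equal(nrow(g$zw_sites), 0L)
})

test_that("planted Z-W substitutions recover the configured divergence", {
  cfg <- tiny_sim(seed = 3, z_length = 50000L, w_repeat_fraction = 0)
  g <- simulate_genome(cfg)
  d_hat <- nrow(g$zw_sites) / cfg$z_length
  sd3 <- 3 * sqrt(cfg$zw_divergence * (1 - cfg$zw_divergence) / cfg$z_length)
  expect_lt(abs(d_hat - cfg$zw_divergence), sd3)
  # ledger-based alignment-free identity
  expect_lt(abs((1 - d_hat) - 0.96), 0.005)
  # every planted site records the actual Z and W alleles
  zc <- strsplit(g$reference[["Z"]], "")[[1]]
  expect_identical(zc[g$zw_sites$pos], g$zw_sites$z_base)
  expect_true(all(g$zw_sites$z_base != g$zw_sites$w_base))
})

test_that("repeat expansion grows W by the configured fraction", {
  cfg <- tiny_sim(z_length = 50000L, w_repeat_fraction = 0.1,
                  repeat_unit_length = 2000L)
  g <- simulate_genome(cfg)
  expect_lt(abs(nchar(g$w_sequence) - 1.1 * 50000), 2000 + 1)
  expect_equal(g$w_repeat$n_copies, as.integer(round(0.1 * 50000 / 2000)))
  expect_equal(nchar(g$w_sequence),
               50000L + g$w_repeat$n_copies * 2000L)
})

test_that("a random-mode W shares no canonical screen k-mer with the reference", {
  cfg <- tiny_sim(seed = 9, w_mode = "random")
  g <- simulate_genome(cfg)
  wk <- count_kmers(g$w_sequence, cfg$screen_k)
  rk <- count_kmers(unname(g$reference), cfg$screen_k)
  expect_length(intersect(wk$kmer, rk$kmer), 0)
  expect_equal(nchar(g$w_sequence), cfg$z_length)
})

test_that("individuals carry the right sex chromosomes and planted het sites", {
  cfg <- tiny_sim(seed = 5, pop_het_rate = 1e-3)
  g <- simulate_individuals(simulate_genome(cfg))
  for (ind in g$individuals) {
    haps <- names(ind$haplotypes)
    if (ind$sex == "F") {
      expect_setequal(haps, c("A1_1", "A1_2", "A2_1", "A2_2", "Z_1", "W_1"))
    } else {
      expect_setequal(haps, c("A1_1", "A1_2", "A2_1", "A2_2", "Z_1", "Z_2"))
    }
  }
  # expected het sites per individual per autosome: Binomial(L, rate)
  led <- g$truth$het_sites
  cnt <- table(led$individual[led$chromosome == "A1"])
  expect_true(all(abs(cnt - 20) < 4 * sqrt(20)))
  # planted alleles differ from the reference base
  a1 <- strsplit(g$reference[["A1"]], "")[[1]]
  sub <- led[led$chromosome == "A1", ]
  expect_identical(a1[sub$pos], sub$ref)
  expect_true(all(sub$ref != sub$alt))
})

test_that("zero het rate reproduces the reference haplotypes exactly", {
  cfg <- tiny_sim(pop_het_rate = 0)
  g <- simulate_individuals(simulate_genome(cfg))
  m1 <- g$individuals[["M1"]]
  expect_identical(m1$haplotypes[["A1_1"]], g$reference[["A1"]])
  expect_identical(m1$haplotypes[["Z_2"]], g$reference[["Z"]])
  expect_equal(nrow(g$truth$het_sites), 0L)
})

test_that("error-free short reads are exact substrings of their source haplotype", {
  cfg <- tiny_sim(seed = 2, short_error = 0, short_coverage = 4)
  g <- simulate_individuals(simulate_genome(cfg))
  sh <- simulate_reads(g, kind = "short", individuals = "F1")
  tr <- sh$truth
  seqs <- sh$reads[["F1"]]$seqs
  ids <- sh$reads[["F1"]]$ids
  expect_identical(sort(ids), sort(tr$read_id))
  idx <- match(ids, tr$read_id)
  for (i in seq_along(ids)) {
    hap <- g$individuals[["F1"]]$haplotypes[[
      paste0(tr$chromosome[idx[i]], "_", tr$haplotype[idx[i]])]]
    span <- substr(hap, tr$start[idx[i]] + 1L, tr$end[idx[i]])
    obs <- if (tr$strand[idx[i]] == "+") seqs[i] else naive_revcomp(seqs[i])
    expect_identical(obs, span)
  }
})

test_that("read yield tracks the configured coverage and truth covers every read", {
  cfg <- tiny_sim(seed = 4)
  g <- simulate_individuals(simulate_genome(cfg))
  sh <- simulate_reads(g, kind = "short")
  for (id in names(sh$reads)) {
    diploid <- sum(nchar(g$individuals[[id]]$haplotypes))
    got <- sum(nchar(sh$reads[[id]]$seqs))
    expect_lt(abs(got - cfg$short_coverage / 2 * diploid) / diploid, 0.01)
  }
  # conservation: every truth origin names a chromosome its individual has
  tr <- sh$truth
  for (id in unique(tr$individual)) {
    chroms <- unique(sub("_[0-9]+$", "",
                         names(g$individuals[[id]]$haplotypes)))
    expect_true(all(tr$chromosome[tr$individual == id] %in% chroms))
  }
})

test_that("long reads are lognormal within bounds and W bases match genome share", {
  cfg <- tiny_sim(seed = 6, z_length = 30000L, long_coverage = 12)
  g <- simulate_individuals(simulate_genome(cfg))
  lg <- simulate_reads(g, kind = "long", individuals = "F1")
  lens <- nchar(lg$reads[["F1"]]$seqs)
  expect_true(all(lens >= 1000 & lens <= 50000))
  tr <- lg$truth
  expect_true("W" %in% tr$chromosome)
  w_frac <- sum(tr$end[tr$chromosome == "W"] - tr$start[tr$chromosome == "W"]) /
    sum(tr$end - tr$start)
  # per-copy coverage is uniform, so W's base share ~ |W| / diploid content
  diploid <- sum(nchar(g$individuals[["F1"]]$haplotypes))
  expect_lt(abs(w_frac - nchar(g$w_sequence) / diploid), 0.05)
  # males have no W-origin reads
  lg_m <- simulate_reads(g, kind = "long", individuals = "M1")
  expect_false("W" %in% lg_m$truth$chromosome)
})

test_that("simulation is deterministic given the seed, down to FASTQ bytes", {
  cfg <- tiny_sim(seed = 8, autosome_lengths = 20000L, short_coverage = 3)
  run <- function(dir) {
    g <- simulate_individuals(simulate_genome(cfg))
    simulate_reads(g, kind = "short", individuals = "M1", out_dir = dir,
                   compress = FALSE)
  }
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run(d1); r2 <- run(d2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  f1 <- file.path(d1, "M1_short.fastq"); f2 <- file.path(d2, "M1_short.fastq")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_sim(zw_divergence = 1.2), "rates")
  expect_error(tiny_sim(n_females = 0), "at least one")
  expect_error(tiny_sim(z_length = 10L), "exceed")
  expect_warning(
    simulate_reads(simulate_individuals(simulate_genome(
      tiny_sim(short_coverage = 0))), kind = "short", individuals = "M1"),
    "zero coverage")
})
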