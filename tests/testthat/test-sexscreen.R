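# builds a panel of per-individual k-mer sets from random sequences
random_panel <- function(n, len = 120, k = 4) {
  lapply(seq_len(n), function(i) count_kmers(random_seq(len), k))
}

test_that("derivation equals the composition of the four set primitives", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    fem <- random_panel(3, k = k)
    mal <- random_panel(3, k = k)
    p <- screen_params(k = k, min_count_female = sample(1:3, 1))
    got <- derive_sex_specific_kmers(fem, mal, p)
    want <- kmer_difference(
      kmer_intersect_all(lapply(fem, filter_min_count,
                                t = p$min_count_female)),
      kmer_union_sum(lapply(mal, filter_min_count, t = p$min_count_male)))
    expect_identical(got, want)
  }
})

test_that("a marker k-mer in all females and no male survives; identical panels yield nothing", {
  # brute-force oracle over the full 3-mer space on a constructed toy;
  # the marker's mixed-alphabet 3-mers cannot arise from G/T-only males
  # (whose canonical closure is {G,T}^3 and {A,C}^3)
  set.seed(29)
  marker <- strrep("ACG", 10)  # canonical 3-mers ACG/CGA/GAC, counts >= 5
  fem <- lapply(1:3, function(i)
    count_kmers(c(marker, random_seq(60, c("G", "T"))), 3))
  mal <- lapply(1:3, function(i) count_kmers(random_seq(60, c("G", "T")), 3))
  spec <- derive_sex_specific_kmers(fem, mal, screen_params(k = 3))
  for (km in c("ACG", "CGA", "GAC")) expect_true(km %in% spec$kmer)
  # G/T-only male k-mers canonicalize into A/C space, so verify by oracle
  all3 <- apply(expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                            b3 = c("A", "C", "G", "T")), 1, paste, collapse = "")
  in_all_fem <- vapply(all3, function(km)
    all(vapply(fem, function(s) {
      cnt <- s$count[s$kmer == naive_canonical(km)]
      length(cnt) == 1 && cnt >= 5
    }, TRUE)), TRUE)
  in_any_mal <- vapply(all3, function(km)
    any(vapply(mal, function(s) naive_canonical(km) %in% s$kmer, TRUE)), TRUE)
  want <- sort(unique(vapply(all3[in_all_fem & !in_any_mal],
                             naive_canonical, "")))
  expect_identical(spec$kmer, want)
  # same panel on both sides leaves nothing specific
  expect_equal(length(derive_sex_specific_kmers(fem, fem,
                                                screen_params(k = 3))), 0L)
  expect_error(derive_sex_specific_kmers(list(), mal, screen_params(k = 3)),
               "at least one")
})

test_that("read screening counts positional hits and applies the threshold", {
  spec <- zwks:::new_kmerset(3, "ACG", 1)
  p <- screen_params(k = 3)
  # TTTACGTTT: the ACG window hits, and the following CGT window
  # canonicalizes to ACG and hits again -> 2 positional hits
  part <- screen_reads(c(r1 = "TTTACGTTT", r2 = "TTTTTTTT", r3 = "ACGACGT"),
                       spec, p)
  expect_equal(part$n_hits, c(2L, 0L, 3L))
  expect_equal(part$kept, c(TRUE, FALSE, TRUE))
  expect_equal(part$read_id, c("r1", "r2", "r3"))
  # hit-count threshold boundary (ACGA has exactly one matching window)
  p2 <- screen_params(k = 3, min_hits_per_read = 2)
  expect_equal(screen_reads(c("ACGA"), spec, p2)$kept, FALSE)
  expect_equal(screen_reads(c("ACGA"), spec, p)$n_hits, 1L)
  expect_error(screen_reads("ACGT", zwks:::new_kmerset(3), p), "empty")
})

test_that("paired mode keeps a pair when either mate passes", {
  spec <- zwks:::new_kmerset(3, "ACG", 1)
  p <- screen_params(k = 3)
  part <- screen_reads(c("a/1" = "ACGT", "a/2" = "TTTT",
                         "b/1" = "TTTT", "b/2" = "TTTT"),
                       spec, p, pair_mode = "either")
  expect_equal(part$kept, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("raising thresholds never grows the outputs (monotonicity)", {
  set.seed(37)
  fem <- random_panel(3, len = 400, k = 5)
  mal <- random_panel(3, len = 400, k = 5)
  reads <- vapply(1:30, function(i) random_seq(60), "")
  sizes <- integer(0)
  kept_sizes <- integer(0)
  for (t in 1:4) {
    p <- screen_params(k = 5, min_count_female = t)
    spec <- derive_sex_specific_kmers(fem, mal, p)
    sizes <- c(sizes, length(spec))
  }
  expect_true(all(diff(sizes) <= 0))
  spec <- derive_sex_specific_kmers(fem, mal, screen_params(k = 5, min_count_female = 1))
  for (h in 1:4) {
    p <- screen_params(k = 5, min_hits_per_read = h)
    kept_sizes <- c(kept_sizes, sum(screen_reads(reads, spec, p)$kept))
  }
  expect_true(all(diff(kept_sizes) <= 0))
})

test_that("fully differentiated W with error-free reads is recovered exactly", {
  cfg <- tiny_sim(seed = 21, w_mode = "random", short_error = 0,
                  long_error = 0, short_coverage = 20)
  g <- simulate_individuals(simulate_genome(cfg))
  sh <- simulate_reads(g, kind = "short")
  lg <- simulate_reads(g, kind = "long", individuals = "F1")
  sexes <- vapply(g$individuals, `[[`, "", "sex")
  ks <- lapply(sh$reads, function(r) count_kmers(r$seqs, 17))
  spec <- derive_sex_specific_kmers(ks[sexes == "F"], ks[sexes == "M"],
                                    screen_params())
  # no specific k-mer occurs in any male read set
  for (id in names(ks)[sexes == "M"])
    expect_length(intersect(spec$kmer, ks[[id]]$kmer), 0)
  part <- screen_reads(lg$reads[["F1"]], spec, screen_params())
  ev <- evaluate_partition(part, lg$truth, target_chrom = "W")
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # the kept reads are exactly the W-origin reads
  w_ids <- lg$truth$read_id[lg$truth$chromosome == "W"]
  expect_setequal(part$read_id[part$kept], w_ids)
})

test_that("partition evaluation handles degenerate and malformed inputs", {
  truth <- data.frame(read_id = c("a", "b", "c"),
                      chromosome = c("W", "Z", "W"))
  part <- data.frame(read_id = c("a", "b", "c"), n_hits = c(1L, 0L, 0L),
                     kept = c(TRUE, FALSE, FALSE))
  ev <- evaluate_partition(part, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 0.5)
  part$kept <- FALSE
  expect_warning(ev2 <- evaluate_partition(part, truth), "precision undefined")
  expect_true(is.nan(ev2$precision))
  expect_equal(ev2$recall, 0)
  part$read_id[1] <- "zzz"
  expect_error(evaluate_partition(part, truth), "without truth")
})
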