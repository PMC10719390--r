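test_that("index stores exactly the unique canonical k-mers", {
  # periodic sequence: every 11-mer recurs, so nothing is unique
  per <- strrep("ACGT", 12)
  idx <- build_index(c(R = per), k = 11)
  expect_equal(idx$n_unique, 0)
  # a sequence concatenated with its reverse complement duplicates every
  # canonical k-mer
  set.seed(41)
  s <- random_seq(60)
  idx2 <- build_index(c(X = paste0(s, "A", naive_revcomp(s))), k = 11)
  expect_lte(idx2$n_unique, 2 * 11)  # only junction-spanning k-mers can be unique
  # random sequence: essentially every position is unique at k = 17
  r <- random_seq(10000)
  idx3 <- build_index(c(C = r), k = 17)
  expect_equal(idx3$n_positions, 10000 - 17 + 1)
  expect_gte(idx3$n_unique, 0.999 * idx3$n_positions)
  expect_lte(idx3$n_unique, nchar(r) - 17 + 1)
  expect_error(build_index(c(A = "ACGTACGTAC"), k = 11), "shorter than k")
  expect_error(build_index(c(A = r), k = 5), "k must be")
})

test_that("error-free reads from unique regions are placed exactly; repeat reads are not", {
  set.seed(43)
  uniq <- random_seq(5000)
  rep_chrom <- strrep("ACGTACGTACG", 100)
  idx <- build_index(c(U = uniq, R = rep_chrom), k = 17)
  starts <- seq(1, 4800, by = 37)
  fwd <- substring(uniq, starts, starts + 99)
  rev <- vapply(fwd, naive_revcomp, "")
  pl <- place_reads(c(fwd, rev), idx, min_anchors = 3)
  expect_true(all(pl$placed))
  expect_true(all(pl$chrom == "U"))
  expect_equal(pl$start, rep(starts - 1L, 2))
  expect_equal(pl$strand, rep(c("+", "-"), each = length(starts)))
  # reads purely from the repeat have no unique anchors
  rr <- substring(rep_chrom, c(1, 101, 301), c(100, 200, 400))
  expect_false(any(place_reads(rr, idx)$placed))
})

test_that("reads with 1% substitutions still place at their true coordinate", {
  set.seed(47)
  ref <- random_seq(20000)
  idx <- build_index(c(C = ref), k = 17)
  n <- 300
  starts <- sample.int(20000 - 150, n)
  reads <- substring(ref, starts, starts + 149)
  # plant ~1.5 substitutions per read
  reads <- vapply(reads, function(r) {
    pos <- which(runif(150) < 0.01)
    for (p in pos) {
      b <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    r
  }, "", USE.NAMES = FALSE)
  pl <- place_reads(reads, idx, min_anchors = 3)
  correct <- pl$placed & pl$start == starts - 1L & pl$chrom == "C"
  expect_gte(mean(correct), 0.99)
})

test_that("depth ratio is zero for identical groups and antisymmetric under swap", {
  set.seed(53)
  ref <- c(A1 = random_seq(30000), Z = random_seq(30000))
  idx <- build_index(ref, k = 17)
  mk_reads <- function(seed) {
    set.seed(seed)
    do.call(rbind, lapply(names(ref), function(cn) {
      s <- sample.int(30000 - 150, 600)
      pl <- place_reads(substring(ref[[cn]], s, s + 149), idx)
      pl
    }))
  }
  a <- mk_reads(1); b <- mk_reads(2)
  tr0 <- depth_log2_ratio(a, a, idx, window = 1000)
  expect_true(all(abs(tr0$log2_ratio) < 1e-12, na.rm = TRUE))
  tr_ab <- depth_log2_ratio(a, b, idx, window = 1000)
  tr_ba <- depth_log2_ratio(b, a, idx, window = 1000)
  expect_equal(tr_ab$log2_ratio, -tr_ba$log2_ratio)
  # depth conservation: window depth * length sums to placed bases
  placed_bases <- sum(a$len[a$placed])
  expect_equal(sum(tr_ab$M * (tr_ab$end - tr_ab$start)), placed_bases)
})

test_that("het caller flags balanced columns and ignores homozygous ones", {
  set.seed(59)
  ref <- c(C = random_seq(400))
  idx <- build_index(ref, k = 17)
  clean <- rep(ref[["C"]], 10)
  mut <- clean
  # give 5 of 10 reads an alternate allele at position 200
  for (i in 1:5) substr(mut[i], 200, 200) <-
    setdiff(c("A", "C", "G", "T"), substr(ref[["C"]], 200, 200))[1]
  pl <- data.frame(read_id = paste0("r", 1:10), len = 400, chrom = "C",
                   start = 0L, strand = "+", n_anchors = 10L, n_votes = 10L,
                   placed = TRUE)
  het <- call_het_sites(pl, mut, idx, min_depth = 5, min_allele_frac = 0.3,
                        sample = "S1")
  expect_equal(het$n_het[het$chrom == "C"], 1L)
  hom <- call_het_sites(pl, clean, idx, min_depth = 5, min_allele_frac = 0.3)
  expect_equal(hom$n_het[hom$chrom == "C"], 0L)
  # below min depth nothing is called
  shallow <- call_het_sites(pl[1:4, ], mut[1:4], idx, min_depth = 5,
                            min_allele_frac = 0.3)
  expect_equal(sum(shallow$n_het), 0L)
})

test_that("female Z accumulates more apparent het sites than male Z in a nascent-W simulation", {
  cfg <- tiny_sim(seed = 61, short_coverage = 20)
  g <- simulate_individuals(simulate_genome(cfg))
  sh <- simulate_reads(g, kind = "short", individuals = c("F1", "M1"))
  idx <- build_index(g$reference, k = 17)
  hets <- lapply(c("F1", "M1"), function(id) {
    pl <- place_reads(sh$reads[[id]], idx)
    call_het_sites(pl, sh$reads[[id]], idx, sample = id)
  })
  f_z <- hets[[1]]$n_het[hets[[1]]$chrom == "Z"]
  m_z <- hets[[2]]$n_het[hets[[2]]$chrom == "Z"]
  # W-derived reads placed on Z create apparent het sites in the female
  expect_gt(f_z, m_z)
})

test_that("VCF het counting matches hand-built genotypes and the simulator ledger", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t20\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1",
    "chr1\t30\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0"), vcf)
  tab <- count_het_from_vcf(vcf)
  expect_equal(tab$n_het[tab$sample == "S1"], 1L)
  expect_equal(tab$n_het[tab$sample == "S2"], 1L)
  expect_error(count_het_from_vcf(vcf, samples = "nope"), "not in VCF")
  # round trip: planted het ledger -> VCF -> counts
  g <- simulate_individuals(simulate_genome(tiny_sim(seed = 67)))
  f <- tempfile(fileext = ".vcf")
  write_het_vcf(g$truth, g, f)
  got <- count_het_from_vcf(f)
  led <- g$truth$het_sites
  for (id in names(g$individuals)) {
    for (cn in names(g$reference)) {
      expect_equal(got$n_het[got$sample == id & got$chrom == cn],
                   sum(led$individual == id & led$chromosome == cn),
                   info = paste(id, cn))
    }
  }
})

test_that("coverage statistics tally base depth and placement rate", {
  set.seed(71)
  ref <- c(C = random_seq(2000))
  idx <- build_index(ref, k = 17)
  # tile the chromosome densely: every base covered by >= 5 reads
  starts <- rep(seq(1, 1901, by = 10), each = 2)
  reads <- substring(ref[["C"]], starts, pmin(starts + 119, 2000))
  pl <- place_reads(reads, idx)
  cs <- coverage_stats(pl, idx, min_depth = 5)
  expect_equal(cs$frac_placed, 1)
  expect_gte(cs$frac_covered, 0.99)
  none <- coverage_stats(pl[0, ], idx, min_depth = 5)
  expect_equal(none$frac_covered, 0)
  expect_true(is.nan(none$frac_placed))
})
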