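---
title: "Recovering a poorly differentiated W chromosome by sex-specific k-mer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a poorly differentiated W chromosome by sex-specific k-mer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a ZZ/ZW sex-determination system the female is the heterogametic sex:
she carries one Z and one W, the male two Z copies. When the W is young
("nascent"), its sequence is still nearly identical to the Z -- identities
above 95% are typical -- so standard assemblers collapse Z and W reads into
a single chromosome and the W is simply missing from the assembly. The way
out is population-scale k-mer arithmetic: any k-mer that occurs in **every**
female but in **no** male must come from W-linked sequence, and long reads
carrying such k-mers can be pulled out and assembled separately.

`zwks` implements this screen and the diagnostics around it, together with
a fully seeded synthetic ZW data generator so that every stage can be
validated against known truth without any external data or tools.

## The sex-specific k-mer screen

All k-mer work is strand-canonical: a k-mer is stored as the lexicographic
minimum of itself and its reverse complement, so counting is independent of
read orientation. The derivation, for female sets $F_1 \dots F_n$ and male
sets $M_1 \dots M_m$ counted per individual at $k = 17$:

1. count canonical k-mers per individual (`count_kmers()`);
2. filter each female set to counts $\ge$ `min_count_female` (default 5),
   which removes k-mers created by sequencing error;
3. intersect the filtered female sets (`kmer_intersect_all()`);
4. union the male sets (`kmer_union_sum()`), filtered at
   `min_count_male` (default 1: any male occurrence disqualifies);
5. subtract the male union (`kmer_difference()`).

```{r}
library(zwks)
spec <- derive_sex_specific_kmers(female_sets, male_sets, screen_params())
```

The frequency threshold deserves a note: descriptions of this procedure
variously phrase the filter as "remove below 5" (keep $\ge 5$) or as a
strict "greater than 5" (keep $> 5$). We implement *keep count $\ge t$*
with $t = 5$ as the default and expose `min_count_female` so either
convention is a one-line change. With a diploid short-read depth of 20x the
single W haplotype is covered at ~10x, so true W k-mers have expected
counts well above 5 while error k-mers (mostly singletons) fall below it.

Long (or paired) reads are then screened by membership
(`screen_reads()`): a read's hit count is the number of its k-mer
*positions* whose canonical k-mer is in the specific set. Positional
counting (rather than distinct-k-mer counting, available via
`distinct = TRUE`) is deliberate: a repeat-expanded W yields reads in which
the same specific k-mer recurs many times, and those recurrences are
evidence, not noise.

### Choosing `min_hits_per_read`

The default threshold of 1 mirrors the idea of keeping any read
"containing" a specific k-mer, and is exactly right when the W shares no
k-mer with the rest of the genome and reads are clean. On a *nascent* W it
is too permissive for noisy long reads, for a mechanism worth
understanding: at 4% Z--W divergence, half of all 17-mer windows on the W
contain a divergent site, and a sequencing error that happens to land on
such a site in a **Z** read converts it, with probability 1/3, into the W
allele -- creating up to $k$ spurious specific-k-mer hits. At a 0.2% error
rate a 15 kb Z read acquires on the order of ten such hits, while a true W
read of minimal length (1 kb) carries hundreds. The two populations are
separated by orders of magnitude, so the test suite fixes
`min_hits_per_read = 50` for the noisy nascent-W experiment, a value the
simulator's truth ledger shows sits far above the false-hit tail and far
below the weakest true W read. For real data the equivalent knob is the
hit-density flag; the separation argument is the same.

## Diagnostics

**Depth ratio (EZ).** Reads of each sex are placed on the male reference
by a unique-anchor mapper: every k-mer occurring exactly once in the
reference votes for an implied (chromosome, start, strand), and a read is
placed at the plurality vote if it has $\ge$ `min_anchors` (default 3)
supporting anchors and a majority of votes. Per-window mean depth is then
normalized per sex by the *median autosomal window depth* -- the ratio's
scaling is not otherwise identifiable, and the median is robust to the
sex-linked windows themselves -- giving
$\log_2(M/F)$ per window. On a fully differentiated Z males carry twice
the female Z dose, so the expectation is 1 on Z and 0 on autosomes; when W
is indistinguishable from Z, female W reads are placed onto Z and the
expectation is 0 everywhere. Windows where either sex has zero normalized
depth are reported as `NA`, never $\pm\infty$.

**Heterozygosity differential.** Before coverage diverges, a nascent W
betrays itself through apparent heterozygosity: female reads from the W
are placed onto the Z and their divergent alleles appear as balanced
heterozygous columns. The package counts het sites either from a VCF's GT
fields (`count_het_from_vcf()`) or with its own naive pileup
(`call_het_sites()`): a column is heterozygous when depth $\ge$ 5 and the
minor allele fraction is $\ge$ 0.3. These thresholds are diagnostic
defaults, not a calibrated variant caller, and the pileup is exact only
because the simulator plants substitutions, never indels. The female
vs. male Z het counts are compared by a one-sided Wilcoxon rank-sum test.

**Z-candidate identification.** The recovered W is matched to its Z by
alignment-free identity: bottom-$s$ MinHash sketches (fixed splitmix64
hash, masked to 53 bits so sketch hashes are exactly representable in R
doubles and identical across platforms) give a Jaccard estimate $j$, and

$$\mathrm{identity} = 1 + \frac{1}{k}\ln\frac{2j}{1+j},$$

floored at 0. With planted divergence $d$ the estimator returns
$1 + \ln(1-d) \approx 1 - d - d^2/2$; the small quadratic bias (0.003 at
$d = 0.08$) is inherent to the Mash relation and well inside the $\pm 0.01$
calibration band checked by the tests.

**Assembly QV.** With read k-mer set $R$ and assembly k-mer positions $T$
of which $b$ are absent from $R$,
$E = 1 - (1 - b/T)^{1/k}$, $\mathrm{QV} = -10\log_{10}E$ and accuracy
$= 100(1-E)$ percent -- the standard k-mer consensus-quality estimator,
counting positions with multiplicity (distinct mode by flag). `qv_estimate()`
reports QV as `Inf` when $b = 0$. The pipeline feeds it the female
short-read k-mers filtered at count $\ge 2$, since unfiltered error
k-mers would only ever *reduce* $b$ and make QV optimistic, not
pessimistic. The companion `hom_snp_accuracy()` converts a homozygous-SNP
count $n$ over an assembly of length $L$ into $100(1 - n/L)$ percent.

## The synthetic data generator

The generator's defaults are the study conditions the rest of the package
is validated under:

| parameter | default | meaning |
|---|---|---|
| `zw_divergence` | 0.04 | Z-to-W substitutions/site (~96% identity, nascent W) |
| `w_repeat_fraction` | 0.1 | W length added as copies of one random repeat unit |
| `repeat_unit_length` | 5000 bp | the repeat unit (a stand-in for an LTR-retrotransposon expansion) |
| `n_females`, `n_males` | 5 / 5 | resequencing panel per sex |
| `pop_het_rate` | $10^{-3}$ | planted het substitutions/site per individual |
| `short_read_length` / `short_coverage` | 150 bp / 20x | paired short reads, fragment = 2 read lengths |
| `long_read_mean` / `long_coverage` | 15 kb / 15x | lognormal HiFi-like reads, truncated to [1 kb, 50 kb] (mimicking a ~20 kb size-selected library) |
| `short_error` / `long_error` | $10^{-3}$ / $2\times10^{-3}$ | substitution-only error |

Design points, and what they imply about test coverage:

* **Substitutions only.** Read errors, population variation and Z--W
  divergence are all point substitutions. This keeps the unique-anchor
  mapper and the pileup exact (no gapped alignment anywhere) but means the
  tests say nothing about indel error modes or structural variation.
* **One repeat unit.** The W expansion is tandem/dispersed copies of a
  single random unit placed uniformly at random; real repeat landscapes
  (nested, diverged families) are not emulated. Repeat placement is on W
  only, matching the expansion being W-specific.
* **`w_mode = "random"`** produces the *fully differentiated* control: an
  independent random W, post-processed so it shares not a single canonical
  17-mer with the reference (collisions are repaired by mid-window point
  substitutions; a random 300 kb W shares a few dozen 17-mers with a
  ~1 Mb reference by chance alone, so this must be enforced, not assumed).
* **Hemizygous copies** (female Z and W) receive *homozygous*
  substitutions at half `pop_het_rate`, the same per-copy mutation density
  as the paired chromosomes; they are ledgered separately since they are
  not heterozygous sites.
* **Determinism.** All randomness flows from one integer seed through
  fixed per-stage offsets; identical configurations give byte-identical
  FASTA/FASTQ/TSV outputs, which the tests check literally.
* **Truth ledger.** Every read carries its origin (individual, chromosome,
  haplotype, 0-based half-open interval, strand), and every planted site
  (Z--W divergence, population hets, hemizygous substitutions) is recorded,
  so precision/recall and het-count checks are exact bookkeeping, not
  estimates.

## Pipeline, configuration and problem sizes

`run_pipeline()` chains all stages and writes each stage's artifact as a
plain file (k-mer sets as sorted TSV with a `#zwks-kmerset k=` header,
tracks and tables as TSV, reports as JSON+TSV); re-running with
`resume = TRUE` reloads whatever artifacts exist and recomputes the rest,
and a deleted artifact is reproduced byte-identically thanks to seeded
determinism. Configuration files are YAML with a `simulate:` block
mirroring `sim_config()` (YAML rather than TOML simply because R has a
mature YAML parser); command-line use goes through the thin
`inst/scripts/zwks` wrapper, whose subcommands map one-to-one onto
exported functions.

The shipped validation experiments use a ~0.9 Mb genome (two 300 kb
autosomes + 300 kb Z) at 20x with 5 females and 5 males for the
depth-ratio checks, and 3 x 100 kb chromosomes for the screening and
heterozygosity experiments -- sizes chosen so the whole suite runs in
minutes on one core while keeping per-window read counts high enough that
the expected values are sharp (a 1 kb window at 20x pooled over 5
individuals averages several hundred reads). The acceptance bands
(e.g. mean Z $\log_2(M/F) = 1 \pm 0.1$) follow from that sampling noise.

## Known limitations

* The mapper requires unique 17-mer anchors; reads wholly inside repeats
  are dropped rather than rescued, so depth in repeat-rich windows is
  underestimated (they appear as low-depth or `NA` windows).
* The het caller is not a production variant caller: no base qualities, no
  indel realignment, hard thresholds.
* Sketch identity substitutes for alignment-based identity; it reports a
  whole-sequence average and cannot localize divergent segments.
* No assembly: the deliverable of the screen is the validated read
  partition (plus all diagnostics), not contigs.
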