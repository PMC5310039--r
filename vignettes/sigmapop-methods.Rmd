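---
title: "Models and methods behind sigmapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sigmapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmapop)
```

`sigmapop` analyses the population genetics and transmission biology of
vertically transmitted insect viruses from three kinds of input: pre-aligned
partial-gene nucleotide sequences (FASTA), sample metadata (TSV), and
laboratory cross / field prevalence records (TSV). This vignette documents
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The data model

All sequence analyses run on a `sigma_alignment`: equal-length sequences
over `A, C, G, T, -, N` with unique ids and a declared strand *sense*
(`genome`, `antigenome`, or `mrna`, the default for Sanger products whose
strand of origin is not recorded). Gaps and `N` are distinct symbols and are
preserved by I/O; every statistic first applies *complete deletion*,
removing any column containing either symbol, so that all quantities share
one denominator `L_used`. Pairwise deletion would give `π` and `S`
inconsistent denominators; a single fixed site count matches how "sites
examined" is conventionally reported for Sanger datasets. Columns are
1-based inside R, as R users expect; exported site lists (the masked-sites
TSV) are 0-based half-open, BED-style, for interoperability.

## ADAR hyper-mutation masking

ADAR enzymes deaminate adenosines in double-stranded RNA; an edited A is read
as G. Editing acts on both the negative-sense genome and its positive-sense
replication intermediate, and prefers adenosines whose 5′ neighbour is A or
U over C and G. Because one editing event produces a clustered tract of
changes, edited sites are not independent draws from the mutation process
and would bias diversity statistics downward-frequency-wise (they mimic an
excess of rare variants).

The procedure is:

1. Build a 50% majority-rule consensus: a column's consensus base must be
   strictly more than half of its non-gap, non-`N` characters; ties give `N`
   (a deliberate conservative choice — an IUPAC tie-break would move sites
   in and out of the Fisher table arbitrarily), and `N` columns are
   ineligible on both senses.
2. Classify every column on both senses against the consensus: a consensus
   `A` is an A-site on the stored sense with 5′ neighbour `consensus[i-1]`;
   a consensus `T` is an A-site on the opposite sense with 5′ neighbour
   `complement(consensus[i+1])`. A site is *preferred* when that neighbour
   is A or T. A column is eligible on exactly one sense; terminal columns
   lacking the required neighbour are never preferred.
3. Call candidates: any sequence with `G` at a stored-sense A-site or `C`
   at an opposite-sense A-site.
4. Test over-representation on the *site* level (a site is "mutated" if at
   least one sequence carries a candidate) with a one-sided hypergeometric
   tail — the exact Fisher probability of at least as many mutated preferred
   sites given the margins. Site-level counting avoids pseudo-replication
   from clustered edits within one sequence; the one-sided alternative is
   directional by mechanism.
5. Mask *all* preferred columns, edited or not, because any preferred site
   is a candidate target of past or future editing. Masking is idempotent:
   a preferred column's base is A or T, so removing preferred columns never
   turns a surviving column's C/G neighbour into an A/T one, and a re-scan
   of the masked alignment masks nothing further.

The classification uses the consensus context rather than per-sequence
context, matching the consensus-comparison design of the procedure, and the
eligibility denominator is all A-sites on both senses. These two choices
mean exact p-values from other implementations may differ slightly; the
calibration properties (false-positive rate at most the nominal α on clean
alignments, power above 90% at 15+ injected edits) are what the test suite
asserts.

## Diversity and neutrality

With `n` sequences and `L_used` sites: `S` counts columns with at least two
distinct bases (multi-allelic columns count once); a *singleton site* is a
segregating column in which every non-major allele occurs in exactly one
sequence; `k̄` is the mean pairwise Hamming difference count, `π = k̄ /
L_used`, and `θ_W = S / (a₁ L_used)` with `a₁ = Σ 1/i`. Tajima's D is

```
D = (k̄ − S/a₁) / sqrt(e₁ S + e₂ S (S − 1))
```

with Tajima's (1989) constants; it is reported as `NA` (not 0) when
undefined (`n < 4` or `S = 0`).

Two null models give p-values:

- **Coalescent simulation** (the null used for all-sites tests): neutral
  constant-size genealogies without recombination, with exactly `S`
  mutations placed on branches proportional to length (fixed-`S`
  conditioning on the observed information, as DnaSP does, rather than
  fixed-θ), infinite-sites accounting. Two-tailed p is
  `2·min(P(D* ≤ D), P(D* ≥ D))` with the `(b+1)/(m+1)` estimator, so p is
  never exactly zero and the test is slightly conservative.
- **Beta approximation** (the null used for synonymous-site tests): D is
  assumed to follow a beta distribution rescaled to its attainable range
  `[D_min, D_max]` (functions of `n` alone) with mean 0 and variance 1.
  Observed D outside the attainable range is clamped with a warning.

Synonymous-site analysis classifies a segregating site as synonymous iff
every observed base, substituted into the consensus codon, encodes the same
amino acid (changes to stops count as non-synonymous); the site denominator
is the Nei–Gojobori count (per codon position, the fraction of the three
possible changes that are synonymous), averaged over sequences. Codons
containing `N`/gap anywhere are dropped whole, as is a trailing partial
codon. Other software's synonymous-D conventions (site counting, rounding)
are not printed anywhere authoritative, so equivalence with any particular
program is documented as a choice, not asserted.

## Population differentiation

`K_ST = 1 − K_S/K_T`, where `K_j` is the mean pairwise difference count
within population `j`, `K_S = Σ (n_j/n) K_j`, and `K_T` is the mean over all
pooled pairs. For more than two populations the `n_j/n` weights are the
natural generalisation of the two-population definition; other weightings
(`n_j − 1`) exist, and no equivalence with any specific implementation is
claimed. Populations with fewer than two sequences are excluded with a
warning; `K_T = 0` (all sequences identical) makes the statistic undefined
and is reported as `NA` rather than 0. The permutation test shuffles
population labels with group sizes fixed, one-tailed (large `K_ST` =
structure), `p = (#{K_ST* ≥ K_ST} + 1)/(m + 1)`.

## Demographic inference

The demographic model is the exponential-growth coalescent: looking
backwards, `N(t) = N₀ e^{−rt}` with `r` in units of per year, so the
pairwise coalescence rate at scaled time `t` is `C(k,2) e^{r_c t}` where
`r_c` is the rate per coalescent unit. Calendar-year scaling uses
`years per coalescent unit = θ / (2 · clock · L)`: `θ/2` is the mutation
rate per sequence per coalescent unit, so dividing by the per-sequence
yearly rate `clock · L` converts units. Time is in calendar years
end-to-end; no generation-time parameter appears.

Inference is rejection ABC, a deliberate desk-scale replacement for full
Bayesian phylogenetic MCMC — the model (exponential-growth coalescent,
informative clock prior, `ln(2)/r` doubling times, strict exclusion rule) is
retained while the inference engine is simulation-based:

- Priors: `r ~ U(−2, 2)` per year (negative growth must be admitted or the
  constant-size exclusion rule is vacuous; 2/yr corresponds to a doubling
  time of four months, faster than any plausible arthropod-virus sweep);
  `θ` log-uniform on `[0.1, 100]` per sequence (a scale parameter spanning
  essentially monomorphic to saturated alignments); clock rate Normal(9.9e-5,
  3.6e-5) substitutions/site/year truncated at zero — the DMelSV rate used
  as a fully informative prior.
- Summaries: `S`, `k̄`, singleton sites, Tajima's D, variance of pairwise
  differences, number of distinct haplotypes, and the largest haplotype
  count. The haplotype pair is what distinguishes a star-like sweep
  genealogy most directly. Count-like summaries are compared on the
  `log(1+x)` scale (they are heavy-tailed across the prior), and all are
  standardized by prior-predictive median absolute deviations — a plain SD
  would let a handful of extreme prior draws effectively delete summaries
  from the distance.
- Acceptance: the nearest 2% of 20,000 draws by default (the regression
  correction needs a few hundred points to estimate its coefficients
  stably). Accepted draws are
  corrected by weighted local-linear regression on the summary
  discrepancies (Epanechnikov weights; positive parameters adjusted on the
  log scale and clamped to their prior support), and posterior summaries are
  weighted quantiles. Plain rejection (`adjust = "none"`) is kept for
  prior-predictive checks, where 100% acceptance must return the prior.
- Intervals: central 95% by default; HPD available. Central intervals are
  more stable at the few hundred draws rejection ABC retains; the HPD
  option matches the convention of MCMC-based reports.
- `exclude_constant()` is `TRUE` only when the 95% interval of `r` strictly
  excludes zero — an interval touching zero keeps the constant model.
- Doubling times `ln(2)/r` are computed only from accepted draws with
  `r > 0`; TMRCA draws are each genealogy's root time converted to years by
  that draw's own scaling.

Numerical details: the exponential time change has a closed-form inverse,
which the simulator uses directly (no discretization). For `r < 0` a pure
exponential may never coalesce (the cumulative rate is finite), so the
ancestral population size is capped at 1000× the present size — beyond that
the population is held constant. The cap only matters for strongly negative
prior draws, which the data reject anyway. Prior draws whose Poisson
mutation count exceeds `10 L` are abandoned without resolving sequences:
they would saturate every column and cannot be near any observed alignment;
they are treated as infinitely distant.

## The synthetic-data generator

`simulate_coalescent()` implements the standard n-coalescent with three
demographies (constant; exponential growth via the exact time change;
two constant-size demes without migration merging at a given split time) and
finite-sites Jukes–Cantor mutation at total rate `θ/2` per unit branch
length, uniform over columns. Finite sites (rather than infinite sites) is
deliberate: back-mutation and multi-allelic columns exercise the statistics'
edge cases. The root sequence is uniform random per column.

`inject_adar_tracts()` emulates hyper-mutation: each event picks one
sequence and one sense, then edits a geometric-length run (default mean 6)
of consecutive ADAR-preferred sites, classified against the alignment's own
consensus, producing a truth table consumed by the detection tests. Only
preferred-context sites are ever edited.

`simulate_crosses()` draws offspring infection independently Bernoulli at
the class rate — maternal-class crosses at the maternal rate, paternal at
the paternal rate, double-uninfected controls at zero — and offspring sex
Bernoulli at the sex ratio. `simulate_prevalence()` is binomial sampling per
population.

What the generator does *not* emulate: rate variation among sites or
lineages (no HKY/codon partitions — Jukes–Cantor only), recombination
(absent or rare in negative-sense RNA viruses), serially sampled tips,
selection, within-host dynamics, or non-independent offspring within a
cross (shared-germline effects). Passing tests therefore demonstrate
correctness of the statistics and calibration under these idealised
conditions, not robustness to model violations in field data.

## Study conditions used by the tests

The test and acceptance suites run at desk scale, chosen to mirror the kind
of dataset this analysis targets (tens to low hundreds of partial-gene
Sanger sequences): sweep-signature and ABC-recovery studies use `n = 50`
sequences × `L = 1000` sites at `θ = 40` with a doubling time of 1.5 years —
which yields a few dozen segregating sites, most of them singletons, like a
recently swept virus population; a DImmSV-sized run (`n = 87`, `L = 929`)
appears in the acceptance script. Null calibrations use 500 replicates
(binomial tolerance ±0.02 around α = 0.05); ABC recovery uses 20 replicates
of 20,000 simulations. TMRCA truths in these conditions fall around 5–15
years, matching the timescale on which biparentally transmitted viruses
sweep.

## Known limitations

- Exact reproduction of any published p-value from field data would require
  the original sequences; the package asserts formula-level identities and
  calibration/recovery on synthetic data instead.
- Rejection ABC posteriors are approximate: intervals are wider than
  likelihood-based ones, and at 20,000 simulations the doubling-time median
  is recoverable only to within about a factor of two.
- The Wilcoxon `W` convention is the rank sum of the first group; other
  software may report the Mann–Whitney `U = W − n₁(n₁+1)/2`.
- χ² heterogeneity uses the asymptotic Pearson test (no continuity
  correction) and warns when expected counts fall below 5.
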