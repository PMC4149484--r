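---
title: "Dating paternal lineages and detecting star-like expansions with ystar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating paternal lineages and detecting star-like expansions with ystar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystar)
```

## The model

The non-recombining region of the Y chromosome (NRY) passes from father to
son without reshuffling, so the ancestry of a panel of men is a single
rooted tree. Two assumptions make that tree datable from sequence alone:

* **Infinite sites.** Over the ~10 Mbp of unique NRY sequence, each new SNP
  arises at a position not mutated before, so every variant marks exactly
  one branch and there is no back-mutation. A data set obeying this
  assumption admits a *perfect phylogeny*: the carrier sets of the variants
  are nested or disjoint, and the tree they generate is unique.
* **Strict molecular clock.** Substitutions accrue at a constant rate
  $\mu$ per base per year on every lineage. Over $L$ analyzable base pairs
  a lineage accumulates counts as a Poisson process with rate $\mu L$ per
  year; with the defaults $\mu = 10^{-9}$ and $L = 3.9\times 10^{6}$ that
  is one substitution per `r round(clock_model()$years_per_substitution, 1)`
  years.

Under these assumptions the age of a node with mean node-to-tip
substitution count $\bar n$ is estimated by
$\hat t = \bar n / (\mu L)$, and the *counting* component of its
uncertainty is the Poisson interval of $\bar n$: the relative 95%
half-width is $z_{0.975}/\sqrt{\bar n}$, the inverse-square-root law that
makes a 210-substitution root pin its age to about ±13.5% while a
9-substitution estimate is barely informative (±65%).

A *star-like expansion* is a node from which many lineages radiate within
a window too short for shared mutations to accumulate — the genealogical
signature of explosive growth of one paternal line. Resolving "short"
depends on $L$: an internal branch with zero observed substitutions is
compatible, at the one-sided 95% Poisson bound (the rule of three), with at
most $3/(\mu L) \approx 769$ years, which is why more than 1 Mbp of
sequence is needed before a star can be confined to a millennium.

## The analysis chain

1. **Calling** ([call_genotypes()]). Each sample × site cell of read counts
   becomes one of four states: `-` (no coverage), `1` (alternative allele
   at ≥ 2 reads and ≥ 3/4 of the cell total), `0` (reference at ≥ 3/4),
   `?` otherwise. Both fraction thresholds are applied inclusively at exact
   ties; the reference-side rule mirrors the alternative-side rule, which
   the published criteria leave implicit. A variant private to one sample
   needs ≥ 4 supporting reads ([apply_private_filter()]), the guard against
   singleton artifacts.
2. **Site filtering** ([filter_sites()]). A site is analyzable when its
   unambiguous calls strictly exceed 100/110 of the cohort, scaled
   proportionally for other cohort sizes (the published behaviour is
   recovered exactly at n = 110). Monomorphic sites are dropped for tree
   building.
3. **Tree building** ([build_tree()]). Carrier patterns are checked for the
   rooted three-gamete condition ([check_compatibility()]); a compatible
   matrix yields its unique perfect phylogeny with every site on one branch
   and branch lengths equal to substitution counts. Conflicting patterns
   are resolved greedily — most supporting sites first, ties by carrier
   count then smallest site ID — and a rejected pattern's sites are placed
   recurrently on the minimal covering clades and flagged for curation.
   This automates what the original workflow resolved semi-manually; the
   conflict report, not further guessing, is the interface for manual
   calls. Multifurcations are represented natively, since star nodes are
   the object of study.
4. **Imputation** ([impute_missing()]). Missing and ambiguous cells are
   filled by the classic Fitch pass over the guide tree: the uppass
   intersects child state sets, the downpass hands each node its parent's
   assignment whenever its own set allows, so a missing cell inside a
   derived clade inherits the clade allele. The root is constrained to the
   ancestral (reference) state, the rooted convention of an
   outgroup-anchored panel. Residual ambiguity — possible only with an
   unconstrained root — falls back on a seeded uniform draw. In the
   pipeline the guide tree is first built from definite carriers only,
   then the completed matrix is re-built into the final genealogy.
5. **Dating** ([date_nodes()], [node_age()]). Node age is the mean
   node-to-tip count divided by $\mu L$. Three interval methods are
   offered: `normal` ($\pm z/\sqrt{\bar n}$, default), `exact` (Garwood
   chi-square), and `gamma` (central interval of a Gamma($\bar n+1$,
   $\mu L$) posterior under a flat age prior) — the last is the
   closed-form stand-in for MCMC machinery: with a fixed rate and a strict
   clock, node dating *is* Poisson rate estimation, so nothing beyond the
   conjugate posterior is required. Descendant lineages share branches, so
   the mean count is treated as a single Poisson observation rather than an
   iid sample; this follows the panel's own approximation and makes the
   intervals conservative (simulated coverage of the root interval is
   essentially 100%, not 95%).
6. **Clock checking** ([clock_dispersion_test()]). The index of dispersion
   of root-to-tip counts against $\chi^2_{k-1}$, an explicit stand-in for a
   likelihood-ratio clock test and labelled as such. Shared branches make
   tip counts positively correlated, so on real trees the test is
   conservative; its size is nominal on iid counts (simulated rejection
   ~5% at $\alpha = 0.05$) and its power against a two-fold rate split
   between panel halves exceeds 80% at $\bar n = 210$.
7. **Expansions** ([detect_stars()], [assign_names()]). Internal branches
   whose count is compatible with less than the window (default 1000
   years; 500 matches the observed expansions) at the upper 95% Poisson
   bound are contracted; any resulting node with ≥ 5 child lineages is a
   star. Names are the haplogroup letter plus a lowercase Greek letter,
   attached to the expansion node itself, in a stable documented order:
   decreasing clade size, then increasing age, then node number. The
   original names follow clade identity rather than any printable
   statistic, so an automated order must be a convention; size-then-age
   reproduces the published lettering for the three eponymous expansions
   (the youngest of three equal-sized stars is α). Population shares of
   disjoint expansion clades are summed by [descent_fraction()] from
   survey frequencies supplied as metadata — they are not estimable from
   the sequenced panel itself.
8. **Bait design** ([unique_regions()]). 70-bp tiles every 10 bp are
   searched genome-wide (both strands, ≤ 2 mismatches); tiles occurring
   anywhere beyond their own origin are discarded; surviving ranges are
   merged and merged ranges under 240 bp dropped. `N` matches nothing,
   including another `N`. Reverse-complement matching is on by default
   (a probe hybridizes either strand) with a flag to disable. Overlap and
   abutment both merge; at step 10 < window 70 the distinction only
   matters for pathological inputs. The matcher is an exact Hamming
   engine (Biostrings); the test suite holds it byte-for-byte equal to a
   naive sliding-window oracle on planted-duplication genomes.

## The simulator and what it does (not) emulate

Scenarios are *scripted* genealogies — explicit node ages, not coalescent
draws — because the tests need exact ground truth. Three generators cover
the study designs:

* [multi_star_scenario()] (default: stars of 10 lineages at 5,400 / 6,500 /
  6,800 years on a 54,100-year ladder, 49 tips) reproduces the
  three-expansion panel geometry;
* [binary_scenario(spacing = "uniform")] spreads splits evenly — the shape
  of a lineage-diversity panel whose divergences are old and well
  separated, used as the star-free null;
* [binary_scenario(spacing = "coalescent")] uses Kingman expected gaps —
  the neutral random-sample null, appropriate when terminal-branch
  geometry matters (e.g. imputation benchmarks).

Mutations are Poisson per branch with distinct uniform positions
(infinite sites enforced by construction); reads are per-cell
Poisson(depth) with a symmetric per-read miscall probability. The
published coverage regime states only a mean, hence the Poisson depth
choice. One master seed drives every stage through deterministically
derived child seeds, so a run is a pure function of its configuration.

Not emulated: read-level artefacts (mapping, duplicates, indel
realignment are upstream of this package's inputs), barcode confusion
(the curation states `x`/`@` are accepted on input, folded to 0/1, and
never generated — the original calls were made manually against the
tree), recombination, selection, and population-size inference.
Consequently, passing tests demonstrate correctness of the calling /
tree / clock machinery under its own stated model, not robustness to
alignment artefacts or rate heterogeneity across the chromosome.

## Numerical and design choices

* Fraction thresholds are inclusive (≥ 3/4); the alternative reading
  ("more than") differs only at exact ties.
* Sites carry 0-based positions internally; human-readable output is
  1-based inclusive (BED output stays 0-based half-open, with a 1-based
  companion TSV).
* The collapse criterion is monotone in the branch count, so contraction
  is order-independent and idempotent; contracted counts migrate onto
  child branches, preserving every root-to-tip path sum exactly. With the
  default window only zero-count branches qualify.
* Pattern acceptance order (support, then carrier count, then smallest
  site ID) makes tree building deterministic and input-order independent.
* `z = qnorm(0.975)` (≈1.96) for 95% intervals; the printed ±13.6% for
  $n = 210$ lies between the normal (13.53%) and exact (13.77%) methods,
  both of which are exposed.
* The interspecies recalibration ([rate_from_outgroup()]) implies
  $45{,}800/(2 \times 6\,\mathrm{Myr}) = 3.82\times10^{-3}$ substitutions
  per lineage-year over the compared region and re-dates a 210-count root
  to ≈41.3 kyr after scaling by the 3/4 of sites with homologous
  outgroup loci; the published rounding ("40 kyr") is not exactly
  derivable from the printed inputs, so the computed value is reported.

## Known limitations

* **Terminal-branch false negatives.** At 6× mean coverage the private
  ≥ 4× rule demotes the real singletons that happen to sit in cells of
  depth < 4 (about 15% of them), and imputation then restores the
  ancestral allele, so terminal branches — and with them absolute ages
  estimated through the full read-level pipeline — are biased short by
  roughly 13%. This is the documented false-negative caveat of the
  original filtering, visible here because the simulator provides truth.
  Age *recovery* benchmarks therefore use well-covered error-free panels,
  where the estimator is unbiased; detection and specificity benchmarks
  use the noisy study conditions.
* **Rank resolution of close expansions.** With $k = 10$ lineages on
  3.9 Mbp, an expansion age has a standard error of ≈400 years, so two
  expansions 300 years apart are rank-ordered correctly only ~70% of the
  time — a fundamental Poisson limit at this $L$, not an implementation
  artefact. Confidently ordering the two older expansions would need
  several times more sequence or lineages.
* **Parsimony cannot recover masked private alleles**: a missing cell
  that was the sole carrier of its site is always imputed ancestral.
  Masking 5% of a clean coalescent-panel matrix recovers ≥99% of states
  (terminal branches hold ~22% of that tree's length); on
  long-terminal-branch panels the recovery is correspondingly lower.
* The dispersion clock test is conservative on trees (shared branches)
  and is a stand-in, not a likelihood-ratio test under a substitution
  model.
* The bait designer is exact but desk-scale: cost is
  O(tiles × genome) per strand; genome-scale designs would need an
  indexed matcher behind the same interface.

## Problem sizes

The shipped checks run 49-tip panels at full $L = 3.9$ Mbp (a few
thousand segregating sites per replicate): 200 replicates for interval
coverage, 1000 draws for the dispersion-test size, 100 noisy replicates
each for star detection and for specificity, 25 clean replicates for age
recovery, and 100 planted-duplication genomes of ~1.4 kb for the bait
oracle equivalence — sizes chosen so each Monte-Carlo proportion has a
standard error of a few percent while the whole suite stays interactive.
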