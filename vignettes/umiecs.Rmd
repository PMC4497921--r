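---
title: "Error-corrected sequencing with molecular indexes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-corrected sequencing with molecular indexes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umiecs)
```

## The problem

Conventional amplicon deep sequencing cannot reliably call variants below a
VAF of roughly 1–2%: at any depth, the per-read substitution error rate
(~0.1–1%) produces wild-type positions whose apparent VAF overlaps the
signal. Applications such as pre-leukemic clone tracking and minimal
residual disease need quantification down to ~1:10,000 molecules.

Error-corrected sequencing solves this by tagging every input molecule
before amplification with a random oligonucleotide index (16 bp per adapter
end here). All reads descending from one molecule carry the same index
pair; comparing them removes errors introduced during PCR cycling and
sequencing, because a true allele is present in (nearly) every read of the
family while an error is present in few.

## Pipeline model

`run_pipeline()` executes five stages, each also available as a tibble-in /
tibble-out function:

1. **Index extraction** (`extract_index`): the first `index_length` bases
   of each mate are removed and recorded; pairs with less than `min_insert`
   template left are rejected (`too_short`).
2. **Amplicon assignment** (`assign_amplicon`): the mate-1 template start
   is matched against each amplicon's two entry k-mers (first `anchor_k`
   bases, and the reverse complement of the last `anchor_k`) within
   `anchor_max_edits` edits. This also fixes the pair's orientation, and the
   family key is the orientation-normalised concatenation of the two
   indexes, so a molecule read in either direction yields one key. Primer
   bases are retained — they align to the reference and are shared by all
   members of a family, so they are harmless to the consensus.
3. **Family grouping** (`group_families`, `filter_families`): the key is
   `(amplicon, index pair)`, matched exactly; an optional directional
   collapse (`collapse_indexes`, off by default) merges an index into a
   ≥10× larger single-mismatch neighbour. Families below `min_family_size`
   read pairs are dropped.
4. **Consensus** (`call_consensus`): a per-position vote (details below)
   yields one ECCS per family; ECCS with more than `max_n_fraction`
   no-calls are dropped.
5. **Calling and profiling** (`align_eccs`, `count_alleles`,
   `wildtype_site_vafs`, `class_profile`, `call_variants`): each ECCS is
   aligned to its amplicon, families are counted per target, and the
   wild-type residual error distribution yields specificity thresholds.

### Consensus rule

At each template position with `d` covering reads of which `m` carry the
modal base, the consensus base is the modal base iff it is unique,
`d >= min_depth`, and `m / d >= min_agreement`; otherwise the position is
`N`. Disagreements are thus *removed* (masked) rather than the family being
discarded, preserving coverage at the family's other positions; families
dominated by `N` are removed by the quality filter instead.

Defaults: `min_agreement = 0.9`, `min_depth = 3`, `min_family_size = 3`.
Three read pairs is the smallest family in which a majority can outvote a
single errored read; with agreement 0.9, one error among up to ten reads
can never flip a base to another base (it can only mask the position). An
exact unanimity rule is available as `min_agreement = 1`; setting
`min_family_size = 1, min_depth = 1, min_agreement = 0` reduces the
pipeline to conventional per-read deep sequencing, which is how the
uncorrected comparator (`raw_site_vafs`) is computed.

Both mates vote independently; where they overlap, one fragment contributes
two observations. This double-counting is deliberate and documented — the
two mate reads are independent sequencing observations of the same
molecule, though not independent PCR observations.

The expected residual error of a consensus follows a binomial form: a
wrong base is emitted only when at least `ceiling(min_agreement * f)` of
`f` reads carry the *same* wrong base, which for per-read error `e` has
probability about `3 * P(Binom(f, e/3) >= ceiling(a f))`. The test suite
checks the empirical rate against this closed form within a factor of 3,
in parameter regimes chosen so the expected event count is large enough to
have power (the rule needs `ceiling(a f) > f/2`, otherwise modal-base
competition, which the simple form ignores, dominates).

### Members that disagree in length

Members are end-anchored by construction: every read either starts at the
molecule's first template base or ends at its last. Within a family each
block's members are compared against the block's modal read from the
anchored end, and a member more than `max_member_edits` mismatches away is
excluded from the vote as an outlier (chimeras, index collisions). The two
blocks' relative offset is reconciled by a bounded shift scan
(`max_shift`, default 10) that maximises agreement between the modal left
and modal right member over their overlap — this is what keeps families of
indel-carrying molecules internally consistent even though their template
length differs from the reference amplicon. A full gapped alignment of
every member was considered and rejected: end-anchored amplicon reads
cannot start mid-template, so the only free parameter is the one offset.

### Alignment and counting

ECCS are aligned to their amplicon by a fitting (glocal) dynamic program
under unit edit costs with free reference overhangs; identical consensus
strings are aligned once. Equal-length consensi within 3 substitutions of
the reference window bypass the dynamic program — at that distance a gapped
alignment cannot score better in practice, and such sequences dominate deep
libraries. Gaps are left-normalised (a deletion block shifts left while the
base before it equals its last base; insertions rotate likewise), so an
indel in a homopolymer has exactly one canonical position — the same
normalisation applied to targets read from a targets file. Alignment
identity is matches over aligned non-`N` columns; below `min_identity`
(default 0.8) an ECCS is discarded as unalignable. `N` columns are excluded
because a no-call is an absence of evidence, not an error.

At a target, a family counts as *variant* only for the exact anchored
replacement (a 2-base deletion target is not matched by an overlapping
1-base deletion), as *reference* for the exact reference allele, and as
*other* for anything else including `N` at the locus. The VAF denominator
is variant + reference families only; `other` families are reported but
never enter the denominator. Zero-coverage loci report VAF `NA`, never 0,
distinguishing "no data" from "no variant families". Reported VAFs are
rounded half-up to four decimals with trailing zeros trimmed, which
reproduces all 25 rows of the bundled patient table including its
boundary rows (7/199945 prints `0`; 10/135861 prints `0.0001`).

### Residual error profile

For every amplicon position not covered by a target allele and every
alternate base, the per-site VAF is alt families over covering families.
The specificity threshold at level `s` is the smallest observed VAF `t`
such that at least a fraction `s` of records lie strictly below `t`;
calling above `t` is then false-positive at rate ≤ `1 - s` on this
distribution by construction. Records are partitioned into three groups —
G>T(C>A), the 8-oxo-guanine signature; C>T(G>A), deamination-type; and the
other eight substitutions — because molecule-level damage is heavily
class-biased while polymerase errors are not. The numeric thresholds
published for the original instrument data (0.0016 global, 0.0034 /
0.00020 / 0.000079 by class) are properties of that data and are not
reproduced here; the package reproduces the estimator and the qualitative
ordering on simulated data.

## The simulator

`sim_config()` / `simulate_library()` generate complete indexed libraries
molecule by molecule. Defaults describe a realistic targeted ECS library
and are the conditions under which the package's claims are validated:

| parameter | default | meaning |
|---|---|---|
| `n_molecules` | 2.5e6 | tagged molecules loaded (qPCR-controlled) |
| `family_size` | Poisson(8), truncated ≥1 | read pairs per molecule |
| `per_read_error` | 0.003 | per-base substitution rate per read |
| `oxo_g_rate` | 1e-5 | pre-amplification oxidative G>T (C>A) conversion per G/C site |
| `ct_error_rate` | 2e-6 | pre-amplification deamination-style C>T (G>A) conversion |
| `pcr_error` | 1e-6 | early-cycle PCR substitution per base, inherited by the family |
| `read_length` / `index_length` | 150 / 16 | paired-end reads, index per mate |

Molecule-level events (oxidative damage, deamination, PCR errors) are
applied to the template *before* family expansion, so every read of the
family inherits them — this is exactly the mechanism by which ECS retains a
residual, class-biased error floor, and the reason the three damage knobs
exist separately from `per_read_error`. Damage is modelled as
strand-consistent (the whole family shows the converted base), the worst
case for consensus correction. Each read pair is emitted in random
orientation with a fresh per-read error draw; indexes are uniform random
16-mers per mate, so index collisions follow the birthday bound on 32
random bases and are negligible.

What the simulator does **not** emulate: quality-score variation (flat
Phred), coverage non-uniformity and fragmentation, adapter read-through,
FFPE-specific end-damage, index-hopping between samples, and
polymerase-slippage indel errors. Passing tests therefore demonstrate the
correctness of the estimators under the stated error model, not robustness
to every artefact of real instruments; the indel-free error model in
particular means alignment left-normalisation is exercised by constructed
fixtures rather than by simulation.

## Validation design and problem sizes

The test suite validates, among others:

* all 25 bundled patient-table VAFs from their read-family counts,
  including both rounding-boundary rows;
* dilution-series linearity: tumor VAF 0.5 diluted over `10^-1 .. 10^-5`,
  two replicates per dilution, full pipeline per library, r² of estimated
  on expected VAF ≥ 0.995 at 2.5e5 molecules per library (the package's
  standing validation scale; the defaults describe the full 2.5e6-molecule
  experiment, which tightens the expected r² toward 0.999+ simply by
  shrinking binomial noise);
* the binomial consensus-error closed form within 3×, the corrected-CDF
  dominance over raw reads at every grid point, a ≥10× shrinkage of the
  99% wild-type quantile, and the class-threshold ordering
  G>T(C>A) > C>T(G>A) > other under active damage;
* exact identity between the pipeline estimate and the realized molecule
  fraction when every error knob is 0;
* parameter recovery: at true VAF 1e-3 with ~100 expected variant families
  per library, the variant-family count falls inside the exact binomial
  99% interval in ≥19 of 20 seeded replicates;
* oracle equivalence of family grouping (brute-force partition), the
  specificity quantile (sort-based oracle), and alignment of a deleted
  base (independent global aligner; canonical homopolymer position).

Numerical choices worth knowing: modal-base ties give `N`; the agreement
comparison uses a 1e-9 epsilon so 9/10 passes at 0.9 exactly; VAF rounding
uses half-up with a 1e-9 guard against binary representation of exact
boundary rationals; all string orderings use radix (locale-independent)
sort; every stochastic step draws from R's RNG under an explicit seed, so
identical configuration and seed give byte-identical FASTQ output, and the
non-simulation pipeline is fully deterministic.

## Known limitations

Single-strand families only: the two strands of one duplex are not paired
(no duplex consensus), so damage affecting one strand before ligation can
still found a variant-looking family — visible as the G>T(C>A) excess the
error profile quantifies. Qualities are ignored in the vote. Mate overlap
double-counts one fragment's evidence. Detection thresholds are
re-estimated per run from that run's wild-type sites, so they inherit that
run's depth resolution; with few families the quantile saturates and the
threshold falls back toward the maximum observed VAF with a warning.
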