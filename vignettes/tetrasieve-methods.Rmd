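---
title: "Methods: tetranucleotide-signature sieving of genome pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetranucleotide-signature sieving of genome pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-genome species demarcation in bacteria and archaea rests on
alignment-based statistics — average nucleotide identity (ANI) and the
percentage of shared genome (PSG) — that are far too expensive to compute
for every pair in a collection of tens of thousands of genomes.
Intraspecies strains, however, share at least ~70% of their genomes and
have very similar genome-wide tetranucleotide usage. `tetrasieve`
exploits this: it "sieves" (pre-selects) the small fraction of candidate
intraspecies pairs using cheap 136-dimensional tetranucleotide-signature
correlations, so that alignment is only run on the sieved pairs. The
package also implements the ANI/PSG calculations from NUCmer `.delta`
output for validating sieved pairs, and a seeded genome simulator for
calibration and benchmarking.

## The signature model

For each tetranucleotide $w = w_1w_2w_3w_4$ we compute, from
double-stranded counts $n(\cdot)$ (sequence plus reverse complement,
windows containing non-ACGT characters skipped):

$$E(w) = \frac{n(w_1w_2w_3)\, n(w_2w_3w_4)}{n(w_2w_3)}, \qquad
\mathrm{var}(w) = E(w)\Bigl(1 - \tfrac{n(w_1w_2w_3)}{n(w_2w_3)}\Bigr)
                       \Bigl(1 - \tfrac{n(w_2w_3w_4)}{n(w_2w_3)}\Bigr),$$

$$z(w) = \frac{n(w) - E(w)}{\sqrt{\mathrm{var}(w)}},$$

the classic maximal-order Markov z-statistic of the TETRA lineage.
Double-stranded counting makes $z(w) = z(\mathrm{revcomp}(w))$ exactly,
so only the 136 canonical tetranucleotides (the lexicographically smaller
member of each reverse-complement pair; 16 palindromes are
self-canonical) are kept, with no loss of information. Whenever
$n(w_2w_3) = 0$ or $\mathrm{var} \le 0$ we set $z = 0$: a neutral value
that cannot create spurious correlation.

Similarity between two z-vectors is their Pearson correlation
coefficient, historically called PCCD ("Pearson's correlation coefficient
distance") even though *higher* values mean *more similar*; we keep the
field's acronym but use the correlation itself, and the sieve keeps pairs
with PCCD at or above a cutoff (the same convention as the TETRA
$r \ge 0.99$ rule).

A subtlety worth knowing: under two-strand counting the $z \approx 0$
null holds only for strand-symmetric generating processes. A
strand-asymmetric Markov chain genuinely deviates from the two-strand
Markov closure and carries signature signal; the test suite therefore
checks the null with strand-symmetric (i.i.d., $p_A = p_T$, $p_C = p_G$)
models.

## Fragmenting stage

Genomes are pre-processed by discarding sequences < 1 kb; the average
retained-sequence size is recorded *before* concatenation because the
window rules depend on it. Draft genomes are concatenated in an informed
order: a 3rd-order Markov model with add-one pseudo-counts is trained on
the whole genome, each sequence is scored by its mean per-position
log-probability, and sequences are concatenated in descending score
order (ties keep input order). The direction is not dictated by the
method's published description; we chose descending (most genome-typical
first) so that coherent runs of sequence sit adjacently, and expose it as
an argument. Only ordering-stability properties are asserted in tests.

The concatenated genome of length $L$ is cut by a sliding window of
length $l$ with $0.5\,l$ overlap:

* $L < 40$ kb — no dividing (one representative fragment);
* $40 \le L \le 800$ kb — $l = L/4$, which yields exactly 8 windows
  (7 full, one final half-length);
* $L > 800$ kb — $l = L/4$ (still 8 windows) if the average
  retained-sequence size exceeds 200 kb, otherwise $l = 200$ kb.

Windows start at integer-rounded multiples of $0.5\,l$ while the start is
below $L$; the final window is truncated at $L$ and kept only if at least
$0.5\,l$ long (a half-bp tolerance absorbs integer rounding of fractional
$l/2$). Genomes shorter than 10 kb are excluded from sieving with an
explicit error.

Each fragment's 136 z-values are summarised into the z-values of the
representative fragment (ZRF) by, per tetranucleotide independently,
sorting the fragment values and averaging the central three (odd
fragment count $\ge 3$) or central four (even count $\ge 4$). One
fragment is returned verbatim; for two fragments we take their mean, the
only consistent degenerate reading of the central-four rule.

The genome-specific cutoff (GSC) comes from the intragenomic PCCDs of
every fragment against the ZRF:

$$\mathrm{GSC} = \mathrm{Mean} - \mathrm{SD} - 0.01,$$

with 0.01 guarding the decision boundary. SD is the sample ($n-1$)
standard deviation — the published description does not specify which;
sample SD matches statistics-package defaults and the embedded-R heritage
of the method. The older rule $\mathrm{Mean} - 2\,\mathrm{SD}$ is
available as `gsc_mode = "legacy"` for comparisons.

## Length-specific cutoffs and calibration

Short genomes have noisy signatures, so the GSC is floored by a
length-specific cutoff derived from empirical intraspecific PCCD
distributions per genome size: with $(\mathrm{Mean}_{kb},
\mathrm{SD}_{kb})$ the distribution at size $kb$ (capped at 200),

$$\mathrm{LSC1} = \mathrm{Mean}_{kb} - \mathrm{SD}_{kb} - 0.01, \qquad
\mathrm{LSC2} = \mathrm{Mean}_{kb} - 2\,\mathrm{SD}_{kb}.$$

If the raw GSC falls below LSC1 the stored GSC is raised to LSC1
(specificity guard). If the raw GSC is at or below LSC2 the genome's
composition is too heterogeneous for the standard windows and the ZRF —
only the ZRF — is recomputed from 10-kb windows. Two readings of the
published workflow differ on strictness (`<` in the text, `≤` in the
figure); we restrict when GSC < LSC1 and re-fragment when GSC ≤ LSC2,
and on whether GSC should be recomputed after re-fragmenting; we follow
the workflow figure literally (update the ZRF, keep the restricted GSC).
Both are measure-zero/boundary choices covered by explicit tests.

The original empirical tables are not printed in the method's
description, so the `calibrate()` module rebuilds one: for each size bin
(every 10 kb from 10 to 200, snapped by nearest bin) it samples pairs of
overlapping extracts of that size from the same genome — mutual overlap
uniform in 70–100%, matching the ≥ 70% PSG definition of intraspecies
pairs — and records the mean and sample SD of their PCCDs. The packaged
default table (`inst/extdata/lsc_synthetic_default.tsv`, provenance line
included) was produced this way from five seeded 1-Mb synthetic genomes
and is a *synthetic stand-in*: supply your own TSV calibrated on real
intraspecific pairs to mirror the original behaviour. Because
same-sequence extracts correlate near-perfectly, the synthetic LSCs are
high (LSC2 ≈ 0.998 at 200 kb); against such a table most genomes take
the LSC1-restriction and 10-kb re-fragmenting paths. That is an honest
property of this calibration proxy, not of real intraspecific
distributions, which include strain-to-strain divergence.

## Determining stage

For a query/reference pair the cutoff is
$\mathrm{GSC}_p = \min(\mathrm{GSC}_q, \mathrm{GSC}_r)$ and the pair is
sieved when the PCCD of the two ZRFs is $\ge \mathrm{GSC}_p$
(inclusive). Self-pairs (identical ids) are excluded. A query that
sieves nothing is rescued: its $N$ (default 100) highest-PCCD references
are returned, ordered by descending PCCD with ties broken by reference
id — the published description does not define tie handling, and a
deterministic rule is required for testing; we return exactly
$\min(N, |\mathrm{refs}|)$ records. The all-vs-all implementation
computes the full correlation matrix in one step; its results are
defined (and tested) to be identical to evaluating each pair
sequentially.

## ANI and PSG from `.delta` files

NUCmer `.delta` alignment blocks carry a seven-value header and signed
indel digits (negative = gap in the reference). Pooled over blocks, with
stretch length $= \mathrm{ref\_end} - \mathrm{ref\_start} + 1$:

$$\mathrm{ANI} = \frac{\sum(\mathrm{stretch} + \mathrm{negatives} -
\mathrm{errors})}{\sum(\mathrm{stretch} + \mathrm{negatives})},$$

$$\mathrm{PSG} = \frac{|\bigcup \text{query intervals}| +
|\bigcup \text{reference intervals}|}{L_1 + L_2},$$

where interval unions count repeated/overlapping alignments once per
genome. The identity formula is reference-based as published; whether
query-side gaps should enter the denominator symmetrically is left
unspecified there, and we implement the printed formula only.
Coordinates are 1-based inclusive in the file, converted to interval
arithmetic internally; reverse-strand alignments (q_start > q_end) are
normalized before the union. Running the aligner itself is out of scope:
the package parses and (for fixtures) writes delta files.

## The simulator and what a green test establishes

`simulate_genome()` lays out a genome in consecutive blocks (default
5 kb) cycling through `n_components` (default 3) distinct 3rd-order
Markov models whose transition rows are drawn from a symmetric Dirichlet
(`alpha = 1`). Above the block scale every region carries the same
component blend, so the genome has a strong genome-wide tetranucleotide
signature — as real bacterial genomes do (intragenomic fragment PCCDs
≈ 0.99) — while distinct parents get independent models and therefore
near-orthogonal signatures. Large blocks with small `alpha` instead
produce chimeric genomes that exercise the LSC2/10-kb path. These
defaults were fixed once, on the criterion that the generated genomes
reproduce field-typical intragenomic PCCD levels; they are not tuned to
any test outcome.

`extract_pair()` realizes an intraspecific pair as two substrings of one
parent with overlap $o = \mathrm{PSG}\,(len_1 + len_2)/200$ placed
uniformly at random. Feasibility requires
$c \le 1/(2 - \mathrm{PSG}/100)$ for equal completeness $c$ — exactly
the published completeness ranges (10–70% at PSG 70 … 10–100% at
PSG 100). The realized PSG follows from the coordinates and equals the
alignment-based PSG of the pair's perfect synthetic alignment exactly
(a cross-module identity the tests assert). Extracts carry no mutations,
matching the simulation design this emulates.

What the simulation does *not* emulate: real strain-to-strain sequence
divergence, sequencing errors and homopolymer indels, plasmids, mobile
elements, and real contig-length distributions. A green benchmark
therefore establishes that the sieve is completeness-independent and
separates same-parent from different-parent signatures under controlled
PSG — not that it reproduces corpus-scale sensitivity/specificity on
real genomes.

## Numerical and design choices

* Sequences are uppercased on load; k-mer windows containing ambiguity
  codes are skipped everywhere; no strand flipping during concatenation
  (z-values are strand-symmetric anyway).
* Fragment z-matrices are computed with one vectorized counting call per
  k-mer width; counts are converted to doubles before forming
  count products (they overflow 32-bit integers on large fragments).
  The result is bit-identical to per-fragment `zvalues()`, which the
  tests assert.
* Correlation of a zero-variance z-vector is undefined: `pccd()` errors,
  and pair evaluation reports such pairs unsieved with a diagnostic flag.
* All randomness flows through explicit seeds; seeded entry points
  save and restore the caller's RNG state. Identical inputs and seed
  give byte-identical outputs, which the CLI tests check by digest.
* Exact ZRF equality between a genome and its reverse complement holds
  when the window layout is mirror-symmetric (single-window genomes,
  L < 40 kb), because the truncated final window otherwise breaks layout
  symmetry; per-fragment z-values are strand-symmetric always.

## Known limitations

* The packaged calibration table is synthetic; realistic length-specific
  cutoffs require calibration on real intraspecific pairs.
* The Naive-Bayes concatenation order (descending posterior) is a
  documented choice; the method's original sort direction is unknown.
* PROMER (protein-space) delta files are rejected, and the parser
  targets the NUCmer 4 dialect.
* The sieve stores the full query x reference correlation matrix;
  collections beyond ~20,000 x 20,000 signatures need chunking.
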