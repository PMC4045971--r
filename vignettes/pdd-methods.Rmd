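---
title: "Modelling probe-directed degradation: thermodynamics, cleavage zones and depletion metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probe-directed degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddkit)
```

Probe-directed degradation (PDD) depletes unwanted sequences from RNA-seq
libraries after reverse transcription: unmodified sense-strand DNA probes
anneal to the single-stranded antisense cDNA — circularized and flanked by
adapters — and duplex-specific nuclease (DSN) cuts wherever a sufficiently
long perfect duplex forms. One cut anywhere prevents amplification. This
vignette explains the models behind `pddkit`, the parameters that matter,
and what the package's simulations can and cannot say about real
libraries.

## Duplex thermodynamics

Probe hybridization is scored with the unified nearest-neighbor DNA/DNA
parameter set (Allawi & SantaLucia lineage), shipped as a plain-text table
(`inst/extdata/nn_unified_dna.tsv`) with a `source_label`, so an
alternative table can be swapped in. Enthalpy and entropy are sums of the
stacking terms over consecutive dinucleotides plus an initiation term per
terminal base pair; the 16 stack keys collapse to 10 unique parameter
pairs under reverse-complement symmetry, and the package tests assert both
this symmetry and frozen hand-summed reference values.

The melting temperature of a perfect duplex of length $N$ is

$$T_m = \frac{1000\,\Delta H}{\Delta S' + R \ln(C_T/x)} - 273.15,\qquad
\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+],$$

with $R = 1.987$ cal/(mol·K). Defaults: $C_T = 0.81\ \mu$M — the per-probe
concentration when a 50-probe panel is hybridized approximately equimolar
with the library — and $x = 4$, since probe and cDNA are distinct strands.
The buffer's ionic strength during hybridization is not a published
constant of the protocol, so the monovalent concentration is an explicit
condition with a conventional default of 50 mM; relative probe rankings
are insensitive to it, absolute Tm values shift by a few degrees. Only
perfect-match duplexes are scored: matches are exact substrings by
construction, so mismatch and dangling-end corrections never apply.
RNA:DNA hybrid thermodynamics (more stable, relevant only as motivation
for using DSN at the cDNA stage) are out of scope.

For a valid duplex both $\Delta H$ and the denominator are negative; a
non-negative denominator can only arise from pathological conditions and
raises an error rather than returning `NaN`.

## Off-target scanning

A probe threatens any transcript that *contains* the probe subsequence in
sense orientation, because hybridization happens on the antisense cDNA.
`scan_probes()` therefore performs same-orientation exact substring
matching only (a `both_strands` flag exists for exploration). It reports
**every maximal shared substring of length ≥ 11 nt** (the "> 10 nt"
threshold; a 10-nt shared substring is deliberately not a hit), found by a
k-mer seed index with bidirectional extension; maximality means neither
end can be extended with matching bases. The Tm annotated on a hit is that
of the *matched segment*, not the whole probe — a 12-nt off-target match
of a 25-nt probe melts like a 12-mer. Ambiguous bases never match
anything.

The test suite checks the scanner against an independent quadratic
dynamic-programming oracle (common-suffix lengths over the full equality
matrix) on a thousand seeded random pairs, plus planted-match edge cases
at the threshold boundary.

`recommend_hybridization_temperature()` summarizes a panel: the usable
window runs from the hottest off-target Tm plus a margin (default 3 °C)
up to the coolest full-length intended-target Tm minus the margin, and
the recommendation is the midpoint. With no off-target hits anywhere the
window is open below and the upper bound minus the margin is recommended.

## The cleavage model

DSN needs at least ten perfectly matched base pairs. With footprints
defined as *full-length* exact probe matches on their intended targets
(a partial match to the intended target is a design error, not a
footprint), an insert $[s, s+L)$ is cleavable iff it overlaps some
footprint by at least `min_duplex` (default 10) nt. The circular geometry
is abstracted away: one cut suffices, adapters have no complementary
strand, so cleavage reduces to interval overlap on the target. The
per-molecule cut probability `p_cut` (default 1) is the handle for
sub-complete enzymatic efficiency.

`survival_profile()` gives, per 5' position, the expected fraction of
inserts escaping treatment, with insert lengths uniform over the
size-selection range unless a `(length, weight)` table is supplied.
Consequences the tests verify against exhaustive insert enumeration:

* the depletion zone's right edge sits `min_duplex − 1 = 9` nt upstream of
  the probe 3' end, and the zone widens with insert length;
* growing an insert can only keep or gain cleavability (containment
  monotonicity).

**Spacing.** The longest insert that can escape between two footprints
separated by `gap` is `gap + 2 (min_duplex − 1)` nt. The published
spacing recommendation — gap at most the minimum anticipated insert size
minus 20 nt — is one nucleotide more conservative than this exact bound
(`gap ≤ L_min − 19`). `validate_spacing()` judges pass/fail by the
published rule, reports the exact bound and an explicit escape enumeration
alongside, and flags where the two disagree rather than re-judging. Gap
distances are footprint-edge to footprint-edge; because shrinking an
escaping insert preserves escape, enumerating inserts of exactly the
minimum size is exhaustive. Uncovered terminal regions are reported
informationally, and footprints of ≤ 22 nt are flagged: short probes are
the one empirically observed failure mode the model cannot otherwise
predict.

**Design.** `design_probe_set()` tiles a target greedily left to right:
each next window sits as far right as the rule allows, and within a ±5-nt
slack the window with the largest Tm differential (target Tm minus best
off-target Tm against the rest of the transcriptome) wins, ties breaking
rightward to maximize spacing. A window is disqualified when its best
off-target comes within twice the margin of its target Tm — no
hybridization temperature could then separate them — and an error names
the blocked interval if a whole slack window is disqualified. The output
is asserted to pass `validate_spacing()` with zero failures.

## The library simulator

`simulate_fragments()` draws inserts by sampling a transcript with
probability proportional to abundance weight × length, then length
uniformly over the size-selection range (truncated to the transcript) and
5' position uniformly over the valid range. This models the 5'-position /
length joint distribution directly instead of simulating chemical
breakpoint chains, because every downstream analysis depends only on that
joint distribution. The default pool — one 1800-nt rRNA-like transcript
at weight 200 plus fifty 500–2000-nt mRNA-like transcripts at weight 1 —
emulates rRNA dominance of fragmented total RNA. The default size
selection is 25–200 nt (the gel-selected insert range) and reads are
150 nt.

`simulate_pdd_pair()` splits one insert draw into two equal aliquots,
treats one with `apply_pdd()` (each cleavable insert removed independently
with probability `p_cut`; 0 and 1 applied deterministically) and leaves
the other untreated — mirroring a split library intermediate. Fixed seeds
give byte-identical emissions (TSV and FASTQ).

What the simulator deliberately does **not** model: sequencing errors,
quality trimming, adapter/poly(A) artifacts inside reads, PCR bias,
non-uniform fragmentation chemistry, RNA secondary structure limiting
probe access, and partial-duplex cutting of RNA:DNA hybrids. Passing
tests therefore demonstrate the internal consistency of the cleavage
model and estimators, not wet-lab efficiencies; the empirical ~94%
depletion efficiency of the published protocol is a laboratory quantity
that the simulator represents only through `p_cut`.

## Depletion and bias metrics

All density work uses per-position counts of read 5' ends. Moving
averages are centered with windows truncated at transcript ends (the mean
over available positions), so profiles stay defined at termini; mass is
conserved exactly in the interior and only edge windows renormalize.
Masked (`NA`) positions are skipped by the smoother, not propagated.

`ratio_profile()` computes, for one transcript and one inclusive
insert-size group: smoothed 5' densities (9-nt window) in each library,
each normalized by that library's total mRNA-mapped read count within the
size group (library-loading normalization), and their ratio × 100.
Positions where the smoothed untreated density falls below a floor
(default $10^{-6}$ of the untreated in-group total) are masked — the
published analysis does not state how zero-coverage positions were
handled, so masking is explicit here. `probe_pileup()` re-indexes each
probe's curve to its 3' end, smooths with a 7-nt window and averages
across probes; `interprobe_ratio()` counts reads between adjacent
footprints extended 10 nt into each probe.

**Efficiency.** `depletion_efficiency()` anchors the profiles at each
functional probe's 3' end, averages across probes, and subtracts the
minimum of that mean curve from 100. The minimum is taken inside the core
zone — the x-range where *every* insert in the size group is cleavable,
$[\,d - L_{\min} - \ell + 1,\ -(d-1)\,]$ for duplex threshold $d$ and
probe length $\ell$ — where the expected ratio is exactly
$(1 - p_\mathrm{cut}) \times 100$. Averaging across probes *before*
taking the minimum matters: the minimum of many noisy per-probe curves is
biased low by extreme-value selection, while the minimum of the averaged
curve recovers the cleavage probability essentially unbiased. The test
suite demonstrates recovery of $100\,p_\mathrm{cut}$ within ±2 percentage
points at $2 \times 10^5$ simulated inserts for
$p_\mathrm{cut} \in \{0.5, 0.9, 1\}$. "Functional" probes are all probes
minus an explicit exclusion list, mirroring the possibility of a failed
probe in a real panel.

**Bias.** `orf_counts_with_offtarget_tm()` pairs per-ORF raw counts with
the best off-target probe match Tm inside each ORF (an `NA` sentinel when
there is none — never 0). In simulation, probes targeting only the
rRNA-like transcript leave per-ORF log2 treated/untreated ratios centered
on zero regardless of planted sub-hybridization-temperature off-target
sites; the suite checks this with $4 \times 10^5$ inserts — chosen once
to give each ORF a few hundred mRNA reads so the per-bin mean is
estimated to well under 0.1 log2 units — and 11–14-nt planted fragments.

**Duplicates.** `duplication_analysis()` compares observed exact 5'
duplicates per ORF with the mean over repeated uniform reshuffles of the
same read count across the ORF's available positions (spliced length
minus the median read length): at least 100 reshuffles for ORFs with more
than 10 reads and at least 500 for ORFs with 2–10 reads; ORFs with fewer
than 2 reads or no available positions are skipped. The mean of
reshuffles is used as the summary statistic, and the tests validate it
against the closed-form expectation $n - P\,(1 - (1 - 1/P)^n)$.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; every TSV report uses
  1-based inclusive coordinates and says so in its header.
* Size-group membership is inclusive on both bounds of the insert length.
* Overlapping footprints are collapsed (with a warning) before gap
  analysis; duplicate probe ids are an error; probes with no full-length
  intended-target match are reported as unable to act as designed.
* Insert lengths exceeding the transcript are truncated away with a
  warning; a transcript shorter than the minimum insert is excluded from
  simulation.
* From SAM/BAM only primary, mapped alignments are counted; the
  hierarchical multi-reference mapping of the original analysis is
  replaced by a user-supplied category table.

## Problem sizes

The shipped test suite runs entirely from generated data: scanner oracle
equivalence on 1,000 random pairs, survival-profile enumeration on
2,000-nt targets, parameter recovery on $2 \times 10^5$-insert pairs and
the bias check on $4 \times 10^5$ inserts — sizes at which the binomial
error of every asserted quantity is several times smaller than its
tolerance.
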