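---
title: "Quantifying genome-editing outcomes with editscan: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-editing outcomes with editscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The estimation problem

Amplicon deep sequencing of a nuclease-targeted locus yields reads that
must be turned into an estimate of the fraction of molecules carrying a
genuine repair outcome. Every step of that conversion can bias the
estimate: reads from other loci (off-target amplification) inflate or
deflate it, primer dimers align as enormous deletions, genetic differences
between the sequenced individuals and the reference amplicon look exactly
like edits, and an alignment model not matched to double-strand-break
repair scatters one indel into several. `editscan` treats each of these
explicitly. This vignette records the models, the tunable parameters, and
the reasoning behind every choice that was genuinely open.

# Alignment model

Reads are globally aligned to their amplicon with the Needleman–Wunsch
algorithm under the scoring

| parameter | default | unit |
|---|---|---|
| match | +5 | per column |
| mismatch | −4 | per column |
| gap opening | −25 | per gap run |
| gap extension | 0 | per gap base |
| end gaps | free | — |

A run of $k$ gap bases costs $\text{open} + k \cdot \text{ext}$; with the
default extension of 0 every internal gap run costs −25 *regardless of
length*. This encodes the biology of repair: a cut-and-repair cycle
produces one deletion and/or one insertion, so an alignment with one long
gap must beat an otherwise equal alignment with two short ones (−25 vs
−50). Free end gaps mean a read covering only part of the amplicon pays
nothing for its unsequenced flanks — and, correspondingly, end-gap columns
never produce deletion events.

The dynamic program is implemented in C++ (Gotoh three-state recursion)
with an integer fast path for whole-valued parameters. Traceback
tie-breaking is fixed: diagonal is preferred over a gap in the read
(deletion), which is preferred over a gap in the amplicon (insertion); the
endpoint scan prefers fewer end gaps. Users may change any scoring
constant; conventional affine-gap behavior is recovered by setting a
nonzero extension penalty.

## Events and coordinates

Alignments decompose into atomic events — insertions, deletions,
mismatches — on 0-based half-open amplicon coordinates (insertions are
zero-width anchors at the insertion point). Exported tables are 1-based
inclusive in the style of GenomicRanges, with insertions reported at the
base immediately left of the insertion point with width 1.

Indel placement inside repeats is ambiguous, so all indels are
**left-normalized** to their leftmost equivalent position, with the
inserted sequence rotated accordingly. This makes event identity — the
tuple (type, start, end, replacement) — canonical, which the control
normalization and HDR matching below rely on. A property test verifies
that applying the extracted events to the amplicon reconstructs the read
over its sequenced span exactly.

## Paired ends

Reverse mates are reverse-complemented before alignment so both mates
share amplicon-forward coordinates. A mate covers the interval between its
first and last aligned (non-end-gap) column. Within the interval covered
by both mates the mate with the higher alignment score decides — events it
lacks are dropped, events it has are kept once — and outside it each mate
contributes its own events. At equal scores the forward mate wins, so
output is deterministic. The full consensus decision procedure of the
original tool is not published in its main text; this rule set implements
the published summary (best alignment wins on disagreement) and is
documented here as such.

# Filters

**Primer dimers** are amplification artifacts without the internal
amplicon. After alignment they appear as a deletion wider than
`amplicon − forward primer − reverse primer − buffer`. The buffer defaults
to 30 nt (configurable); the comparison is strict (`>`).

**Off-target / artifact reads** originate from a different locus and
therefore carry far more mismatches than on-target reads. The filter
estimates a per-base mismatch noise rate as the count-weighted median of
per-read mismatch rates, floored at `min_noise_rate = 0.01`, and flags a
read when the binomial upper-tail probability of its mismatch count over
its aligned length falls below `alpha = 1e-3`, or when it carries more
than `max_indel_events = 4` indel events. Design notes:

* the *median* keeps the estimate anchored to the clean majority even with
  substantial contamination;
* the *floor* prevents a degenerate estimate of 0 on error-free data,
  where a single stray mismatch would otherwise have tail probability 0
  and every such read would be flagged;
* with the floor, a 200-nt read needs roughly 9+ mismatches (≥ 4.5% of
  its span) to be flagged, while genuine contaminants at 10–50% per-base
  divergence are flagged essentially always.

Flagged reads leave every numerator and denominator; their counts are
reported per stage in the filter report, which conserves read counts:
input = quality-rejected + unassigned + per-experiment assigned, and
assigned = dimer + artifact + retained.

# Control normalization

Controls (unedited samples) are processed by the identical pipeline. Any
event whose frequency among control reads is **strictly greater than 1%**
(configurable) is removed from the treatment — by event identity, not by
read: the retained read count is unchanged, and other events on the same
read survive. A read carrying a control-supported 11-bp deletion *and* a
novel insertion therefore still counts as edited. Normalization is
idempotent and can only lower the efficiency estimate; both properties are
enforced by tests. Event matching is exact after left-normalization; a
coordinate-slack option exists for fuzzy matching but defaults to 0.

Treatments link to the union of all control rows sharing their amplicon
and barcode, or to an explicit `Control_ID` column when present.

# Quantification

**Cut window.** For a 20-nt SpCas9 guide found on the forward strand at
position $p$, the blunt cut lies 3 nt 5' of the PAM, i.e. at coordinate
$p + L - 3$; reverse-strand guides are mirrored. The window is the cut
± 5 nt (half-open), clamped to the amplicon. The offset and flank are
configurable, and an explicit window override supports nickases and TALENs
where the cut position is uncertain. The −3 offset is the standard Cas9
convention; it is a package choice, documented here, since protocols vary
for other nucleases.

**Efficiency.** A read is edited iff at least one insertion or deletion
overlaps the window; insertions overlap iff their anchor lies inside it
(zero-width "overlap" is otherwise ill-defined). Mismatches never count:
substitution sequencing errors must not inflate indel efficiency.

**Frameshift.** The net indel length — insertions minus deletions — is
summed over *all* retained indels on the read, not only window-overlapping
ones, and the read is frameshift iff the net is not divisible by 3.
Frameshift reads are counted among edited reads, so the frameshift
percentage can never exceed the efficiency.

**HDR / base editing.** The donor template is aligned to the amplicon with
the standard scoring and its events become the expected-event set (for
base editors these are mismatches). A read is HDR iff it contains *every*
expected event; extra events are tolerated, because a genuine integration
may co-occur with additional indels. Non-HDR reads with window indels are
NHEJ; the classes are disjoint by construction. Whether a read carrying
the donor events *plus* extra cut-site indels should count as HDR, NHEJ or
both is not decidable from the published description; the
strict-but-tolerant disjoint rule used here recovers generating HDR/NHEJ
mixtures in simulation, which is the property that matters for the
estimates.

**Heterogeneity.** Reads group by signature (their sorted event list;
event-free reads share the empty signature). The spectrum's Shannon
entropy in bits summarizes mosaicism: 0 for homogeneous outcomes, 1 bit
for a 50/50 mixture.

**Aggregation.** Statistics aggregate at identifier, barcode, guide,
amplicon, group and summary levels by summing read counts and recomputing
percentages from the sums — never averaging percentages, so experiments
weigh by read count. Ties in top-signature tables break lexically for
deterministic output.

# The synthetic-data generator

`simulation_spec()` / `simulate_experiment()` generate the benchmark the
package is validated on: by default 20 independent loci of 200 nt (20-nt
primers at both ends, a unique 20-nt protospacer mid-amplicon), 1000
single-end full-length reads per locus at constant Phred 37, and a
per-read editing probability taken from the study levels 0, 1/3, 2/3 and
0.9. Edited reads carry one indel; lengths are uniform within the mode's
range (`short_only` 1–9 nt, `mixed` 1–30 nt, `long_insertions` /
`long_deletions` 10–30 nt). Off-target contaminants are amplicon copies
substituted at a per-base rate (default 30%) at uniformly chosen
positions; sequencing errors are uniform substitutions (default rate
0.001, set to 0 in the exactness benchmarks). In donor mode the donor is
the amplicon with a 6-bp insertion at the cut, HDR reads carry exactly the
donor sequence, and NHEJ reads carry a random cut-site indel. A truth
table records every read's category and indel. All randomness flows from
one seed; identical seeds give byte-identical FASTQ output.

**Indel placement.** Deletions start uniformly in $\{c-d, \dots, c\}$
(they span the cut coordinate $c$); insertions anchor within ±2 nt of the
cut. Placement at the break is the biologically faithful model — NHEJ
indels form at the double-strand break — and it also keeps the benchmark
honest: an indel placed merely *near* the window edge can be shifted out
of the window by left-normalization through a repeat, which would
systematically undercount truth through no fault of the estimator.

**What the simulator does not model:** sequencer-specific error profiles
(per-cycle error rates, homopolymer errors, quality-score variation),
PCR chimeras, real genetic variation between individuals, or mixed indel
events with microhomology. Passing the recovery benchmarks therefore shows
that the estimator is unbiased under idealized reads with known truth; it
does not certify performance on any particular instrument's error
profile.

# Validation and problem sizes

The test suite validates the alignment kernel against two independent
oracles (a memoized recursion over run-costed alignments, itself checked
against literal enumeration of all alignment paths for short sequences),
primer matching against a brute-force Hamming scan, and the pipeline
end-to-end against simulator truth. The end-to-end benchmarks use the
full 20-locus × 1000-read design at every efficiency level and indel mode,
with 25% contamination at 10–50% divergence for the robustness check and a
30%/30% HDR/NHEJ mixture for donor mode; recovery is required within
three binomial standard errors of the realized truth. The worked-example
fixture (11-bp frameshift deletion in 11% of reads, 3-bp in-frame deletion
in 3%, and a control sharing the 11-bp deletion at 9%) reproduces its raw
efficiency, frameshift fraction and post-normalization efficiency exactly;
`scripts/acceptance.R` recomputes all of these from scratch.

# Known limitations

* Single-end assignment uses the forward primer only when no reverse
  FASTQ is configured; primer anchoring at position 0 is the default and
  relaxing it to a 5' scan window is opt-in.
* The artifact model is a per-read binomial test; it does not model
  overdispersion across reads, which a locus with internal repeats or
  systematic context errors could exhibit.
* HDR quantification requires the donor's expected events to be
  alignable landmarks; donors differing from the amplicon only in regions
  a read does not cover cannot be scored.
* Event identity for normalization is exact; true biological equivalence
  classes broader than left-normalized coordinates (e.g. distinct indels
  with identical protein consequence) are intentionally not merged.
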