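---
title: "Methods: cross-sample enrichment of polymorphic microsatellites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-sample enrichment of polymorphic microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyssr)
```

## The model

A microsatellite locus is a maximal perfect run of a 1–6 bp motif. If
two transcripts from different samples are homologs (assembled from the
same gene), carry the same repeat motif in the same flanking context,
and differ in the number of repeat units, the locus is *putatively
polymorphic*: the repeat-length difference observed between assemblies
is the same signal a genotyping assay would read out. `polyssr`
operationalises this comparison as a pipeline of six stages — mining,
clustering, strand normalisation, enrichment, false-positive removal,
reporting — each of which is an exported, individually testable
function.

The key assumptions are:

* assembled transcripts represent each ecotype's allele faithfully
  enough that the repeat count in the assembly equals the repeat count
  in the template (assembly collapse of heterozygous repeat alleles is
  not modelled);
* homology is recoverable by sequence identity alone (≥ 90 % over the
  shorter sequence), which holds within species but is not designed for
  cross-species comparisons;
* a repeat locus is usable as a marker only with ≥ 50 bp of flanking
  sequence on both sides, the minimum for primer placement.

## Mining rules and their edge cases

Mining reports every maximal run of whole motif copies meeting the
per-unit-size minimum counts (defaults `10, 6, 5, 5, 5, 5` for unit
sizes 1–6). Several rules make "every maximal run" unambiguous:

* **Whole copies only.** `(AC)6` followed by a lone `A` is a 6-copy
  locus; partial trailing units never count.
* **Shortest period wins.** A run of period 2 is also a run of period 4
  and 6; only the primitive (non-decomposable) motif is reported, and
  when two loci of different unit sizes cover exactly the same interval
  only the shorter period is kept.
* **Leftmost anchoring.** A phase-shifted tandem array (`CACACAC`) has
  two equally maximal descriptions; the leftmost start is reported, and
  two reported loci of the same unit size never overlap.
* **`N` is a hard break.** Motifs never contain `N`, and an `N` inside a
  run splits it into two runs that are scored independently.

These rules are enforced twice: once in the vectorised implementation
and once in a literal brute-force enumeration over (start, unit size,
count) triples used as the test oracle; the suite requires exact
agreement on 1,000 random sequences (length ≤ 500, 1 % `N`).

Compound microsatellites — runs separated by at most `max_interruption`
(default 100) interrupting bases — are *annotations*, not merged
records: each component keeps its own repeat count so that downstream
count comparisons remain per-component. Candidates that sit inside a
compound group are emitted with `inside_compound = TRUE` rather than
suppressed (suppression is available via
`enrichment_params(keep_compound = FALSE)`); flagging preserves
information, and whether compound loci make good markers is a decision
better left to the user.

## Pairwise alignment and the identity definition

All alignments use one deterministic affine-gap kernel (C++): match +1,
mismatch −1, gap open −4, gap extend −1, where a gap of length $L$ costs
$-4 - (L-1)$. This convention equals Biostrings' `gapOpening = 3,
gapExtension = 1`, which is what the test suite uses as an independent
engine. `N` never matches anything (it scores as a mismatch and never
counts as an identity). Traceback ties are broken in a fixed order —
match/mismatch, then gap in the incoming sequence, then gap in the
reference — so alignments are reproducible across platforms.

**Identity** between two transcripts is the number of identical aligned
bases in an end-gap-free ("overlap") alignment divided by the length of
the *shorter* sequence. This makes a perfect substring score 1.0, which
is the behaviour wanted for transcript isoforms of different lengths.
The definition degrades when sequences are highly diverged, which is why
thresholds below 0.80 are rejected at configuration time.

## Clustering design

The clustering contract is deliberately *not* a re-implementation of
CD-HIT-EST's internals (short-word counting, first-fit assignment);
those are heuristic and implementation-defined. Instead the procedure is
fixed so it can be checked against an oracle:

* records are processed longest-first (ties by source tag, then id), so
  permuting input rows or input files cannot change the result;
* each record joins the *best-fitting* existing representative at or
  above the identity threshold, on whichever strand scores higher, else
  founds a new cluster — the representative is therefore the longest
  member, matching the length-sorted convention of clustering tools in
  this field;
* clusters are formed jointly across all input files (polymorphism is a
  cross-file property, and a single clustering pass keeps every homolog
  of a family in one cluster);
* singleton clusters are dropped (`min_members = 2`) because a
  repeat-count comparison needs at least two members.

A shared-11-mer prescreen skips alignment against representatives with
fewer than `min_shared_kmers = 5` shared 11-mers on either strand. This
is an optimisation with a correctness contract, not an approximation
knob: at the identities the pipeline accepts (≥ 0.80 over ≥ 100 bp
after the short-sequence bypass), a true pair shares hundreds of
11-mers, and the test suite verifies that planted families are never
split. Sequences under 100 bp bypass the prescreen entirely.

## Matching homologous loci and calling polymorphism

How to decide that two loci in two cluster members are "the same"
locus is left open by the enrichment idea itself; `polyssr` uses
**flanking anchors**: two loci match when their canonical motifs and
unit sizes agree and the 20 bp immediately upstream of both loci — or
the 20 bp immediately downstream — differ at ≤ 4 positions. Anchors are
cheaper than a full multiple alignment, independent of member order,
and robust to a paralogous extra copy elsewhere in the transcript.
Pairing is greedy on best anchor agreement (fewest mismatches, ties to
the leftmost pair), each locus joins at most one group, and a group
holds at most one locus per member. Canonical motifs are the smallest
cyclic rotation *without* strand folding — members are already
co-oriented by the time motifs are compared, and folding strands would
wrongly merge a motif with its reverse complement within one
orientation.

A matched group is called polymorphic when max − min repeat count ≥ 1.
No minimum difference larger than one unit is imposed: one repeat unit
(2–6 bp) is resolvable by standard fragment analysis. By default the
differing counts must come from members of *different* input files
(`require_cross_file = TRUE`); a repeat difference between isoforms of
one assembly is an assembly artifact, not evidence of polymorphism.

The **false-positive screen** drops an entire cluster when, for any
motif, one member carries ≥ 2 loci of that motif and another member
carries strictly fewer — applied per canonical motif at cluster scope,
on the *post-filter* loci (the screen is defined on the enrichment
results), and dropping the whole cluster rather than just the motif:
a member set that disagrees on repeat copy *number* is paralogous or
chimeric, and none of its count comparisons can be trusted.

The 50 bp flank rule is interpreted strictly: a flank of exactly 50
passes, 49 fails.

## Multiple alignment for reporting

Per-cluster alignments use centre-star progressive alignment with the
representative as centre and "once a gap, always a gap" merging, under
the same scoring kernel. No external MSA program is involved: at ≥ 90 %
identity centre-star is near-optimal, fully deterministic, and each
member-to-centre pair can be verified against a dynamic-programming
oracle, which the test suite does. Output is gapped FASTA (gap `-`)
plus a table mapping every SSR locus to its alignment columns.

## The synthetic-data generator

The generator emulates the input regime the pipeline is built for:
families of homologous transcripts shared across ecotypes, with planted
repeat loci whose counts differ between ecotypes, negative-strand
copies, substitution divergence, and decoys. Default study conditions
(chosen once, as realistic for transcriptome comparisons of conspecific
ecotypes):

| parameter | default | rationale |
|---|---|---|
| ecotypes | 2 | the minimal cross-sample design |
| transcript length | 400–800 bp | typical assembled transcript sizes |
| polymorphic families | 30 % | enriched relative to real data so every run exercises the positive path |
| decoys (mononucleotide, near-end, paralog, monomorphic, within-file) | 10 % each | every rejection rule is exercised |
| substitution rate | 0.01 | conspecific transcript divergence |
| negative-strand copies | 20 % | strand is effectively random in assemblies; 20 % keeps both branches hot |
| planted counts | dimer 6–13, trimer 5–10, tetramer 5–8 (+1..3 units across ecotypes) | at or above mining thresholds, differences within fragment-analysis range |

Two constructions keep the truth table exact. Substitutions never hit a
planted tract or its ±30 bp anchor region, so planted counts and anchors
are never mutated — divergence elsewhere stresses clustering
realistically without blurring the ground truth. And a fixed *guard
base* is placed on each side of a planted tract (different from the
motif base that would continue the run), so random backbone sequence can
never extend a planted repeat by a whole unit and silently shift its
count.

The truth table's `expected_detectable` flag re-derives the pipeline's
filters independently (unit size ≥ 2, both flanks ≥ 50 bp in every copy,
counts meeting the mining thresholds, a genuine cross-ecotype
difference); the headline validation property is that the pipeline and
this independently computed flag agree perfectly at zero substitution
noise.

What the generator does **not** emulate: indels outside repeat tracts,
sequencing/assembly errors, chimeric transcripts, alternative splicing
within a family, allele collapse, or repeat interruptions. Passing the
end-to-end tests therefore demonstrates that the *logic* of every stage
is correct under clean homology, not that recall on real assemblies will
be 100 % — on real data, recall is bounded by assembly quality, and the
wet-lab polymorphic rate of candidates is an empirical question outside
the package's scope.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the MISA dialect).
* IUPAC ambiguity codes are converted to `N` with a warning rather than
  rejected; `U` maps to `T`.
* An empty FASTA file, duplicate record ids within a file, and duplicate
  source tags across files are errors; a run with zero candidates is not
  (it writes a header-only table).
* With no candidates, `score_against_truth()` reports precision 1 with
  `precision_defined = FALSE` rather than 0/0.
* All randomness in the generator flows through one seed; the pipeline
  itself uses none, and every TSV output is byte-identical across reruns
  and input-order permutations.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) runs the
mining oracle comparison at 1,000 random sequences, clustering recovery
at 200 families (5 % divergence, 20 % negative strands), and end-to-end
recovery at 500 families with all decoy categories at their default
rates and zero substitution noise. These sizes exercise every code path
many times over while keeping a full validation run in the minutes
range on a single core.

## Known limitations

* Imperfect (interrupted) repeats are not detected; unit sizes are
  capped at 6.
* The identity definition (matches / shorter length) is permissive for
  short fragments contained in longer transcripts; such fragments join
  the longer member's cluster by design.
* Centre-star alignment quality degrades below ~80 % identity — outside
  the supported clustering range, but worth knowing if the aligner is
  reused directly.
* Primer design, allele-frequency estimation and genotype calling are
  out of scope; the output is a candidate list for downstream marker
  development.
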