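---
title: "Curation methods: rules, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: rules, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igrefset)
```

`igrefset` turns a curation protocol for immunoglobulin germline reference
sets into testable code: structural gates, evidence independence rules,
exact-paralog collapse, truncation repair and AIRR-seq-based locus
inference. This vignette records the model behind each stage, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open — together with what the synthetic tests do and do not show
about real data.

## The curation model

**Structural gates.** Candidate V alleles are exon-start-anchored germline
sequences, so the reading frame is frame 0 from the first nucleotide; an
allele is an ORF when no full codon of its span is TAA/TAG/TGA. The two
conserved cysteines framing the V-domain fold are located by mapping each
candidate onto a per-family exemplar that carries annotated cysteine codon
positions — alignment to an exemplar rather than a hard-coded gapped
numbering system, because the inputs are plain nucleotide sequences and the
exemplar travels with the fixture or dataset. The gate is gene-level: a gene
survives when at least one allele is an ORF with both cysteines, and
non-ORF alleles of surviving genes are retained with `is_orf = FALSE`. This
removes most pseudogenes without any claim about functionality, which the
package deliberately does not assess (regulatory and RSS variation put
functionality outside what sequence content can decide).

**Truncation.** A candidate is compared with the longest *other* allele of
its gene, falling back to the longest allele of its family and then to the
family exemplar. A lone allele with no longer comparison is never flagged:
a genuinely short gene cannot incriminate itself. Missing ≥ 25 nt at one
end excludes the candidate (`major_truncation_nt`); any smaller deficit is
flagged as extendable. The threshold enum distinguishes only minor and
major classes; deficits of 3–24 nt are treated as extendable like the 1–2 nt
class, because documented cases of substantial-but-sub-major truncations
were repaired from genomic or AIRR evidence, while the similar-allele donor
(see below) stays capped at 2 nt. The comparison itself uses, in order: an
exact substring match, an end-anchored placement accepting ≤ 25 % mismatch
over the overlap, and finally an overlap (ends-free) pairwise alignment
(match 2, mismatch −3, gap open 5, extend 2). The anchored path covers
same-length variants and clean end-truncations — the overwhelmingly common
cases — and keeps the pipeline fast; the alignment fallback handles indels.

**Evidence.** Confirmation needs `min_independent_reports = 2` independent
reports. Independence is evaluated pairwise by (kind, laboratory/study):
genomic reports from the same laboratory collapse to one; a single genomic
study confirms alone when it unequivocally covers at least
`min_genomic_individuals = 2` individuals. An AIRR-seq inference counts as
one report only conjunctively — seen in at least `min_airr_individuals = 2`
individuals *and* corroborated by an unrearranged GenBank record — never as
an additive count of individuals. An IARC affirmation counts as one report;
a configuration switch (`iarc_auto_confirm`, default `FALSE`) covers the
alternative reading in which an affirmation suffices alone, since whether
the affirmation and the AIRR data behind it are one report or two is not
decidable from the rules themselves and the shared-provenance reading is
the conservative one. Novelty matters for the single-genomic-study
exception: a previously unreported sequence (temporary "NL" or "*i"-style
names) needs `min_airr_individuals_novel_genomic = 6` individuals rather
than 2, reflecting the stricter bar applied to novel alleles observed in a
single genomic survey. These rules are monotone: adding evidence can never
un-confirm a candidate (a property the test suite checks directly).

**IGHD expression admissibility.** Exonuclease trimming removes D gene ends
from expressed rearrangements, so AIRR-seq genotypes can only vouch for
centrally located nucleotides. Expression evidence is admissible for a D
allele only when every position distinguishing it from its same-length
relatives lies ≥ `d_central_margin_nt = 3` nt from both ends, the allele is
longer than `2·3 + 1` nt, and the allele is not a member of an
identical-sequence pair (expression cannot attribute reads to either
member). The exported rule returns `FALSE` for an empty distinguishing set;
inside the pipeline a D candidate with *no* same-length relative keeps its
AIRR evidence, since length alone then identifies the gene.

**Reference Set construction.** Extension donors are prioritised IARC
recommendation > genomic > AIRR consensus > similar-allele endings. The
similar-allele donor is the majority ending among longer same-gene alleles
(ties to the lowest allele number) and is limited to
`minor_truncation_max_nt = 2` nt — endings borrowed from relatives are a
last resort and only credible for a couple of nucleotides. Both 3' and 5'
machinery exist, though 3' truncations dominate in practice. Extensions
never alter interior nucleotides, and stripping `extended_5p`/`extended_3p`
recovers the Source Set sequence exactly; Source Sets themselves are never
modified. Exact-paralog collapse operates on full-length string equality
only (no near-duplicate clustering): the representative is chosen by
explicit override, else the non-"D" gene name (IGHV1-69 over IGHV1-69D,
proximal IGKV3-15 over distal IGKV3D-15), else lexicographically smallest
gene and lowest allele number. Overrides exist because at least one real
case (a sequence retained under a different gene's name) follows curatorial
judgement, not a derivable rule.

**Locus inference.** "Always associated with one J allele" is
operationalised as: ≥ `haplotype_min_reads = 10` anchored unmutated reads
and purity ≥ `haplotype_purity = 0.95` for assignment to one haplotype;
adequate coverage failing purity is called "both", less coverage
"unassigned". The mutation cap for informative reads defaults to 0
(unmutated only) — inference from naive-cell repertoires is the intended
setting, and mutated reads risk mis-phasing; the cap is configurable. A
co-location call requires opposition in *every* informative individual; a
single contradictory individual vetoes the call, and a call never overrides
an explicitly recorded locus. Kappa frequency classification aggregates
per-individual expression frequencies by the median (robust to one
outlying repertoire; per-individual panels are what the underlying
observations look like) against bands `proximal_freq_hi = 4.0 %` and
`distal_freq_lo = 0.6 %` of the productive VJ repertoire, and is monotone
in the frequencies. Lambda location inference is not attempted: there is no
commonly heterozygous IGLJ anchor to phase by.

## What the synthetic data emulates

`generate_locus()` builds a toy locus with per-family exemplars, functional
genes (every third carrying two alleles, so haplotype tests have
heterozygous genes), pseudogenes with injected stop codons or cysteine
knockouts, exact paralog pairs (labelled proximal/distal for kappa), an
anchor J gene with two alleles, and short D genes. `generate_reports()`
emits every true allele with independently confirmable evidence and adds
the historical error modes — substitution errors, stop codons, cysteine
knockouts, 1–2 nt 3' truncations (with genomic donor endings recording the
truth) and ≥ 25 nt truncations — always with single-source evidence for the
erroneous candidates, mirroring how errors in the literature are usually
singletons. `simulate_repertoire()` draws each record from one haplotype
with perfect V–J linkage (an optional noise rate exists), gives proximal
pair genes an expected 5.5 % repertoire share and distal members 0.35 %
(inside the 4 % / 0.6 % bands), and trims D ends by independent geometric
amounts with mean ≈ 2 nt per end, so full-length D observations are a
minority. Reads cover the V region fully from its 5' end, because the
artifact under study concerns 3' ends.

The truncation-misassignment demonstration uses a two-allele gene in which
*01 is reported 2 nt short, *02 differs at one internal position, and both
share the true 3' end: under identity-count scoring with ties to the lowest
allele number, reads from a *01 carrier are misassigned to *02 exactly when
their trimmed 3' end plus random junction nucleotides extend the *02
alignment past the truncated *01 entry — a minority of reads, every one
carrying the internal mismatch — and extending the *01 entry removes the
effect entirely. This geometry was chosen over placing the distinguishing
difference inside the truncated window because only an internal difference
reproduces the observed signature that every misassigned alignment shows at
least one mismatch.

What passing these tests does **not** show: the generator has no somatic
hypermutation beyond an optional uniform rate, no clonal lineage structure,
no sequencing error in reads, no allele-frequency skew across individuals,
and its evidence patterns are cleanly typed rather than the ambiguous
provenance of real literature reports. Results on it validate the *rules*,
not the difficulty of applying them to real corpora.

## Fixtures and problem sizes

The per-chain candidate fixtures mirror the category composition of the
curated human corpora (e.g. 295 IGHV candidates: 67 structural rejects, 22
unconfirmed, 8 exact-duplicate pairs, 29 short-truncated; 102 IGKV with 5
proximal/distal duplicate pairs; 115 IGLV including 3 substantial
truncations repaired from genomic/AIRR endings; 34 IGHD with 2 identical
pairs and one candidate whose only expression evidence is a terminal
nucleotide). Substantially truncated fixtures carry a full-length sibling
allele, since their truncation removes the second-cysteine codon and the
gene must pass the gate through another allele — which is also how such
alleles survive in real curation. The repertoire tests use 20 individuals ×
1500 reads, and the artifact demonstration 10⁴ reads over 5 seeds; these
sizes give fully deterministic category counts and stable stochastic
summaries while keeping the whole suite inside a few minutes on one CPU.

## Degenerate inputs and tie-breaks

Empty evidence confirms nothing; an empty candidate sequence fails
validation everywhere except D/J structural filtering, where it is the one
rejection reason. An empty Source Set builds an empty Reference Set with
"(none)" release notes. Equal anchored-read splits (purity exactly 0.5)
are "both"; a comparison allele tie is broken by lowest allele number then
name; annotation ties go to the lowest allele number then lexicographic
gene name, matching downstream tools' observed behaviour. Version labels
are caller-supplied strings — the package never invents version numbers,
leaving registry mechanics (DOIs, database integration) out of scope.

## Known limitations

Conserved-cysteine detection depends on the supplied exemplar annotations;
a wrong exemplar position silently shifts the check. Truncation flagging of
a lone allele requires a family comparison and can in principle flag a
genuinely short gene whose family is longer. The evidence engine treats
laboratory identifiers as ground truth for independence and does not judge
study quality — that editorial decision lives in the evidence tables it is
given. The comparator and diff operate on sequences and names only, not on
the alignment-level coverage statistics a full benchmark against real
repertoires would need.
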