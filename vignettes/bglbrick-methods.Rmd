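---
title: "BglBrickKit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BglBrickKit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BglBrickKit)
```

This vignette records how the package models BglBrick cloning and the
datasheet analytics, which parameters matter, and where the design was
genuinely open — and what was decided in those places.

## Sequence model and restriction chemistry

DNA is a `DnaSeq`: an uppercase ACGT string with a topology flag and 0-based
half-open feature coordinates (GenBank serialization converts to 1-based
inclusive, with `join()` locations for features wrapping a circular origin).
IUPAC ambiguity codes are rejected outright rather than matched fuzzily:
every downstream guarantee (site counting, digestion, validation) relies on
exact hexamer matching, and an `N` would silently weaken all of them.
Circular molecules compare equal under rotation and reverse complement
(`circularEqual`), which is the identity notion every round-trip test uses.

Enzyme geometry is a bundled eight-row table (recognition hexamer plus top-
and bottom-strand cut offsets). The cut offsets are standard restriction
enzymology rather than anything measured here, so they are pinned by tests
against the facts the cloning steps imply: BglII and BamHI leave the same
5' `GATC` overhang (that compatibility is what makes the assembly standard
work), AvrII and SpeI share 5' `CTAG` (used to install the pBBR1 origin
while destroying one junction site), and AatII/SacI leave 4-nt 3'
overhangs (`ACGT`/`AGCT`) that are mutually incompatible, which is what
keeps the three module boundaries orthogonal.

A digest fragment stores the parent top strand between top-strand cuts plus
explicit end chemistry (kind, overhang text, generating enzyme). Two ends
ligate iff both are blunt or the kinds and overhang texts match; all eight
recognitions are palindromic, so their overhangs are self-complementary and
text equality is exactly Watson-Crick annealing. Ligation is deterministic
pairwise joining chosen by the caller — this is CAD semantics, not reaction
kinetics; no partial digests, star activity, or ligation efficiency.

## Part validity and why assembly is idempotent

A BglBrick part is prefix (EcoRI, spacer, BglII) + insert + suffix (BamHI,
spacer, XhoI). Validity is deliberately defined on the **full molecule**:
the only four-enzyme hits allowed are the four flank sites themselves. This
is stronger than "no internal sites in the insert" and it matters: an insert
ending `CTCGA` forms an XhoI site against the suffix's leading `G`, and an
insert starting `CGAG` forms one against the prefix's trailing `CT`. Such a
molecule would be cut in the wrong place in a real digest, so it is not a
usable part — and excluding it buys a clean theorem: because the `GGATCT`
scar and the default suffix share their first five bases (`GGATC`), and the
scar's `CT` tail matches the prefix's, every junction context that could
create a forbidden site in a composite is a context already excluded by the
parents' own validity. Valid parts are therefore exactly closed under
assembly, which is what the idempotence property tests exercise on random
part pairs. With non-default flanks the closure argument may not hold;
assembly then still verifies its product and refuses with a report.

The default flank spacers (`GAATTC aaa AGATCT` / `GGATCC aaa CTCGAG`) are
read off the construction-primer tails bundled with the package; they are
arguments of `makePart` so a user following a different flank convention can
substitute exact sequences. The scar's Gly-Ser translation is standard-code
arithmetic on `GGATCT`, exposed as such.

## Site removal (domestication)

`proposeRemoval` enumerates all 18 single-base substitutions inside the
target hexamer and filters by three conditions: the site is destroyed, no
new forbidden site is created anywhere in the sequence, and — in CDS mode —
the annotated ORF's translation is unchanged. Coding proposals are ranked by
the relative synonymous-codon frequency of the new codon under a bundled
E. coli K-12 usage table (61 sense codons, frequencies normalized within
each amino acid; swappable for another organism). Noncoding proposals are
ranked by distance from annotated features (farther first, ties by position)
and carry an explicit "regulatory context — effect not modeled" flag: the
package makes no claim about promoter activity after such an edit. Only
single-base plans are generated; a site with no qualifying substitution is
reported "undomesticable" rather than escalated to multi-base edits.

The bundled mutagenesis QC primer pairs encode only the *mutant* sequence
(capitalized base = introduced mutation). The wild-type base is recovered by
requiring the named recognition site to exist at the capital position; the
verification report then checks reverse-complementarity of each pair, the
uniqueness of the capital difference, and that wild-type/mutant contain/lack
the site. The pBBR1 copy-up mutation is recorded strand-explicitly (A on the
printed forward strand) without guessing which strand a "C to T" phrasing
refers to.

## Primers and PCR simulation

Primer specificity is "exact match, unique occurrence" on the relevant
strand — no mismatch-tolerant annealing — so products are pure sequence
algebra: `tail + span + revcomp(tail)`, with origin-spanning amplicons
allowed on circular templates. Mutagenic pairs default to ~13-nt arms but
accept asymmetric `c(left, right)` arms, which is what reproduces the
printed pairs exactly (their capitals are roughly, not exactly, centered).
Melting temperature uses the Wallace rule below 14 nt and the simple GC
formula `64.9 + 41(GC − 16.4)/N` otherwise: deterministic, dependency-free,
and documented so it can be swapped; no thermodynamic nearest-neighbor model
is claimed. SOE fusion plans place mutual-revcomp inner primers across each
junction (default overlap half-width 15 nt), warn when an overlap picks up a
forbidden site or fails to cover a planned mutation, and their simulated
product is by construction the concatenation of the mutated segments with
the outer tails.

## The pBb module architecture and synthetic payloads

A vector is `AatII + expression + AvrII + origin + SacI + marker`, circular;
the expression payload is promoter region + `EcoRI aaa BglII` + RBS + gene +
`BamHI aaa XhoI` + terminator. Module swapping really runs the digestion/
ligation machinery (vector and a donor mini-circle digested at the two
boundary enzymes, backbone ligated to the donor's module fragment), and
cassette replacement excises the BglII–BamHI fragment of a full part, so
both junctions regenerate their sites — these operations are cross-checked
against direct textual assembly in the tests.

Full parent-plasmid sequences are not bundled. The module catalog ships
**synthetic placeholder payloads**: deterministic (fixed internal seed),
unique, length-realistic (origins ~1.2 kb, markers ~0.9 kb, promoter regions
~0.4 kb), scrubbed of all eight relevant sites *in their assembly context*
so no junction can form a stray site. Where a local mutation context is
evidenced by a printed primer (pSC101\*\* origin, kanamycin and
chloramphenicol markers, pBBR1 copy-up), the payload embeds that exact
window, and a pre-domestication wild-type variant is provided for the
site-removal demos. Real sequences imported from GenBank drop into the same
catalog structure. Promoter codes 2, 3/4, 5, 8 are pinned by documented
usage (Ptet, the two PprpB variants, PlacUV5, PBAD); the assignment of codes
1, 6, 7 to Ptrc, PLlacO-1, PT7 — and the Salmonella-vs-E. coli order of the
PprpB pair — could not be pinned from text alone, so it is an explicit
package default, overridable via the catalog, not an assertion about the
originals.

## Datasheet analytics

* **Specific fluorescence**: pointwise F/OD600 after optional medium-blank
  subtraction; wells below an OD floor (default 0.05) are masked, not
  divided, to avoid ratio blow-up. Blanking is off by default since the
  measurement protocol does not state it; both are config.
* **Dose response**: the summary uses the nearest measured timepoint to 18 h
  (570-s cadence keeps the offset under 285 s) with no interpolation or
  smoothing; mean ± sd over triplicates, no outlier rejection; both absolute
  and control-normalized values are emitted since figure bars could be read
  either way. The control condition (pBbE5a-RFP, 100 µM IPTG) is a config
  field because the protocol text gives 12.5 µM in one place and 100 µM in
  another; the default follows the normalization statement (100 µM).
* **Hill fit**: least squares on basal + span·cⁿ/(Kⁿ+cⁿ) with deterministic
  initialization (basal = min, span = max − min, K = geometric mean of the
  nonzero doses, n = 1), bounds span ≥ 0, K > 0, n ≥ 0.05;
  non-convergence returns diagnostics, never an exception.
* **Ratios**: crosstalk and repression are `100·(condition − reference) /
  reference` with the modified condition in the numerator role, so "20%
  less" reads −20 and a 1.4× enhancement reads +40. Both are invariant under
  common rescaling of raw fluorescence (gain invariance).
* **qPCR**: per-target standard curves (OLS of Ct on log10 Q over a
  four-fold, seven-dilution series) rather than the ΔΔCt shortcut; a
  positive slope raises a data-orientation error; quantities outside the
  calibrated Ct range are flagged as extrapolated. Copy number is the dual
  ratio of nptII to 16S quantities, sample over reference, so the reference
  strain is exactly 1 by construction.

## Synthetic-data generators

Every generator is a pure function of (parameters, seed) and restores the
caller's RNG state. The plate generator uses logistic growth (OD₀ = 0.1,
capacity 0.9, r = 1.6·10⁻⁴ s⁻¹ — saturating within a typical overnight
plate run), a Hill expression model whose output ramps linearly to its
plateau within 6 h and then holds it (so the noiseless 18-h plateau equals
the Hill value *exactly*, giving tests a sharp oracle), multiplicative
log-normal fluorescence noise (default sd 0.05, i.e. few-percent triplicate
CVs typical of plate assays), 570-s cadence over 20.5 h, triplicate wells,
and three control wells. A scalar `condition_factor` multiplies the
measurement wells to emulate a non-cognate-inducer or glucose condition with
a planted coefficient. The qPCR generator draws Ct = intercept −
log10(Q)/log10(1+E) + N(0, sd) per target, standards from reference-strain
DNA, unknowns diluted so they fall inside the calibrated range. Ground truth
rides alongside every dataset, so tests never re-derive truth from data.

What the generators do **not** emulate: growth-phase-dependent expression,
maturation kinetics of fluorophores, instrument gain drift, plasmid-burden
feedback on growth, inter-plasmid copy-number interactions, or pipetting
structure in the noise. Passing recovery tests therefore demonstrates that
the analytics invert the stated measurement model, not that they are robust
to every artifact of real plate data.

## Problem sizes and numerical choices in the test suite

The property suites run digest/re-ligate round trips on 1,000 random
circular sequences (80–200 bp, random enzyme subsets), assembly idempotence
and the length law on 1,000 random part pairs, and domestication-proposal
completeness against an exhaustive single-edit oracle on 200 random CDS
instances. The recovery studies use 100 seeds per planted copy number
{5, 10, 60} at Ct sd 0.1 (asserting the study mean within 10% — single runs
ride on four Ct measurements and scatter several times wider) and 100
replicates for Hill K at 5% noise (asserting every replicate within 20%).
Sequence fixtures are generated in code at test time; nothing binary ships
with the package.

## Known limitations

Only exact ACGT sequences; no methylation, star activity, or partial
digests; single-base domestication only; no primer secondary-structure or
dimer screening; no thermodynamic Tm model; no SBOL; synthetic payloads
stand in for deposited vector sequences, so absolute vector lengths are
realistic but not authentic; and the three-plasmid copy-number biology is
out of scope — only the quantification arithmetic is implemented.
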