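---
title: "neovax: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neovax: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

neovax implements the in-silico arm of a tandem-minigene mRNA cancer-vaccine
workflow: somatic variants expressed in transcript coordinates are applied to
coding sequences, mutant/wild-type 27-mer windows are extracted, candidates
are ranked by a multi-feature composite score, the top candidates are
assembled into a single mRNA construct, codons are chosen by a joint
folding-energy / codon-adaptation optimization, and the surrounding
bench arithmetic (lipopolyplex formulation, ELISpot responder calling,
tumor-burden summaries) is provided as closed-form functions. This vignette
records the models and every convention the package had to choose where the
underlying procedure is not fully public.

## Variant application and peptide windows

Variants are 1-based CDS-coordinate records with VCF-style anchor encoding
for indels (`ref = "G", alt = "GAT"` inserts `AT` after the anchor). Each
variant is applied independently; multi-variant phasing on one transcript is
not modeled because no phasing procedure is defined for this design. After
editing, both alleles are translated to the first stop codon and the
consequence is classified (synonymous, missense, in-frame indel, frameshift,
stop gain, stop loss, start loss). Only missense, in-frame indel, and
frameshift variants proceed: a stop gain or start loss leaves no mutant
residue to present.

The vaccine encodes 27-mer windows. For missense and in-frame indels the
window is centered on the (first) changed residue — 13 flanking residues per
side, mutant residue at position 14 — because a centered window maximizes
the number of mutation-spanning MHC-I (8–11-mer) and MHC-II (15-mer)
sub-peptides. Near a protein terminus the window is truncated, never padded.
For frameshifts, where everything downstream of the first changed residue is
novel, the window starts 13 residues upstream of the first changed residue
and runs toward the new stop, capped at 27; no wild-type counterpart exists.
The frameshift rule is this package's declared convention (the windowing of
indel-derived peptides is not specified in the underlying procedure) and is
flagged in the peptide TSV header.

## Ranking

For each candidate, all mutation-spanning 8–11-mers (class I) and 15-mers
(class II) are scored against every allele and the best (lowest) affinity is
kept; the wild-type best is computed over the aligned wild-type windows.
Binding prediction is a pluggable interface: external NetMHCpan-style TSV
output can be ingested, and a deterministic seeded position-weight-matrix toy
model (affinity `50000^(1 - s)` nM for the min-max-normalized PWM score `s`)
ships for tests and synthetic cohorts. Neural binding predictors are out of
scope by design.

Features are mapped to [0, 1] and combined linearly:

* mutant affinity: `max(0, 1 - log(aff) / log(50000))` (the standard
  "1 − log50k" transform);
* agretopicity (wild-type / mutant affinity): `min(1, log2(ratio + 1) / 4)`;
  frameshifts, having no wild-type, receive a configurable cap (default 16,
  which saturates the transform);
* expression (TPM), DNA VAF, RNA VAF, binding stability: min-max within the
  candidate pool; a feature constant across the pool contributes 0.5 for
  every candidate (documented degenerate-pool convention);
* immunogenicity: used as-is in [0, 1];
* germline VAF: contributes as one minus its normalized value;
* stability and immunogenicity default to a neutral 0.5 when no predictor
  output is supplied, keeping the total order well defined.

The published ranker's exact weights are proprietary, so the defaults here
(affinity 0.30, agretopicity 0.15, expression 0.15, RNA VAF 0.15, DNA VAF
0.10, stability 0.05, immunogenicity 0.05, germline absence 0.05) are this
package's own, clearly non-canonical, and fully configurable; linearity of
the composite is likewise a declared choice. Hard filters follow common
field practice (germline VAF ≤ 0.02, tumor-DNA VAF ≥ 0.05, expression ≥ 1
TPM, best mutant affinity ≤ 500 nM) and every exclusion is reported with the
violated threshold. Survivors are sorted by score with a fully deterministic
tie-break: higher tumor-DNA VAF, then lower mutant affinity, then
lexicographically smaller peptide. The default selection size is 20.

## Construct architecture

The open reading frame is `SP – linker – neo1 – linker – … – linker – MITD`,
with the start and middle linkers both `GGSGGGGSGG` and the distinct end
linker `GGSLGGGGSG` preceding the MITD — the only reading consistent with
that segment pattern. The signal peptide, MITD, 5'UTR (beginning `AG` for
capping and ending in the Kozak `GCCACC` immediately before the AUG), the
alpha-globin-derived 3'UTR, and the 75-nt polyA tail are stored verbatim as
package constants, all overridable. Because an ORF must terminate before the
3'UTR and no stop codon is stated for the original constructs, a single UAA
(lowest read-through) is appended after the MITD; this is flagged in output
metadata. Sequences are emitted as RNA (AUGC); the N1-methylpseudouridine
substitution for U is recorded as metadata only. All coordinates are 1-based
inclusive and the region map tiles the sequence exactly.

## Codon design

The design objective is

```
minimize  fold(s) - lambda * sum_i log w(codon_i)
```

over all codon choices `s` encoding the peptide, where `w` is the relative
adaptiveness from a Kazusa-style codon usage table (so the second term is
`-lambda * n * log CAI`). The folding term is a Nussinov pair-score model
(GC/CG −2, AU/UA −1, GU/UG −0.5, minimum hairpin 3) rather than
nearest-neighbor thermodynamics: the substitution is deliberate and loud.
A pair-score model admits an exhaustive oracle — every structure of a short
sequence can be enumerated, and every codon combination of a short peptide
scored — so both dynamic programs in the package are verifiable end to end.
The energy model is an interface; a nearest-neighbor scorer can be plugged
in to re-score designed sequences but not to drive the DP.

The optimizer is a lattice dynamic program: each sequence position carries
the codon-automaton states (distinct codon prefixes of the residue's
synonymous codons), transitions are labelled with nucleotides and carry the
`-lambda log w` cost on codon completion, and the Nussinov recursion runs
over state-annotated spans. Up to 300 coding nucleotides (100 residues) the
optimum is exact. Longer ORFs are designed in overlapping windows (60 codons,
20-codon overlap) stitched at codon boundaries and re-scored globally; the
result is flagged `windowed` and is approximate — the exact mode remains
available and is what the oracle tests exercise. `lambda` defaults to 1.0
(the value used for the original vaccine constructs is not public) and only
the ORF is folded by default. Ties on the objective are broken toward higher
CAI as a secondary DP criterion; residual ties resolve through a fixed
deterministic traceback order (A<C<G<U, unpaired before paired, leftmost
split), which guarantees reproducibility though not a provably
lexicographically-minimal sequence — lexicographic minimality does not
compose across interval-DP concatenation without storing whole subsequences.

Numerical choices: DP cell comparisons use an absolute tolerance of 1e-9,
traceback re-derivation 1e-7; empty sequences fold to 0; the folding score
is never positive.

## Formulation, ELISpot, and tumor summaries

The lipopolyplex recipe is pure stoichiometry: phosphate moles = mRNA mass /
mean nucleotide molar mass (default 330 g/mol); ionizable-lipid moles = N:P
(4.8) × phosphate moles / amines per lipid (default 1); DOPE, cholesterol,
and mPEG-DMG scale from the ionizable lipid's 40 mol% by the 40 : 15 : 43.5
: 1.5 fractions; masses follow by molar mass. The ionizable lipid is
proprietary and unnamed, so its molar mass is a required configuration field
(tests use a 710 g/mol fixture); the round-trip invariants — mole fractions
and N:P recomputed from emitted masses equal the configured values to 1e-9
relative — are independent of any molar-mass choice. Volumes derive from the
working mRNA concentration and the 5:1 (mRNA:protamine, v/v) and 3:1
(aqueous:ethanol) mixing ratios.

ELISpot responder calling subtracts the group's negative-control mean
(floored at zero) and calls a responder when the peptide mean is at least
2× the negative mean **and** the normalized count is at least 10 spots per
well. The original study does not state its responder definition; this
2×/10 rule is a standard ELISpot convention, configurable, and echoed in
the output. Tumor volume is `1/2 × length × width²` (widths exceeding
lengths are swapped with a warning) and TGI is `100 × (1 − treated/control)`
on group means of the final measurement; growth-inhibition percentages from
figure-derived volumes are deliberately not reproduced.

## The synthetic cohort generator

`generate_cohort()` stands in for exome plus RNA sequencing of a tumor line.
It emits transcripts (120–400 codons, log-normal TPM), somatic SNVs and
small anchored indels (tumor VAF uniform on 0.05–0.6, germline VAF 0, RNA
VAF tracking DNA VAF with Gaussian noise, SD 0.08), an optional germline
contaminant fraction (VAF ≈ 0.5 in both compartments, caught by the
germline filter), and a configurable synonymous fraction (default 0.2).
"Planted" strong neoantigens — used for recovery testing — get a PWM
consensus 9-mer embedded around the mutant residue, tumor VAF 0.4–0.6, and
50 TPM. These choices are fixed study conditions, not tuning knobs.

What the generator does **not** emulate: linked variants and phasing,
splice or fusion neoantigens, expression measurement noise, alignment and
calling artifacts, HLA typing uncertainty, and real binding-affinity
landscapes (the toy PWM is smooth and unimodal where real predictors are
not). Passing tests therefore demonstrate the pipeline's arithmetic,
invariants, and ranking behavior under controlled conditions — not clinical
prediction accuracy on real tumors.

## Problem sizes and limitations

The test suite exercises exact codon design up to 4 residues against full
enumeration (200 random peptides), folding up to 12 nt against full
structure enumeration, ranking properties over 100 seeded cohorts, and
planted-candidate recovery over 10 cohorts of 35 variants; the end-to-end
pipeline tests run 10–12 transcript cohorts with the fast max-CAI codon
source, sizes chosen so the whole suite completes in a few minutes on one
CPU. Known limitations: the folding proxy ignores stacking, loop entropies,
and pseudoknots; windowed design is approximate; the toy binding model is
not a predictor of real immunogenicity; "evaluable" neoantigen status in
reported precision rates is an experimental designation the software cannot
derive, so responder rates are computed from user-supplied counts.
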