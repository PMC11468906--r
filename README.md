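# neovax

Design toolkit for tandem-minigene mRNA cancer vaccines. Given a tumor's
somatic variants (in transcript CDS coordinates), transcript expression, and
MHC alleles, `neovax`:

1. applies each variant, translates, and extracts the mutant/wild-type
   **27-mer** window around the changed residue (13 + 1 + 13, truncated at
   protein termini);
2. scores every mutation-spanning 8–11-mer (MHC-I) and 15-mer (MHC-II)
   sub-peptide, builds a feature vector per candidate — tumor/germline/RNA
   variant allele frequencies, expression, best mutant and wild-type
   peptide–MHC affinities, agretopicity, binding stability, immunogenicity —
   and ranks candidates by a configurable linear composite score, selecting
   the top 20 by default;
3. assembles the vaccine mRNA
   `5'UTR — SP — linker — neo1 — linker — … — linker — MITD — stop — 3'UTR — polyA(75)`
   with the construct's exact sequence constants and a coordinate-annotated
   region map;
4. chooses codons by jointly minimizing a folding-energy proxy and
   maximizing the codon adaptation index,

   minimize over synonymous choices:  `fold(s) − λ · Σᵢ log w(codonᵢ)`

   via an exact lattice dynamic program (Nussinov recursion over
   codon-automaton states; exhaustively verifiable, windowed above 300 nt);
5. provides the surrounding bench arithmetic: lipopolyplex formulation
   (N:P 4.8, lipid mole fractions 40 : 15 : 43.5 : 1.5, 5:1 mRNA:protamine
   v/v, 3:1 aqueous:ethanol), ELISpot responder calling with exact binomial
   confidence intervals, and tumor-volume / growth-inhibition summaries.

A seeded synthetic-cohort generator produces all inputs with the real file
structure (CDS FASTA, variant/expression TSV, allele list), so the entire
pipeline is testable without any external data or predictors. External
NetMHCpan-style binding tables plug in where the bundled toy PWM model is
not wanted. See `vignettes/neovax-methods.Rmd` for every model and
convention, including which choices are this package's own.

## Worked example

```r
library(neovax)

cfg <- run_config(out_dir = "readme_run", seed = 42, n_transcripts = 15,
                  n_variants = 20, cohort = list(n_planted = 5),
                  top_n = 5, codon_method = "design")
res <- run_design(cfg)

res$ranking$selected[1:3, c("id", "mut_peptide", "composite_score", "rank")]
#>             id                 mut_peptide composite_score rank
#>  T0002:100:A>G STLLRGMTTHRERENRSYGRIATPCLY       0.6964986    1
#>  T0004:100:A>G LLGNSYSIRHRERENRSYKVCWNPNPS       0.6722496    2
#>  T0003:100:A>G NYECSISLSHRERENRSYELLGANGGS       0.6686855    3

res$design_metrics
#>       mode mfe_proxy       cai lambda objective orf_aa_len
#> 1 windowed    -599.5 0.9403422      1 -582.5844        275

nchar(res$construct$rna_sequence)   # 1061 nt
res$construct$regions[1:3, ]
#>           name start end
#> 1         utr5     1  64
#> 2           SP    65 142
#> 3 linker_start   143 172
```

The five selected 27-mers (each carrying its mutation at position 14) are
concatenated into a 275-aa ORF behind the signal peptide and ahead of the
MITD; the designed mRNA folds to a proxy energy of −599.5 with CAI 0.94,
and the full construct is 1061 nt including the 64-nt 5'UTR and the 75-nt
polyA tail. Every output (ranked candidates, attrition log, construct
FASTA/GenBank/region TSV, design metrics, formulation recipe, manifest) is
written under `out_dir`, and `replay_manifest()` reproduces the run
byte-for-byte.

Single functions work standalone:

```r
u <- read_codon_usage()
d <- design("MSIINFEKLT", u, lambda = 1)
d$rna_codons   # "AUGAGCAUCAUCAACUUCGAGAAGCUCACU"
d$mfe_proxy    # -16
d$cai          # 0.8996

r <- lpp_check_recipe(lpp_recipe(100, lpp_config(ionizable_mw = 710)))
r$mole_fractions[["cholesterol"]]   # 43.5
r$np_ratio                          # 4.8

responder_rate(10, 19)$percent      # 52.6  (95% CI 28.9–75.6)
```

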