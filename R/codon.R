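#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over the codons of a
#' coding sequence: `CAI = (prod w_i)^(1/n)`, in `(0, 1]`. A sequence made of
#' each amino acid's most-used synonym has CAI 1.
#'
#' @param rna_codons coding nucleotide string (RNA or DNA), length divisible
#'   by 3, no stop codons.
#' @param usage a `codon_usage` table from [read_codon_usage()].
#' @return CAI value.
#' @export
#' @examples
#' u <- read_codon_usage()
#' cai("AUG", u)  # 1: AUG is Met's only codon
cai <- function(rna_codons, usage = read_codon_usage()) {
  codons <- dna_to_rna(codon_split(rna_codons))
  if (nchar(rna_codons) %% 3L != 0L)
    stop("sequence length not divisible by 3", call. = FALSE)
  if (length(codons) == 0L) stop("empty sequence", call. = FALSE)
  w <- usage$w[match(codons, usage$codon)]
  if (anyNA(w))
    stop("codon absent from usage table (stop codon?): ",
         codons[which(is.na(w))[1]], call. = FALSE)
  exp(mean(log(w)))
}

# per-codon log relative adaptiveness, in usage-table order
.logw_lookup <- function(codons, usage) {
  w <- usage$w[match(dna_to_rna(codons), usage$codon)]
  if (anyNA(w)) stop("codon absent from usage table", call. = FALSE)
  log(w)
}

#' Naive maximum-CAI reverse translation
#'
#' Each residue gets its amino acid's most-used codon (`w = 1`); ties go to
#' the alphabetically first codon. This is the pure-CAI limit of [design()]
#' and the fast default codon source for construct assembly.
#'
#' @param peptide amino-acid string (canonical residues).
#' @param usage a `codon_usage` table.
#' @return RNA string of length `3 * nchar(peptide)`.
#' @export
reverse_translate_max_cai <- function(peptide, usage = read_codon_usage()) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (!all(aa %in% AA_CANONICAL))
    stop("non-canonical residue in peptide: ",
         paste(setdiff(aa, AA_CANONICAL), collapse = ","), call. = FALSE)
  # usage table is sorted by (amino_acid, codon); first w==1 row per aa is
  # the alphabetically smallest top codon
  top <- usage[usage$w == 1, ]
  best <- setNames(top$codon[!duplicated(top$amino_acid)],
                   top$amino_acid[!duplicated(top$amino_acid)])
  paste(best[aa], collapse = "")
}

#' Codons available for each residue of a peptide
#'
#' @param peptide amino-acid string.
#' @param usage a `codon_usage` table.
#' @return list (one element per residue) of data.frames `codon`, `w`.
#' @keywords internal
codon_choices <- function(peptide, usage) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (!all(aa %in% AA_CANONICAL))
    stop("residue with no codons in the table: ",
         paste(setdiff(aa, AA_CANONICAL), collapse = ","), call. = FALSE)
  lapply(aa, function(a) {
    u <- usage[usage$amino_acid == a, c("codon", "w")]
    rownames(u) <- NULL
    u
  })
}
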