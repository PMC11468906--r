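#' Split a nucleotide string into codons
#'
#' Trailing bases that do not complete a codon are dropped.
#'
#' @param x single nucleotide string (DNA or RNA).
#' @return character vector of 3-letter codons.
#' @keywords internal
codon_split <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code (via [Biostrings::GENETIC_CODE]). DNA or RNA input is
#' accepted; translation runs codon by codon and, by default, stops at the
#' first stop codon.
#'
#' @param x nucleotide string; a trailing partial codon is ignored.
#' @param to_first_stop stop translating at the first stop codon (default).
#' @return amino-acid string (stop not included), with attribute
#'   `stop_found` (logical) indicating whether a stop codon terminated it.
#' @export
#' @examples
#' translate_nt("ATGGCTTAA")  # "MA"
translate_nt <- function(x, to_first_stop = TRUE) {
  codons <- rna_to_dna(codon_split(x))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (anyNA(aa)) {
    bad <- codons[which(is.na(aa))[1]]
    stop("untranslatable codon '", bad, "' (non-ACGT base?)", call. = FALSE)
  }
  stop_at <- which(aa == "*")
  stop_found <- length(stop_at) > 0L
  if (to_first_stop && stop_found) aa <- aa[seq_len(stop_at[1] - 1L)]
  out <- paste(aa[aa != "*"], collapse = "")
  attr(out, "stop_found") <- stop_found
  out
}

#' Validate a coding sequence
#'
#' A well-formed CDS has length divisible by 3, begins with ATG, and contains
#' exactly one in-frame stop codon, located at its end.
#'
#' @param cds DNA string.
#' @param id identifier used in error messages.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_cds <- function(cds, id = "<cds>") {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop("CDS of '", id, "' contains non-ACGT characters", call. = FALSE)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS of '", id, "' has length ", nchar(cds),
         ", not divisible by 3", call. = FALSE)
  codons <- codon_split(cds)
  if (codons[1] != "ATG")
    stop("CDS of '", id, "' does not begin with ATG", call. = FALSE)
  gc <- Biostrings::GENETIC_CODE
  stops <- which(unname(gc[codons]) == "*")
  if (length(stops) != 1L || stops != length(codons))
    stop("CDS of '", id,
         "' must contain exactly one in-frame stop codon, at its end",
         call. = FALSE)
  invisible(TRUE)
}
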