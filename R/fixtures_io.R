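#' Read coding sequences from a FASTA file
#'
#' Headers carry the transcript identifier as the first whitespace token,
#' optionally followed by `key=value` fields `gene_id` and `tpm`, e.g.
#' `>T1 gene_id=G1 tpm=12.5`.
#'
#' @param path FASTA file of CDS sequences (DNA alphabet).
#' @param validate check CDS invariants (start codon, frame, single terminal
#'   stop); default `TRUE`.
#' @return data.frame with columns `transcript_id`, `cds`, `gene_id`, `tpm`,
#'   in file order.
#' @export
read_cds_fasta <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA at line 1 of ", path,
         ": expected a '>' header", call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  headers <- names(set)
  parse_header <- function(h) {
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    kv <- toks[-1][grepl("=", toks[-1], fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    list(id = toks[1],
         gene_id = if ("gene_id" %in% keys) vals[keys == "gene_id"][1] else NA_character_,
         tpm = if ("tpm" %in% keys) as.numeric(vals[keys == "tpm"][1]) else NA_real_)
  }
  parsed <- lapply(headers, parse_header)
  out <- data.frame(
    transcript_id = vapply(parsed, `[[`, "", "id"),
    cds = as.character(set),
    gene_id = vapply(parsed, `[[`, "", "gene_id"),
    tpm = vapply(parsed, `[[`, 0, "tpm"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (validate) validate_transcripts(out)
  out
}

#' Write coding sequences to FASTA
#'
#' @param transcripts data.frame as returned by [read_cds_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(transcripts$cds)
  hdr <- transcripts$transcript_id
  has_gene <- !is.na(transcripts$gene_id)
  hdr[has_gene] <- paste0(hdr[has_gene], " gene_id=", transcripts$gene_id[has_gene])
  has_tpm <- !is.na(transcripts$tpm)
  hdr[has_tpm] <- paste0(hdr[has_tpm], " tpm=",
                         format(transcripts$tpm[has_tpm], digits = 15, trim = TRUE,
                                scientific = FALSE))
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a transcript table
#'
#' @param transcripts data.frame with `transcript_id`, `cds`, `gene_id`, `tpm`.
#' @return invisibly `TRUE`.
#' @export
validate_transcripts <- function(transcripts) {
  need <- c("transcript_id", "cds", "gene_id", "tpm")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("transcript table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id values", call. = FALSE)
  for (i in seq_len(nrow(transcripts))) {
    validate_cds(transcripts$cds[i], transcripts$transcript_id[i])
    tpm <- transcripts$tpm[i]
    if (!is.na(tpm) && tpm < 0)
      stop("tpm of '", transcripts$transcript_id[i], "' is negative",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a somatic variant table
#'
#' Tab-separated with header columns `transcript_id`, `cds_pos`, `ref`, `alt`,
#' `vaf_tumor_dna`, `vaf_normal_dna`, `vaf_tumor_rna`. Coordinates are 1-based
#' positions within the CDS; indels use a VCF-style shared anchor base
#' (ref `G`, alt `GAT` is an insertion of `AT` after the anchor).
#'
#' @param path TSV file.
#' @param transcripts optional transcript table; when given, each `ref` is
#'   cross-checked against the CDS.
#' @return validated data.frame of variants.
#' @export
read_variant_table <- function(path, transcripts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(
    transcript_id = "character", ref = "character", alt = "character"))
  validate_variants(v, transcripts)
  v
}

#' Write a variant table as TSV
#' @param variants variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a variant table
#'
#' @inheritParams read_variant_table
#' @param variants data.frame of variants.
#' @return invisibly `TRUE`.
#' @export
validate_variants <- function(variants, transcripts = NULL) {
  need <- c("transcript_id", "cds_pos", "ref", "alt",
            "vaf_tumor_dna", "vaf_normal_dna", "vaf_tumor_rna")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    where <- paste0(v$transcript_id, ":", v$cds_pos)
    if (v$cds_pos < 1) stop("cds_pos < 1 at ", where, call. = FALSE)
    if (identical(v$ref, v$alt)) stop("ref equals alt at ", where, call. = FALSE)
    if (grepl("[^ACGT]", v$ref) || grepl("[^ACGT]", v$alt))
      stop("non-ACGT allele at ", where, call. = FALSE)
    for (f in c("vaf_tumor_dna", "vaf_normal_dna", "vaf_tumor_rna")) {
      val <- v[[f]]
      if (is.na(val) || val < 0 || val > 1)
        stop(f, " = ", val, " outside [0,1] at ", where, call. = FALSE)
    }
    if (!is.null(transcripts)) {
      j <- match(v$transcript_id, transcripts$transcript_id)
      if (is.na(j)) stop("unknown transcript '", v$transcript_id, "'",
                         call. = FALSE)
      cds <- transcripts$cds[j]
      if (v$cds_pos + nchar(v$ref) - 1L > nchar(cds))
        stop("variant at ", where, " extends past CDS end", call. = FALSE)
      obs <- substr(cds, v$cds_pos, v$cds_pos + nchar(v$ref) - 1L)
      if (obs != v$ref)
        stop("ref mismatch at ", where, ": table says '", v$ref,
             "', CDS has '", obs, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read / write an expression table (transcript and gene TPM)
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, `tpm`.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "tpm")
  miss <- setdiff(need, names(e))
  if (length(miss)) stop("expression table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(e$tpm < 0)) stop("negative tpm in expression table", call. = FALSE)
  e
}

#' @rdname read_expression_table
#' @param expression expression data.frame.
#' @export
write_expression_table <- function(expression, path) {
  write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an MHC allele list (one opaque label per line)
#'
#' @param path text file, e.g. lines `H-2-Kb`, `HLA-A*02:01`.
#' @return character vector of allele labels.
#' @export
read_hla_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_hla_list
#' @param alleles character vector of allele labels.
#' @export
write_hla_list <- function(alleles, path) {
  writeLines(alleles, path)
  invisible(path)
}

#' Read a codon usage table
#'
#' Kazusa-style TSV with columns `codon` (DNA or RNA alphabet), `amino_acid`
#' (one-letter, `*` for stop), and `fraction` (usage fraction among synonymous
#' codons). Stop codons are accepted and ignored. Per amino acid the relative
#' adaptiveness `w = fraction / max(fraction)` is added; the most-used synonym
#' of each amino acid has `w = 1`.
#'
#' @param path TSV file; default is the bundled human codon usage table.
#' @return data.frame of 61 sense codons with columns `codon` (RNA alphabet),
#'   `amino_acid`, `fraction`, `w`, of class `codon_usage`.
#' @export
read_codon_usage <- function(path = system.file("extdata",
                                                "codon_usage_human.tsv",
                                                package = "neovax")) {
  u <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "amino_acid", "fraction")
  miss <- setdiff(need, names(u))
  if (length(miss)) stop("codon usage table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  u$codon <- dna_to_rna(u$codon)
  u <- u[u$amino_acid != "*", , drop = FALSE]
  if (nrow(u) != 61L || anyDuplicated(u$codon))
    stop("codon usage table must list the 61 sense codons exactly once (got ",
         nrow(u), ")", call. = FALSE)
  gc <- Biostrings::GENETIC_CODE
  expect_aa <- unname(gc[rna_to_dna(u$codon)])
  if (!all(u$amino_acid == expect_aa))
    stop("codon/amino-acid assignment disagrees with the standard code at ",
         u$codon[which(u$amino_acid != expect_aa)[1]], call. = FALSE)
  sums <- tapply(u$fraction, u$amino_acid, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("usage fractions per amino acid must sum to 1 (off at ",
         names(sums)[which.max(abs(sums - 1))], ")", call. = FALSE)
  wmax <- tapply(u$fraction, u$amino_acid, max)
  u$w <- u$fraction / unname(wmax[u$amino_acid])
  u <- u[order(u$amino_acid, u$codon), , drop = FALSE]
  rownames(u) <- NULL
  class(u) <- c("codon_usage", "data.frame")
  u
}

#' Read / write an ELISpot count table
#'
#' TSV columns: `group`, `peptide_id`, `replicate`, `spot_count`,
#' `cells_per_well`, `is_negative_control`, `is_positive_control`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_elispot <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "peptide_id", "replicate", "spot_count",
            "cells_per_well", "is_negative_control", "is_positive_control")
  miss <- setdiff(need, names(e))
  if (length(miss)) stop("ELISpot table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  e$is_negative_control <- as.logical(e$is_negative_control)
  e$is_positive_control <- as.logical(e$is_positive_control)
  if (any(e$spot_count < 0)) stop("negative spot_count", call. = FALSE)
  for (g in unique(e$group))
    if (!any(e$is_negative_control[e$group == g]))
      stop("group '", g, "' has no negative-control row", call. = FALSE)
  e
}

#' @rdname read_elispot
#' @param elispot ELISpot data.frame.
#' @export
write_elispot <- function(elispot, path) {
  write.table(elispot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
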