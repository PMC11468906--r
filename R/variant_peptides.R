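#' Apply a somatic variant to a coding sequence and translate
#'
#' Edits the CDS at the variant's 1-based position (VCF-style anchor encoding
#' for indels), translates both alleles to the first stop codon, and
#' classifies the protein-level consequence.
#'
#' @param transcript one-row transcript data.frame (or list) with
#'   `transcript_id` and `cds`.
#' @param variant one-row variant data.frame (or list) with `cds_pos`, `ref`,
#'   `alt`.
#' @return list of class `mutant_protein`: `transcript_id`, `wt_protein`,
#'   `mut_protein`, `first_changed_residue` (NA for synonymous),
#'   `variant_class` in `synonymous`, `missense`, `inframe_indel`,
#'   `frameshift`, `stop_gain`, `start_loss`, `stop_loss`, plus the `variant`
#'   row. Only missense, in-frame indel, and frameshift variants go on to
#'   peptide extraction; the other classes are excluded from vaccine design.
#' @export
#' @examples
#' tx <- list(transcript_id = "T1", cds = "ATGGCTGATTAA")
#' v  <- list(cds_pos = 4, ref = "G", alt = "A")
#' apply_variant(tx, v)$variant_class  # missense: MAD -> MTD
apply_variant <- function(transcript, variant) {
  cds <- toupper(transcript$cds)
  pos <- as.integer(variant$cds_pos)
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  if (pos < 1L || pos + nchar(ref) - 1L > nchar(cds))
    stop("variant at ", transcript$transcript_id, ":", pos,
         " lies outside the CDS", call. = FALSE)
  obs <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("ref mismatch at ", transcript$transcript_id, ":", pos,
         ": expected '", ref, "', CDS has '", obs, "'", call. = FALSE)

  edited <- paste0(substr(cds, 1L, pos - 1L), alt,
                   substr(cds, pos + nchar(ref), nchar(cds)))

  wt <- translate_nt(cds)
  if (substr(edited, 1L, 3L) != "ATG") {
    res <- list(transcript_id = transcript$transcript_id,
                wt_protein = as.character(wt), mut_protein = "",
                first_changed_residue = 1L, variant_class = "start_loss",
                variant = variant)
    class(res) <- "mutant_protein"
    return(res)
  }
  mut <- translate_nt(edited)
  wt_s <- as.character(wt); mut_s <- as.character(mut)

  frameshift <- (nchar(ref) - nchar(alt)) %% 3L != 0L
  # first residue at which the proteins differ
  n <- min(nchar(wt_s), nchar(mut_s))
  wt_v <- strsplit(wt_s, "")[[1]]; mut_v <- strsplit(mut_s, "")[[1]]
  diff_at <- which(wt_v[seq_len(n)] != mut_v[seq_len(n)])
  first_changed <- if (length(diff_at)) diff_at[1]
                   else if (nchar(wt_s) != nchar(mut_s)) n + 1L
                   else NA_integer_

  cls <- if (is.na(first_changed)) "synonymous"
    else if (frameshift) "frameshift"
    else if (nchar(ref) != nchar(alt)) "inframe_indel"
    else if (nchar(mut_s) < nchar(wt_s)) "stop_gain"   # SNV created a stop
    else if (nchar(mut_s) > nchar(wt_s)) "stop_loss"   # SNV removed the stop
    else "missense"

  res <- list(transcript_id = transcript$transcript_id,
              wt_protein = wt_s, mut_protein = mut_s,
              first_changed_residue = first_changed,
              variant_class = cls, variant = variant)
  class(res) <- "mutant_protein"
  res
}

#' Extract the mutant/wild-type peptide window around a variant
#'
#' For missense and in-frame indels the window is centered on the (first)
#' mutant residue: 13 flanking residues on each side, so an interior mutation
#' gives a 27-mer with the mutant residue at position 14; near a terminus the
#' window is truncated, never padded. For frameshifts the window starts 13
#' residues upstream of the first changed residue and runs toward the new
#' stop, capped at 27 residues; no wild-type counterpart is reported.
#'
#' @param mp a `mutant_protein` from [apply_variant()].
#' @param window maximal peptide length (default 27).
#' @return list of class `peptide_pair`: `mut_peptide`, `wt_peptide` (NA for
#'   frameshift), `window_start` (1-based residue in the mutant protein),
#'   `mutant_offset` (1-based position of the first altered residue within the
#'   peptide), `variant_class`.
#' @export
extract_peptide_pair <- function(mp, window = 27L) {
  if (!mp$variant_class %in% c("missense", "inframe_indel", "frameshift"))
    stop("no neoantigen: variant class is ", mp$variant_class, call. = FALSE)
  flank <- (window - 1L) %/% 2L
  m <- mp$first_changed_residue
  len <- nchar(mp$mut_protein)
  if (m > len)
    stop("no neoantigen: mutant protein ends before the changed residue",
         call. = FALSE)
  if (mp$variant_class == "frameshift") {
    start <- max(1L, m - flank)
    end <- min(len, start + window - 1L)
    wt_pep <- NA_character_
  } else {
    start <- max(1L, m - flank)
    end <- min(len, m + flank)
    wt_pep <- substr(mp$wt_protein, start, min(nchar(mp$wt_protein), end))
  }
  res <- list(mut_peptide = substr(mp$mut_protein, start, end),
              wt_peptide = wt_pep,
              window_start = start,
              mutant_offset = m - start + 1L,
              variant_class = mp$variant_class)
  class(res) <- "peptide_pair"
  res
}

#' Candidate peptides for a whole cohort
#'
#' Applies every variant to its transcript, drops synonymous, stop-gain, and
#' start-loss variants, and extracts the peptide window for the rest. Variant
#' identifiers are keyed `transcript_id:cds_pos:ref>alt`.
#'
#' @param transcripts transcript data.frame.
#' @param variants variant data.frame.
#' @param window maximal peptide length (default 27).
#' @return data.frame with one row per usable variant: `id`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt`, `variant_class`, `mut_peptide`, `wt_peptide`,
#'   `window_start`, `mutant_offset`, and the three VAF columns.
#' @export
peptides_from_cohort <- function(transcripts, variants, window = 27L) {
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tx <- transcripts[match(v$transcript_id, transcripts$transcript_id), ]
    if (is.na(tx$transcript_id[1]))
      stop("unknown transcript '", v$transcript_id, "'", call. = FALSE)
    mp <- apply_variant(tx, v)
    if (!mp$variant_class %in% c("missense", "inframe_indel", "frameshift"))
      next
    # a variant whose new reading frame stops before the first changed
    # residue leaves nothing mutant to present; skip it like a stop gain
    if (mp$first_changed_residue > nchar(mp$mut_protein)) next
    pp <- extract_peptide_pair(mp, window)
    rows[[i]] <- data.frame(
      id = paste0(v$transcript_id, ":", v$cds_pos, ":", v$ref, ">", v$alt),
      transcript_id = v$transcript_id, cds_pos = v$cds_pos,
      ref = v$ref, alt = v$alt,
      variant_class = mp$variant_class,
      mut_peptide = pp$mut_peptide, wt_peptide = pp$wt_peptide,
      window_start = pp$window_start, mutant_offset = pp$mutant_offset,
      vaf_tumor_dna = v$vaf_tumor_dna, vaf_normal_dna = v$vaf_normal_dna,
      vaf_tumor_rna = v$vaf_tumor_rna,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Write candidate peptides as FASTA and TSV
#'
#' `*_mut.fasta` and `*_wt.fasta` hold the mutant and wild-type windows
#' (frameshift rows have no wild-type entry); the TSV carries window
#' coordinates and metadata. Frameshift windowing is a declared convention of
#' this package, recorded in the TSV header comment.
#'
#' @param peptides data.frame from [peptides_from_cohort()].
#' @param prefix output path prefix.
#' @return named vector of paths, invisibly.
#' @export
write_peptides <- function(peptides, prefix) {
  paths <- c(mut = paste0(prefix, "_mut.fasta"),
             wt = paste0(prefix, "_wt.fasta"),
             tsv = paste0(prefix, ".tsv"))
  mut <- Biostrings::AAStringSet(setNames(peptides$mut_peptide, peptides$id))
  Biostrings::writeXStringSet(mut, paths["mut"])
  has_wt <- !is.na(peptides$wt_peptide)
  wt <- Biostrings::AAStringSet(setNames(peptides$wt_peptide[has_wt],
                                         peptides$id[has_wt]))
  Biostrings::writeXStringSet(wt, paths["wt"])
  con <- file(paths["tsv"], "w")
  writeLines(paste0("# neovax peptide windows; coordinates 1-based inclusive; ",
                    "frameshift windows use the package's declared convention ",
                    "(13 residues upstream of the first changed residue, ",
                    "capped at the window length)"), con)
  write.table(peptides, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
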