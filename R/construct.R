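#' Constants of the tandem-minigene vaccine construct
#'
#' The fixed parts of the mRNA: the signal peptide (SP) routing the
#' polypeptide into the secretory pathway, the flexible glycine-serine
#' linkers separating neoantigen segments, the MHC class I trafficking
#' signal domain (MITD) appended at the C terminus, the 5' UTR (beginning
#' `AG`, required for capping, and ending in the Kozak hexamer `GCCACC`),
#' the alpha-globin-derived 3' UTR, and a 75-nt polyA tail. The open reading
#' frame is `SP - linker - neo1 - linker - neo2 - ... - linker - MITD`. A
#' single UAA stop codon is appended after the MITD; the stop codon is a
#' package convention (configurable) and is flagged in output metadata.
#'
#' @param sp_aa signal peptide (amino acids).
#' @param start_linker,middle_linker,end_linker linker segments (amino acids);
#'   the start linker sits between SP and the first neoantigen, the end linker
#'   before the MITD.
#' @param mitd_aa MITD segment (amino acids).
#' @param utr5_rna,utr3_rna untranslated regions (RNA alphabet).
#' @param polya_len polyA tail length in nt (default 75).
#' @param stop_codon stop codon appended after the MITD (default `UAA`).
#' @return list of class `construct_spec`.
#' @export
construct_spec <- function(
    sp_aa = "MRVTAPRTLILLLSGALALTETWAGS",
    start_linker = "GGSGGGGSGG",
    middle_linker = "GGSGGGGSGG",
    end_linker = "GGSLGGGGSG",
    mitd_aa = "VGIVAGLAVLAVVVIGAVVATVMCRRKSSGGKGGSYSQAASSDSAQGSDVSLTA",
    utr5_rna = "AGGAAAUUCCAUUUGGCUGCAGCUUCUGGAGGGAGCCGACAGGAGACGUGGGGAGACGGCCACC",
    utr3_rna = paste0("GCUGCCUUCUGCGGGGCUUGCCUUCUGGCCAUGCCCUUCUUCUCUCCCUUGCA",
                      "CCUGUACCUCUUGGUCUUUGAAUAAAGCCUGAGUAGGAAGU"),
    polya_len = 75L,
    stop_codon = "UAA") {
  utr5_rna <- dna_to_rna(utr5_rna); utr3_rna <- dna_to_rna(utr3_rna)
  if (!startsWith(utr5_rna, "AG"))
    stop("5'UTR must begin with AG (capping requirement)", call. = FALSE)
  if (!endsWith(utr5_rna, "GCCACC"))
    stop("5'UTR must end with the Kozak hexamer GCCACC", call. = FALSE)
  if (polya_len <= 0L) stop("polya_len must be positive", call. = FALSE)
  if (!dna_to_rna(stop_codon) %in% c("UAA", "UAG", "UGA"))
    stop("stop_codon must be a stop codon", call. = FALSE)
  structure(list(sp_aa = sp_aa, start_linker = start_linker,
                 middle_linker = middle_linker, end_linker = end_linker,
                 mitd_aa = mitd_aa, utr5_rna = utr5_rna, utr3_rna = utr3_rna,
                 polya_len = as.integer(polya_len),
                 stop_codon = dna_to_rna(stop_codon)),
            class = "construct_spec")
}

.check_aa <- function(x, what) {
  bad <- setdiff(strsplit(toupper(x), "")[[1]], AA_CANONICAL)
  if (length(bad))
    stop("non-canonical residue ", paste(bad, collapse = ","), " in ", what,
         call. = FALSE)
  invisible(TRUE)
}

#' Assemble the tandem-minigene open reading frame
#'
#' Concatenates `SP || start_linker || p1 || middle_linker || p2 || ... ||
#' middle_linker || pk || end_linker || MITD` and returns the amino-acid
#' string together with a 1-based, inclusive segment map.
#'
#' @param peptides character vector of neoantigen peptides, in vaccine order;
#'   names (if any) become segment labels, otherwise `neo_01`, `neo_02`, ...
#' @param spec a [construct_spec()].
#' @return list `orf_aa`, `segments` (data.frame `name`, `start`, `end`),
#'   `peptide_ids`.
#' @export
assemble_orf <- function(peptides, spec = construct_spec()) {
  if (length(peptides) == 0L) stop("empty peptide list", call. = FALSE)
  ids <- names(peptides) %||% sprintf("neo_%02d", seq_along(peptides))
  if (is.null(names(peptides))) names(peptides) <- ids
  for (i in seq_along(peptides))
    .check_aa(peptides[i], paste0("peptide '", ids[i], "'"))
  segs <- c(SP = spec$sp_aa, linker_start = spec$start_linker)
  for (i in seq_along(peptides)) {
    segs <- c(segs, setNames(toupper(peptides[i]), ids[i]))
    if (i < length(peptides))
      segs <- c(segs, setNames(spec$middle_linker,
                               sprintf("linker_%02d", i)))
  }
  segs <- c(segs, linker_end = spec$end_linker, MITD = spec$mitd_aa)
  len <- nchar(segs)
  end <- cumsum(len)
  segments <- data.frame(name = names(segs),
                         start = end - len + 1L, end = end,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(orf_aa = paste(segs, collapse = ""), segments = segments,
       peptide_ids = ids)
}

#' Build the complete vaccine mRNA
#'
#' `5'UTR || codons(ORF) || stop || 3'UTR || polyA`, with the SP's AUG as the
#' first codon after the UTR (Kozak context `GCCACC AUG`). The region map is
#' 1-based inclusive and tiles the sequence exactly. The sequence stays in
#' the AUGC alphabet; the N1-methylpseudouridine substitution for U is
#' recorded as metadata only.
#'
#' @param orf result of [assemble_orf()].
#' @param spec a [construct_spec()].
#' @param codon_fn codon source: a function `(peptide) -> RNA string`, e.g.
#'   `function(p) design(p, ...)$rna_codons`; `NULL` uses the naive
#'   most-frequent-codon reverse translation with `usage`.
#' @param usage codon usage table for the default codon source.
#' @return list of class `assembled_construct`: `rna_sequence`, `regions`
#'   (data.frame `name`, `start`, `end`), `peptide_manifest`, `notes`.
#' @export
build_mrna <- function(orf, spec = construct_spec(), codon_fn = NULL,
                       usage = read_codon_usage()) {
  if (is.null(codon_fn))
    codon_fn <- function(p) reverse_translate_max_cai(p, usage)
  cds <- dna_to_rna(codon_fn(orf$orf_aa))
  if (nchar(cds) != 3L * nchar(orf$orf_aa))
    stop("codon source returned ", nchar(cds), " nt for ",
         nchar(orf$orf_aa), " residues", call. = FALSE)
  back <- translate_nt(cds, to_first_stop = FALSE)
  if (attr(back, "stop_found") || as.character(back) != orf$orf_aa)
    stop("codon source emitted a stop codon inside the ORF or mistranslates",
         call. = FALSE)

  n5 <- nchar(spec$utr5_rna)
  rna <- paste0(spec$utr5_rna, cds, spec$stop_codon, spec$utr3_rna,
                strrep("A", spec$polya_len))

  orf_nt <- data.frame(name = orf$segments$name,
                       start = n5 + 3L * (orf$segments$start - 1L) + 1L,
                       end = n5 + 3L * orf$segments$end,
                       stringsAsFactors = FALSE)
  tail_start <- n5 + 3L * nchar(orf$orf_aa)
  regions <- rbind(
    data.frame(name = "utr5", start = 1L, end = n5, stringsAsFactors = FALSE),
    orf_nt,
    data.frame(name = c("stop", "utr3", "polyA"),
               start = c(tail_start + 1L, tail_start + 4L,
                         tail_start + 4L + nchar(spec$utr3_rna)),
               end = c(tail_start + 3L,
                       tail_start + 3L + nchar(spec$utr3_rna),
                       tail_start + 3L + nchar(spec$utr3_rna) + spec$polya_len),
               stringsAsFactors = FALSE))
  rownames(regions) <- NULL
  stopifnot(regions$end[nrow(regions)] == nchar(rna))
  structure(list(rna_sequence = rna, regions = regions,
                 peptide_manifest = orf$peptide_ids,
                 notes = c(
                   modification = paste("N1-methylpseudouridine substitutes U",
                                        "(metadata only; sequence in AUGC)"),
                   stop_codon = paste("single", spec$stop_codon,
                                      "appended after MITD (package convention)"),
                   coordinates = "1-based inclusive")),
            class = "assembled_construct")
}

#' Region sequence of a construct
#' @param construct an `assembled_construct`.
#' @param name region name.
#' @return the region's RNA substring.
#' @export
region_seq <- function(construct, name) {
  r <- construct$regions[construct$regions$name == name, ]
  if (nrow(r) != 1L) stop("no unique region '", name, "'", call. = FALSE)
  substr(construct$rna_sequence, r$start, r$end)
}

#' Export an assembled construct
#'
#' Formats: `fasta` (RNA sequence), `genbank` (GenBank-style flat file with
#' one misc_feature per region, 1-based inclusive coordinates), `tsv`
#' (region table with the sequence in a header comment). All three round-trip
#' through [read_construct()].
#'
#' @param construct an `assembled_construct`.
#' @param path output file.
#' @param format one of `"fasta"`, `"genbank"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_construct <- function(construct, path,
                            format = c("fasta", "genbank", "tsv")) {
  if (length(format) > 1L) format <- format[1]
  if (!format %in% c("fasta", "genbank", "tsv"))
    stop("unknown format '", format, "'; available: fasta, genbank, tsv",
         call. = FALSE)
  rna <- construct$rna_sequence
  if (format == "fasta") {
    lines <- c(paste0(">construct length=", nchar(rna),
                      " peptides=", length(construct$peptide_manifest),
                      " coordinates=1-based_inclusive"),
               substring(rna, seq(1, nchar(rna), 60),
                         pmin(nchar(rna), seq(60, nchar(rna) + 59, 60))))
    writeLines(lines, path)
  } else if (format == "tsv") {
    con <- file(path, "w")
    writeLines(c(paste0("# sequence=", rna),
                 paste0("# peptides=", paste(construct$peptide_manifest,
                                             collapse = ","))), con)
    write.table(construct$regions, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  } else {
    feats <- unlist(lapply(seq_len(nrow(construct$regions)), function(i) {
      r <- construct$regions[i, ]
      c(sprintf("     misc_feature    %d..%d", r$start, r$end),
        sprintf("                     /label=%s", r$name))
    }))
    origin <- vapply(seq(1, nchar(rna), 60), function(s) {
      chunk <- substr(rna, s, min(nchar(rna), s + 59))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
      sprintf("%9d %s", s, paste(tolower(tens), collapse = " "))
    }, "")
    writeLines(c(
      sprintf("LOCUS       construct %d nt RNA linear", nchar(rna)),
      "DEFINITION  tandem-minigene vaccine mRNA; coordinates 1-based inclusive.",
      "FEATURES             Location/Qualifiers",
      feats, "ORIGIN", origin, "//"), path)
  }
  invisible(path)
}

#' Re-import an exported construct
#'
#' @param path file written by [write_construct()].
#' @param format the format it was written in.
#' @return list with `rna_sequence` and/or `regions`, depending on what the
#'   format stores (`fasta`: sequence; `tsv`: sequence + regions; `genbank`:
#'   sequence + regions).
#' @export
read_construct <- function(path, format = c("fasta", "genbank", "tsv")) {
  if (length(format) > 1L) format <- format[1]
  lines <- readLines(path)
  if (format == "fasta") {
    list(rna_sequence = paste(lines[-1], collapse = ""))
  } else if (format == "tsv") {
    seq_line <- sub("^# sequence=", "", lines[startsWith(lines, "# sequence=")])
    body <- lines[!startsWith(lines, "#")]
    regions <- read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
    list(rna_sequence = seq_line, regions = regions)
  } else if (format == "genbank") {
    fl <- grep("^     misc_feature", lines)
    regions <- data.frame(
      name = sub("^\\s*/label=", "", lines[fl + 1L]),
      start = as.integer(sub("\\.\\..*$", "",
                             sub("^     misc_feature\\s+", "", lines[fl]))),
      end = as.integer(sub("^.*\\.\\.", "",
                           sub("^     misc_feature\\s+", "", lines[fl]))),
      stringsAsFactors = FALSE)
    o <- which(lines == "ORIGIN")
    seq_lines <- lines[(o + 1L):(length(lines) - 1L)]
    rna <- toupper(gsub("[ 0-9/]", "", paste(seq_lines, collapse = "")))
    list(rna_sequence = rna, regions = regions)
  } else stop("unknown format '", format, "'; available: fasta, genbank, tsv",
              call. = FALSE)
}
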