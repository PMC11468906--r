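#' Parameters for the synthetic-cohort generator
#'
#' Defaults emulate whole-exome plus RNA-seq derived inputs for a murine tumor
#' line: CDS lengths of 120-400 codons, log-normal expression, somatic SNVs
#' and small indels with tumor VAFs in 0.05-0.6 and germline VAF 0, and an
#' optional set of "planted" strong neoantigens (high VAF, high expression,
#' PWM-consensus binding) used for recovery tests.
#'
#' @param cds_len_codons integer range (min, max) of CDS length in codons,
#'   stop codon included.
#' @param tpm_meanlog,tpm_sdlog log-normal TPM parameters.
#' @param vaf_tumor_range uniform range of somatic tumor-DNA VAF.
#' @param rna_vaf_noise SD of additive noise linking RNA VAF to DNA VAF.
#' @param synonymous_fraction fraction of SNVs forced synonymous.
#' @param indel_fraction fraction of variants generated as small indels
#'   (1-3 nt, VCF-style anchor encoding).
#' @param germline_fraction fraction of variants emitted as germline
#'   contaminants (VAF about 0.5 in both tumor and normal DNA).
#' @param n_planted number of engineered strong neoantigens.
#' @param planted_vaf_range tumor-DNA VAF range for planted variants.
#' @param planted_tpm TPM assigned to transcripts carrying a planted variant.
#' @param hla_alleles allele labels for the cohort.
#' @param pwm_set optional `toy_pwm_set`; built from `hla_alleles` when
#'   planting is requested and none is supplied.
#' @return named list of parameters.
#' @export
cohort_params <- function(cds_len_codons = c(120L, 400L),
                          tpm_meanlog = 2, tpm_sdlog = 1.5,
                          vaf_tumor_range = c(0.05, 0.6),
                          rna_vaf_noise = 0.08,
                          synonymous_fraction = 0.2,
                          indel_fraction = 0.1,
                          germline_fraction = 0,
                          n_planted = 0L,
                          planted_vaf_range = c(0.4, 0.6),
                          planted_tpm = 50,
                          hla_alleles = c("H-2-Kb", "H-2-Db", "H-2-IAb"),
                          pwm_set = NULL) {
  as.list(environment())
}

# single-nucleotide neighbors of a codon at one position
.codon_neighbors <- function(codon, pos) {
  b <- strsplit(codon, "")[[1]]
  vapply(setdiff(DNA_BASES, b[pos]), function(nb) {
    b2 <- b; b2[pos] <- nb; paste(b2, collapse = "")
  }, "")
}

# random sense codons (no stop), vectorized
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a seeded synthetic cohort
#'
#' Produces transcripts, a somatic variant table, an expression table, and an
#' allele list with the same structure the pipeline reads from files. Identical
#' `seed` and `params` give identical outputs. When `params$n_planted > 0`,
#' that many variants are engineered to be strong candidates: the mutant
#' 27-mer contains the consensus 9-mer of the first class I allele's PWM
#' (mutant residue at the consensus center), tumor VAF is drawn from
#' `planted_vaf_range`, germline VAF is 0, and the host transcript gets
#' `planted_tpm`.
#'
#' @param seed integer seed.
#' @param n_transcripts number of transcripts.
#' @param n_variants total number of variants (planted ones included).
#' @param params list from [cohort_params()].
#' @return list of class `neovax_cohort` with elements `transcripts`,
#'   `variants`, `expression`, `hla_alleles`, `planted` (data.frame of
#'   engineered variant keys, possibly empty), `pwm_set` (NULL unless planting
#'   used or supplied), `seed`, `params`.
#' @export
generate_cohort <- function(seed, n_transcripts = 20L, n_variants = 30L,
                            params = cohort_params()) {
  stopifnot(n_transcripts >= 0L, n_variants >= 0L)
  p <- modifyList(cohort_params(), params)
  if (p$n_planted > n_variants)
    stop("n_planted exceeds n_variants", call. = FALSE)
  if (p$n_planted > n_transcripts)
    stop("n_planted exceeds n_transcripts", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  pwm_set <- p$pwm_set
  if (is.null(pwm_set) && p$n_planted > 0L)
    pwm_set <- make_toy_pwm_set(p$hla_alleles, seed = as.integer(seed) + 1L)

  sense <- .sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  gc <- Biostrings::GENETIC_CODE

  empty_tx <- data.frame(transcript_id = character(0), cds = character(0),
                         gene_id = character(0), tpm = numeric(0),
                         stringsAsFactors = FALSE)
  empty_var <- data.frame(transcript_id = character(0), cds_pos = integer(0),
                          ref = character(0), alt = character(0),
                          vaf_tumor_dna = numeric(0), vaf_normal_dna = numeric(0),
                          vaf_tumor_rna = numeric(0), stringsAsFactors = FALSE)

  if (n_transcripts == 0L) {
    out <- list(transcripts = empty_tx, variants = empty_var,
                expression = empty_tx[c("transcript_id", "gene_id", "tpm")],
                hla_alleles = p$hla_alleles,
                planted = empty_var[c("transcript_id", "cds_pos")],
                pwm_set = pwm_set, seed = seed, params = p)
    class(out) <- "neovax_cohort"
    return(out)
  }

  lens <- p$cds_len_codons[1]:p$cds_len_codons[2]
  n_codons <- lens[sample.int(length(lens), n_transcripts, replace = TRUE)]
  cds <- vapply(n_codons, function(k) {
    paste0("ATG", paste(sample(sense, k - 2L, replace = TRUE), collapse = ""),
           sample(stops, 1L))
  }, "")
  transcripts <- data.frame(
    transcript_id = sprintf("T%04d", seq_len(n_transcripts)),
    cds = cds,
    gene_id = sprintf("G%04d", seq_len(n_transcripts)),
    tpm = round(rlnorm(n_transcripts, p$tpm_meanlog, p$tpm_sdlog), 3),
    stringsAsFactors = FALSE
  )

  planted <- empty_var[c("transcript_id", "cds_pos")]
  variants <- empty_var

  ## -- planted strong neoantigens ------------------------------------------
  if (p$n_planted > 0L) {
    al <- pwm_set_lengths(pwm_set)
    allele1 <- al$allele[al$class == "I"][1]
    if (is.na(allele1)) stop("planting requires a class I allele", call. = FALSE)
    cons <- strsplit(pwm_consensus(pwm_set, allele1, 9L), "")[[1]]
    # first DNA codon of each amino acid, deterministic
    aa2codon <- vapply(AA_CANONICAL, function(a) names(gc)[gc == a][1], "")
    plant_rows <- vector("list", p$n_planted)
    for (i in seq_len(p$n_planted)) {
      tx <- i                      # one planted variant per leading transcript
      codons <- codon_split(transcripts$cds[tx])
      c0 <- 30L                    # consensus occupies codons c0..c0+8
      mut_codon_idx <- c0 + 4L     # consensus center = the mutant residue
      aa_mut <- cons[5L]
      # find (wt codon, mut codon) differing at one nt with different residues
      found <- NULL
      for (mc in names(gc)[gc == aa_mut]) {
        for (k in 1:3) {
          for (wc in .codon_neighbors(mc, k)) {
            if (gc[wc] != "*" && gc[wc] != aa_mut) { found <- list(mc = mc, wc = wc, k = k); break }
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      embed <- vapply(cons, function(a) aa2codon[[a]], "")
      embed[5L] <- found$wc        # wild type carries the non-consensus residue
      codons[c0:(c0 + 8L)] <- embed
      transcripts$cds[tx] <- paste(codons, collapse = "")
      transcripts$tpm[tx] <- p$planted_tpm
      pos <- 3L * (mut_codon_idx - 1L) + found$k
      vaf <- runif(1, p$planted_vaf_range[1], p$planted_vaf_range[2])
      plant_rows[[i]] <- data.frame(
        transcript_id = transcripts$transcript_id[tx], cds_pos = pos,
        ref = substr(found$wc, found$k, found$k),
        alt = substr(found$mc, found$k, found$k),
        vaf_tumor_dna = vaf, vaf_normal_dna = 0,
        vaf_tumor_rna = min(1, max(0, vaf + rnorm(1, 0, p$rna_vaf_noise))),
        stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, plant_rows)
    planted <- variants[c("transcript_id", "cds_pos")]
  }

  ## -- background variants --------------------------------------------------
  n_bg <- n_variants - p$n_planted
  if (n_bg > 0L) {
    # usable positions leave the start codon, the stop codon, and an indel
    # margin untouched
    pool <- do.call(rbind, lapply(seq_len(n_transcripts), function(i) {
      len <- nchar(transcripts$cds[i])
      hi <- len - 9L
      if (hi < 4L) return(NULL)
      data.frame(tx = i, pos = 4:hi)
    }))
    # keep planted loci and their consensus windows untouched
    if (p$n_planted > 0L) {
      keep <- rep(TRUE, nrow(pool))
      for (i in seq_len(p$n_planted)) {
        guard <- (3L * 29L + 1L):(3L * 39L)   # codons 30..39 of transcript i
        keep <- keep & !(pool$tx == i & pool$pos %in% guard)
      }
      pool <- pool[keep, , drop = FALSE]
    }
    if (n_bg > nrow(pool))
      stop("n_variants (", n_variants, ") exceeds available CDS positions (",
           nrow(pool) + p$n_planted, ")", call. = FALSE)
    idx <- sample(nrow(pool), n_bg)
    rows <- vector("list", n_bg)
    for (r in seq_len(n_bg)) {
      tx <- pool$tx[idx[r]]; pos <- pool$pos[idx[r]]
      cds_t <- transcripts$cds[tx]
      is_indel <- runif(1) < p$indel_fraction
      if (is_indel) {
        anchor <- substr(cds_t, pos, pos)
        if (runif(1) < 0.5) {      # insertion after the anchor
          ins_len <- sample(1:3, 1L)
          ref <- anchor
          alt <- paste0(anchor, paste(sample(DNA_BASES, ins_len, replace = TRUE),
                                      collapse = ""))
        } else {                   # deletion of the bases after the anchor
          del_len <- sample(1:3, 1L)
          ref <- substr(cds_t, pos, pos + del_len)
          alt <- anchor
        }
      } else {
        codon_idx <- (pos - 1L) %/% 3L + 1L
        k <- (pos - 1L) %% 3L + 1L
        codons <- codon_split(cds_t)
        wt_codon <- codons[codon_idx]
        want_syn <- runif(1) < p$synonymous_fraction
        # the sampled within-codon position may not offer the wanted
        # consequence (e.g. third positions of 4-fold codons are always
        # synonymous); walk the codon's positions starting from the sampled
        # one until a suitable change exists
        pick <- NULL
        for (k_try in unique(c(k, 1L, 2L, 3L))) {
          nb <- .codon_neighbors(wt_codon, k_try)
          cls <- unname(gc[nb])
          cand <- if (want_syn) nb[cls == gc[wt_codon]]
                  else nb[cls != "*" & cls != unname(gc[wt_codon])]
          if (length(cand)) {
            pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
            k <- k_try
            break
          }
        }
        if (is.null(pick)) next   # no change of the wanted kind in this codon
        pos <- 3L * (codon_idx - 1L) + k
        ref <- substr(wt_codon, k, k)
        alt <- substr(pick, k, k)
      }
      germline <- runif(1) < p$germline_fraction
      vaf <- if (germline) min(1, max(0, rnorm(1, 0.5, 0.03)))
             else runif(1, p$vaf_tumor_range[1], p$vaf_tumor_range[2])
      rows[[r]] <- data.frame(
        transcript_id = transcripts$transcript_id[tx], cds_pos = pos,
        ref = ref, alt = alt,
        vaf_tumor_dna = vaf,
        vaf_normal_dna = if (germline) min(1, max(0, rnorm(1, 0.5, 0.03))) else 0,
        vaf_tumor_rna = min(1, max(0, vaf + rnorm(1, 0, p$rna_vaf_noise))),
        stringsAsFactors = FALSE)
    }
    variants <- rbind(variants, do.call(rbind, rows))
  }
  rownames(variants) <- NULL
  validate_variants(variants, transcripts)

  out <- list(
    transcripts = transcripts,
    variants = variants,
    expression = transcripts[c("transcript_id", "gene_id", "tpm")],
    hla_alleles = p$hla_alleles,
    planted = planted,
    pwm_set = pwm_set,
    seed = seed,
    params = p
  )
  class(out) <- "neovax_cohort"
  out
}

#' Write a cohort's tables to a directory
#'
#' Emits `cds.fasta`, `variants.tsv`, `expression.tsv`, and `hla.txt`.
#'
#' @param cohort a `neovax_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cds = file.path(dir, "cds.fasta"),
    variants = file.path(dir, "variants.tsv"),
    expression = file.path(dir, "expression.tsv"),
    hla = file.path(dir, "hla.txt")
  )
  write_cds_fasta(cohort$transcripts, paths["cds"])
  write_variant_table(cohort$variants, paths["variants"])
  write_expression_table(cohort$expression, paths["expression"])
  write_hla_list(cohort$hla_alleles, paths["hla"])
  invisible(paths)
}
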