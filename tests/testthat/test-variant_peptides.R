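toy_tx <- function(cds, id = "T1") list(transcript_id = id, cds = cds)

test_that("variant application classifies and translates toy cases correctly", {
  tx <- toy_tx("ATGGCTGATTAA")                      # M A D
  mp <- apply_variant(tx, list(cds_pos = 4, ref = "G", alt = "A"))
  expect_equal(mp$wt_protein, "MAD")
  expect_equal(mp$mut_protein, "MTD")
  expect_equal(mp$variant_class, "missense")
  expect_equal(mp$first_changed_residue, 2L)

  # GCT -> GCA, both Ala
  mp2 <- apply_variant(tx, list(cds_pos = 6, ref = "T", alt = "A"))
  expect_equal(mp2$variant_class, "synonymous")
  expect_true(is.na(mp2$first_changed_residue))

  # insertion shifts the frame from residue 2 onward
  mp3 <- apply_variant(tx, list(cds_pos = 4, ref = "G", alt = "GA"))
  expect_equal(mp3$variant_class, "frameshift")
  expect_equal(mp3$first_changed_residue, 2L)
  expect_equal(substr(mp3$mut_protein, 1, 1), "M")

  # destroying the start codon
  mp4 <- apply_variant(tx, list(cds_pos = 2, ref = "T", alt = "C"))
  expect_equal(mp4$variant_class, "start_loss")

  # SNV creating a stop: GAT -> TAT would be missense; make GAT -> TAA via
  # a 3-nt inframe replacement instead is an indel, so use pos 7 G -> T on a
  # longer CDS where GAA -> TAA
  tx2 <- toy_tx("ATGGCTGAACGTTAA")                  # M A E R
  mp5 <- apply_variant(tx2, list(cds_pos = 7, ref = "G", alt = "T"))
  expect_equal(mp5$variant_class, "stop_gain")
  expect_equal(mp5$mut_protein, "MA")

  # errors: out of bounds and ref mismatch
  expect_error(apply_variant(tx, list(cds_pos = 13, ref = "A", alt = "T")),
               "outside the CDS")
  expect_error(apply_variant(tx, list(cds_pos = 4, ref = "C", alt = "A")),
               "ref mismatch")
})

test_that("peptide windows follow the centered-27 convention with truncation", {
  # missense at residue 100 of a 300-aa protein
  prot <- strrep("A", 300)
  mut <- paste0(substr(prot, 1, 99), "W", substr(prot, 101, 300))
  mp <- structure(list(wt_protein = prot, mut_protein = mut,
                       first_changed_residue = 100L,
                       variant_class = "missense"), class = "mutant_protein")
  pp <- extract_peptide_pair(mp)
  expect_equal(pp$window_start, 87L)
  expect_equal(nchar(pp$mut_peptide), 27L)
  expect_equal(pp$mutant_offset, 14L)
  expect_equal(substr(pp$mut_peptide, 14, 14), "W")
  expect_equal(pp$mut_peptide, substr(mut, 87, 113))

  # missense at residue 5: truncated at the N terminus, never padded
  mut5 <- paste0(substr(prot, 1, 4), "W", substr(prot, 6, 300))
  mp5 <- structure(list(wt_protein = prot, mut_protein = mut5,
                        first_changed_residue = 5L,
                        variant_class = "missense"), class = "mutant_protein")
  pp5 <- extract_peptide_pair(mp5)
  expect_equal(pp5$window_start, 1L)
  expect_equal(nchar(pp5$mut_peptide), 18L)   # residues 1..18
  expect_equal(pp5$mutant_offset, 5L)

  # frameshift changing residues 50 onward, mutant protein 60 aa long
  mut_fs <- paste0(substr(prot, 1, 49), strrep("V", 11))
  mp_fs <- structure(list(wt_protein = prot, mut_protein = mut_fs,
                          first_changed_residue = 50L,
                          variant_class = "frameshift"),
                     class = "mutant_protein")
  pp_fs <- extract_peptide_pair(mp_fs)
  expect_equal(pp_fs$window_start, 37L)
  expect_equal(nchar(pp_fs$mut_peptide), 24L)  # 37..60
  expect_true(is.na(pp_fs$wt_peptide))

  # synonymous input is rejected
  mp_syn <- structure(list(wt_protein = prot, mut_protein = prot,
                           first_changed_residue = NA_integer_,
                           variant_class = "synonymous"),
                      class = "mutant_protein")
  expect_error(extract_peptide_pair(mp_syn), "no neoantigen")
})

test_that("interior missense windows are 27-mers with the mutation at 14", {
  for (seed in c(2, 5, 8)) {
    co <- generate_cohort(seed, 8, 12,
                          cohort_params(indel_fraction = 0,
                                        synonymous_fraction = 0))
    pep <- peptides_from_cohort(co$transcripts, co$variants)
    interior <- pep[pep$variant_class == "missense", ]
    for (i in seq_len(nrow(interior))) {
      r <- interior[i, ]
      tx <- co$transcripts[co$transcripts$transcript_id == r$transcript_id, ]
      mp <- apply_variant(tx, co$variants[co$variants$transcript_id ==
        r$transcript_id & co$variants$cds_pos == r$cds_pos, ][1, ])
      m <- mp$first_changed_residue
      if (m > 13 && nchar(mp$mut_protein) - m >= 13) {
        expect_equal(nchar(r$mut_peptide), 27L)
        expect_equal(r$mutant_offset, 14L)
      }
      # the peptide is a substring of the mutant protein at the coordinates
      expect_equal(r$mut_peptide,
                   substr(mp$mut_protein, r$window_start,
                          r$window_start + nchar(r$mut_peptide) - 1L))
    }
  }
})

test_that("synonymous variants never yield a peptide pair", {
  co <- generate_cohort(13, 10, 15, cohort_params(synonymous_fraction = 1,
                                                  indel_fraction = 0))
  pep <- peptides_from_cohort(co$transcripts, co$variants)
  syn_ids <- vapply(seq_len(nrow(co$variants)), function(i) {
    v <- co$variants[i, ]
    tx <- co$transcripts[co$transcripts$transcript_id == v$transcript_id, ]
    apply_variant(tx, v)$variant_class == "synonymous"
  }, TRUE)
  if (nrow(pep) > 0)
    expect_false(any(pep$id %in% paste0(
      co$variants$transcript_id[syn_ids], ":", co$variants$cds_pos[syn_ids],
      ":", co$variants$ref[syn_ids], ">", co$variants$alt[syn_ids])))
  expect_gt(sum(syn_ids), 0)
})

test_that("translation agrees with an independent codon table on random edits", {
  skip_if_not_installed("seqinr")
  set.seed(21)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  for (i in 1:1000) {
    n_codons <- sample(5:40, 1)
    cds <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""), "TAA")
    pos <- sample(nchar(cds), 1)
    base <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    edited <- paste0(substr(cds, 1, pos - 1), alt,
                     substr(cds, pos + 1, nchar(cds)))
    expect_identical(as.character(translate_nt(edited)),
                     oracle_translate(edited))
    expect_identical(as.character(translate_nt(cds)), oracle_translate(cds))
  }
})
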