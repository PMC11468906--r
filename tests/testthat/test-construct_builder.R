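test_that("ORF assembly follows SP-linker-neo...-linker-MITD with exact constants", {
  spec <- construct_spec()
  # segment constants, character for character
  expect_equal(spec$sp_aa, "MRVTAPRTLILLLSGALALTETWAGS")
  expect_equal(spec$mitd_aa,
               "VGIVAGLAVLAVVVIGAVVATVMCRRKSSGGKGGSYSQAASSDSAQGSDVSLTA")
  expect_equal(spec$start_linker, "GGSGGGGSGG")
  expect_equal(spec$end_linker, "GGSLGGGGSG")

  # twenty 27-mers: 26 + 10 + 540 + 190 + 10 + 54 = 830 aa
  peps <- vapply(1:20, function(i) random_peptide(27), "")
  set.seed(71)
  orf <- assemble_orf(peps, spec)
  expect_equal(nchar(orf$orf_aa), 830L)
  segs <- orf$segments
  expect_equal(substr(orf$orf_aa, segs$start[segs$name == "SP"],
                      segs$end[segs$name == "SP"]), spec$sp_aa)
  expect_equal(substr(orf$orf_aa, segs$start[segs$name == "MITD"],
                      segs$end[segs$name == "MITD"]), spec$mitd_aa)
  expect_equal(sum(segs$name == "linker_start"), 1L)
  expect_equal(sum(grepl("^linker_\\d", segs$name)), 19L)

  # single peptide: no middle linker
  orf1 <- assemble_orf(c(p = "ACDEFYKL"), spec)
  expect_equal(nchar(orf1$orf_aa), 26 + 10 + 8 + 10 + 54)
  expect_false(any(grepl("^linker_\\d", orf1$segments$name)))

  expect_error(assemble_orf(character(0), spec), "empty")
  expect_error(assemble_orf(c(bad = "ACDEFZ"), spec), "bad")
})

test_that("the assembled mRNA has verbatim UTRs, Kozak context, and a 75-nt tail", {
  spec <- construct_spec()
  orf <- assemble_orf(c(n1 = "ACDEFGHIKLMNPQRSTVWYACDEFGH",
                        n2 = "MNPQRSTVWYACDEFGHIKLMNPQRST"), spec)
  con <- build_mrna(orf, spec)
  rna <- con$rna_sequence

  # polyA: exactly 75 trailing A, preceded by a non-A
  expect_equal(nchar(region_seq(con, "polyA")), 75L)
  expect_match(rna, "[^A]A{75}$")
  expect_equal(region_seq(con, "polyA"), strrep("A", 75))

  # 5'UTR verbatim, ending immediately before the AUG of the SP
  utr5 <- region_seq(con, "utr5")
  expect_equal(utr5, spec$utr5_rna)
  expect_true(startsWith(utr5, "AG"))
  expect_true(endsWith(utr5, "GCCACC"))
  expect_equal(substr(rna, nchar(utr5) + 1, nchar(utr5) + 3), "AUG")
  expect_equal(region_seq(con, "utr3"), spec$utr3_rna)

  # decode check: translating the ORF region returns the assembled protein
  sp_start <- con$regions$start[con$regions$name == "SP"]
  mitd_end <- con$regions$end[con$regions$name == "MITD"]
  orf_rna <- substr(rna, sp_start, mitd_end)
  expect_equal(as.character(translate_nt(orf_rna, to_first_stop = FALSE)),
               orf$orf_aa)
  expect_equal(region_seq(con, "stop"), spec$stop_codon)

  # a codon source that emits a stop mid-ORF is rejected
  expect_error(build_mrna(orf, spec, codon_fn = function(p)
    paste0("UAA", strrep("GCC", nchar(p) - 1L))), "stop codon|mistranslates")
})

test_that("regions tile the construct exactly for random peptide sets", {
  spec <- construct_spec()
  set.seed(81)
  for (rep in 1:10) {
    k <- sample(1:8, 1)
    peps <- vapply(seq_len(k), function(i) random_peptide(sample(10:27, 1)), "")
    con <- build_mrna(assemble_orf(peps, spec), spec)
    r <- con$regions
    expect_equal(r$start[1], 1L)
    expect_equal(r$end[nrow(r)], nchar(con$rna_sequence))
    expect_true(all(r$start[-1] == r$end[-nrow(r)] + 1L))   # no gaps/overlaps
    expect_equal(sum(r$end - r$start + 1L), nchar(con$rna_sequence))
    expect_equal(con$peptide_manifest, sprintf("neo_%02d", 1:k))
  }
})

test_that("identical inputs assemble byte-identical constructs (both codon sources)", {
  spec <- construct_spec()
  orf <- assemble_orf(c(a = "ACDEFGHIKL", b = "MNPQRSTVWY"), spec)
  u <- read_codon_usage()
  c1 <- build_mrna(orf, spec, usage = u)
  c2 <- build_mrna(orf, spec, usage = u)
  expect_identical(c1$rna_sequence, c2$rna_sequence)
  dfn <- function(p) design(substr(p, 1, nchar(p)), u,
                            max_exact_nt = 3L * nchar(p))$rna_codons
  d1 <- build_mrna(orf, spec, codon_fn = dfn, usage = u)
  d2 <- build_mrna(orf, spec, codon_fn = dfn, usage = u)
  expect_identical(d1$rna_sequence, d2$rna_sequence)
  # translation round-trip holds for the optimizing source too
  sp_start <- d1$regions$start[d1$regions$name == "SP"]
  mitd_end <- d1$regions$end[d1$regions$name == "MITD"]
  expect_equal(as.character(translate_nt(
    substr(d1$rna_sequence, sp_start, mitd_end), to_first_stop = FALSE)),
    orf$orf_aa)
})

test_that("construct exports round-trip in all three formats", {
  spec <- construct_spec()
  con <- build_mrna(assemble_orf(c(x = "ACDEFGHIKLMNP"), spec), spec)

  f_fa <- withr::local_tempfile(fileext = ".fasta")
  write_construct(con, f_fa, "fasta")
  expect_identical(read_construct(f_fa, "fasta")$rna_sequence,
                   con$rna_sequence)

  f_gb <- withr::local_tempfile(fileext = ".gb")
  write_construct(con, f_gb, "genbank")
  gb <- read_construct(f_gb, "genbank")
  expect_identical(gb$rna_sequence, con$rna_sequence)
  expect_equal(gb$regions, con$regions)
  # one feature per region
  expect_equal(sum(grepl("misc_feature", readLines(f_gb))),
               nrow(con$regions))

  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_construct(con, f_tsv, "tsv")
  tsv <- read_construct(f_tsv, "tsv")
  expect_identical(tsv$rna_sequence, con$rna_sequence)
  expect_equal(tsv$regions, con$regions)
  expect_equal(sum(tsv$regions$end - tsv$regions$start + 1),
               nchar(con$rna_sequence))

  expect_error(write_construct(con, f_fa, "xlsx"), "fasta, genbank, tsv")
})
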