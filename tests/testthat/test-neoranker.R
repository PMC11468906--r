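test_that("toy PWM predictor maps normalized score to the affinity scale", {
  pwm <- toy_ranking_model("K1")
  cons <- pwm_consensus(pwm, "K1", 9)
  expect_equal(toy_binding_predictor(cons, "K1", pwm)$affinity_nM, 1)

  # anti-consensus: per-position minimum scores -> s = 0 -> 50,000 nM
  m <- pwm$alleles[["K1"]]$pwms[["9"]]
  worst <- paste(rownames(m)[apply(m, 2, which.min)], collapse = "")
  expect_equal(toy_binding_predictor(worst, "K1", pwm)$affinity_nM, 50000)

  # hand-computed s for an arbitrary peptide
  p <- "ACDEFGHIK"
  aa <- strsplit(p, "")[[1]]
  raw <- sum(m[cbind(match(aa, rownames(m)), 1:9)])
  s <- (raw - sum(apply(m, 2, min))) / (sum(apply(m, 2, max)) -
                                        sum(apply(m, 2, min)))
  expect_equal(toy_binding_predictor(p, "K1", pwm)$affinity_nM, 50000^(1 - s))

  expect_error(toy_binding_predictor(p, "nope", pwm), "available")
})

test_that("sub-peptide scanning enumerates exactly the mutation-spanning windows", {
  pwm <- toy_ranking_model("K1")   # class I: lengths 8-11
  pred <- make_toy_predictor(pwm)
  info <- pwm_set_lengths(pwm)

  pair <- list(mut_peptide = strrep("A", 13) %+% "W" %+% strrep("A", 13),
               wt_peptide = strrep("A", 27), mutant_offset = 14L,
               variant_class = "missense")
  sc <- scan_subpeptides(pair, info, pred)
  expect_equal(sc$n_windows, 38L)   # 8 + 9 + 10 + 11 spanning windows

  # matches the brute-force window enumeration for several offsets
  for (m in c(1L, 5L, 14L, 27L)) {
    pr <- list(mut_peptide = strrep("A", 27), wt_peptide = strrep("A", 27),
               mutant_offset = m, variant_class = "missense")
    expect_equal(scan_subpeptides(pr, info, pred)$n_windows,
                 length(brute_windows(27, m, 8:11)))
  }

  # a lone 8-mer has exactly one scanned window per allele
  pair8 <- list(mut_peptide = "ACDEFGHI", wt_peptide = "ACDEFGHL",
                mutant_offset = 8L, variant_class = "missense")
  expect_equal(scan_subpeptides(pair8, info, pred)$n_windows, 1L)

  # duplicated alleles with identical PWMs leave the best unchanged
  pwm2 <- pwm
  pwm2$alleles[["K1b"]] <- pwm2$alleles[["K1"]]
  sc1 <- scan_subpeptides(pair, info, pred)
  sc2 <- scan_subpeptides(pair, pwm_set_lengths(pwm2),
                          make_toy_predictor(pwm2))
  expect_equal(sc2$best_mut_affinity_nM, sc1$best_mut_affinity_nM)

  # scanning minima equal the brute-force minimum over enumerated windows
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:27, 1)
    m <- sample(seq_len(n), 1)
    pep <- random_peptide(n)
    pr <- list(mut_peptide = pep, wt_peptide = random_peptide(n),
               mutant_offset = m, variant_class = "missense")
    got <- scan_subpeptides(pr, info, pred)
    wins <- brute_windows(n, m, 8:11)
    if (length(wins)) {
      subs <- vapply(wins, function(w)
        substr(pep, w["start"], w["start"] + w["len"] - 1L), "")
      expect_equal(got$best_mut_affinity_nM, min(pred(subs, "K1")))
      expect_equal(got$n_windows, length(wins))
    }
  }
})

test_that("composite score matches hand arithmetic and its reductions", {
  w <- score_weights()
  # a candidate normalized to 1 on every feature scores exactly 1
  pool <- list(expr_tpm = c(0, 10), vaf_tumor_rna = c(0, 1),
               vaf_tumor_dna = c(0, 1), vaf_normal_dna = c(0, 1),
               stability_halflife_h = c(0, 8))
  top <- feature_row("top", vaf_dna = 1, vaf_norm = 0, vaf_rna = 1,
                     tpm = 10, mut_aff = 1, wt_aff = 50000)
  top$stability_halflife_h <- 8
  top$immunogenicity_score <- 1
  top$agretopicity <- 50000    # transform saturates at 1
  expect_equal(composite_score(top, w, pool), 1)

  # one-hot expression weight reduces ranking to TPM ordering
  w_expr <- score_weights(weights = c(expression = 1))
  cands <- rbind(feature_row("a", tpm = 5), feature_row("b", tpm = 50),
                 feature_row("c", tpm = 20))
  s <- composite_score(cands, w_expr)
  expect_equal(order(-s), order(-cands$expr_tpm))

  # three-candidate worked table against spreadsheet-style arithmetic
  t3 <- rbind(
    feature_row("x", vaf_dna = 0.4, vaf_norm = 0.00, vaf_rna = 0.5,
                tpm = 20, mut_aff = 10, wt_aff = 1000),
    feature_row("y", vaf_dna = 0.2, vaf_norm = 0.01, vaf_rna = 0.1,
                tpm = 5, mut_aff = 100, wt_aff = 500),
    feature_row("z", vaf_dna = 0.1, vaf_norm = 0.02, vaf_rna = 0.3,
                tpm = 50, mut_aff = 400, wt_aff = 400))
  pool3 <- make_pool_context(t3)
  got <- composite_score(t3, w, pool3)
  L <- log(50000)
  hand <- function(vd, vn, vr, tpm, ma, wa) {
    f <- c(affinity = max(0, 1 - log(ma) / L),
           agretopicity = min(1, log2(wa / ma + 1) / 4),
           expression = (tpm - 5) / 45,
           vaf_rna = (vr - 0.1) / 0.4,
           vaf_dna = (vd - 0.1) / 0.3,
           stability = 0.5,
           immunogenicity = 0.5,
           germline = 1 - (vn - 0) / 0.02)
    sum(w$weights[names(f)] * f)
  }
  expect_equal(got[1], hand(0.4, 0.00, 0.5, 20, 10, 1000), tolerance = 1e-12)
  expect_equal(got[2], hand(0.2, 0.01, 0.1, 5, 100, 500), tolerance = 1e-12)
  expect_equal(got[3], hand(0.1, 0.02, 0.3, 50, 400, 400), tolerance = 1e-12)

  # degenerate pool: constant feature contributes 0.5 everywhere
  same <- rbind(feature_row("a", tpm = 7), feature_row("b", tpm = 7))
  w_expr_only <- score_weights(weights = c(expression = 1))
  expect_equal(composite_score(same, w_expr_only), c(0.5, 0.5))
})

test_that("selection keeps at most top_n, reports attrition, breaks ties as declared", {
  # 30 passing candidates -> exactly 20 selected
  set.seed(41)
  cands <- do.call(rbind, lapply(1:30, function(i)
    feature_row(sprintf("c%02d", i), vaf_dna = runif(1, 0.1, 0.6),
                tpm = runif(1, 2, 60), mut_aff = runif(1, 5, 400),
                vaf_rna = runif(1, 0.1, 0.6))))
  rk <- rank_and_select(cands, score_weights(), top_n = 20)
  expect_equal(nrow(rk$selected), 20L)
  expect_equal(rk$selected$rank, 1:20)
  expect_true(all(diff(rk$selected$composite_score) <= 1e-12))

  # fewer candidates than requested: all returned
  rk5 <- rank_and_select(cands[1:5, ], score_weights(), top_n = 20)
  expect_equal(nrow(rk5$selected), 5L)

  # filter attrition names every violated threshold; survivors violate none
  mixed <- rbind(
    feature_row("ok"),
    feature_row("germ", vaf_norm = 0.5),
    feature_row("lowvaf", vaf_dna = 0.01),
    feature_row("lowexpr", tpm = 0.1),
    feature_row("weak", mut_aff = 5000))
  rkm <- rank_and_select(mixed, score_weights())
  expect_setequal(rkm$attrition$id, c("germ", "lowvaf", "lowexpr", "weak"))
  expect_match(rkm$attrition$reason[rkm$attrition$id == "germ"],
               "max_vaf_normal_dna")
  expect_match(rkm$attrition$reason[rkm$attrition$id == "weak"],
               "max_best_mut_affinity_nM")
  expect_equal(rkm$selected$id, "ok")

  # zero survivors: empty result plus report, not an exception
  rk0 <- rank_and_select(mixed[2:3, ], score_weights())
  expect_equal(nrow(rk0$selected), 0L)
  expect_equal(nrow(rk0$attrition), 2L)

  # tie-break: equal scores resolved by higher tumor-DNA VAF, then lower
  # affinity, then peptide
  w_aff <- score_weights(weights = c(affinity = 1))
  tie <- rbind(
    feature_row("t1", mut_aff = 50, vaf_dna = 0.2, peptide = "B"),
    feature_row("t2", mut_aff = 50, vaf_dna = 0.4, peptide = "A"),
    feature_row("t3", mut_aff = 50, vaf_dna = 0.4, peptide = "C"))
  tie$agretopicity <- 1
  rkt <- rank_and_select(tie, w_aff)
  expect_equal(rkt$selected$id, c("t2", "t3", "t1"))
  # t2/t3 share score and VAF and affinity: peptide "A" < "C"
  tie2 <- tie; tie2$mut_peptide <- c("B", "A", "C")
  rkt2 <- rank_and_select(tie2, w_aff)
  expect_equal(rkt2$selected$id[1:2], c("t2", "t3"))
})

test_that("raising a positively weighted feature never lowers a candidate's rank", {
  set.seed(51)
  base <- do.call(rbind, lapply(1:12, function(i)
    feature_row(sprintf("c%02d", i), vaf_dna = runif(1, 0.1, 0.6),
                tpm = runif(1, 2, 60), mut_aff = runif(1, 5, 400),
                vaf_rna = runif(1, 0.1, 0.6))))
  w <- score_weights()
  rk1 <- rank_and_select(base, w, top_n = 12)
  target <- rk1$selected$id[7]
  for (col in c("expr_tpm", "vaf_tumor_rna", "vaf_tumor_dna")) {
    up <- base
    up[[col]][up$id == target] <- max(up[[col]]) * 1.5
    rk2 <- rank_and_select(up, w, top_n = 12)
    expect_lte(match(target, rk2$selected$id), match(target, rk1$selected$id))
  }
  # lowering the mutant affinity (stronger binding) also never hurts
  up <- base
  up$best_mut_affinity_nM[up$id == target] <- 2
  up$agretopicity[up$id == target] <-
    up$best_wt_affinity_nM[up$id == target] / 2
  rk3 <- rank_and_select(up, w, top_n = 12)
  expect_lte(match(target, rk3$selected$id), match(target, rk1$selected$id))
})

test_that("affine rescaling of pool-wide TPM leaves ranks unchanged", {
  set.seed(61)
  base <- do.call(rbind, lapply(1:15, function(i)
    feature_row(sprintf("c%02d", i), vaf_dna = runif(1, 0.1, 0.6),
                tpm = runif(1, 2, 60), mut_aff = runif(1, 5, 400))))
  w <- score_weights(min_expr_tpm = 0)   # keep the filter out of the picture
  rk1 <- rank_and_select(base, w, top_n = 15)
  scaled <- base
  scaled$expr_tpm <- 3.7 * scaled$expr_tpm + 11
  rk2 <- rank_and_select(scaled, w, top_n = 15)
  expect_equal(rk2$selected$id, rk1$selected$id)
})

test_that("external binding tables parse and drive a predictor", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\taffinity_nM\tpercentile_rank\textra",
               "ACDEFGHI\tK1\t12.5\t0.3\tignored",
               "ACDEFGHL\tK1\t800\t5.0\tignored"), f)
  b <- read_binding_tsv(f)
  expect_equal(nrow(b), 2L)
  expect_false("extra" %in% names(b))
  pred <- make_table_predictor(b)
  expect_equal(pred(c("ACDEFGHI", "ACDEFGHL", "UNSEENPEP"), "K1"),
               c(12.5, 800, 50000))
})
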