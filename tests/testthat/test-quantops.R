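test_that("the recipe follows N:P and mole-fraction arithmetic exactly", {
  cfg <- lpp_config(ionizable_mw = 710)

  # zero mass: everything zero
  r0 <- lpp_recipe(0, cfg)
  expect_true(all(r0$component_masses_ug == 0))
  expect_true(all(r0$volumes_ul == 0))

  # 10 ug, mean nt MW 330, one amine per lipid: hand arithmetic
  r <- lpp_recipe(10, cfg)
  phosphate <- 10 / 330
  expect_equal(r$phosphate_umol, phosphate)
  expect_equal(r$component_umol[["ionizable"]], 4.8 * phosphate)
  expect_equal(r$component_masses_ug[["ionizable"]], 4.8 * phosphate * 710)
  total <- 4.8 * phosphate / 0.40
  expect_equal(r$component_masses_ug[["dope"]], total * 0.15 * 744.03)
  expect_equal(r$component_masses_ug[["cholesterol"]], total * 0.435 * 386.65)
  expect_equal(r$component_masses_ug[["mpeg_dmg"]], total * 0.015 * 2509.2)

  # volumes: 5:1 mRNA:protamine, 3:1 aqueous:ethanol
  expect_equal(r$volumes_ul[["protamine"]], r$volumes_ul[["mrna"]] / 5)
  expect_equal(r$volumes_ul[["ethanol"]], r$volumes_ul[["aqueous"]] / 3)

  # back-computation from the emitted masses
  chk <- lpp_check_recipe(r)
  expect_equal(chk$mole_fractions[["cholesterol"]], 43.5)
  expect_equal(chk$np_ratio, 4.8)

  expect_error(lpp_config(ionizable_mw = 0), "positive")
  expect_error(lpp_recipe(-1, cfg), ">= 0")
})

test_that("recipe inversion recovers N:P and all mole fractions at 1e-9", {
  set.seed(141)
  for (i in 1:100) {
    cfg <- lpp_config(ionizable_mw = runif(1, 300, 1200),
                      amines_per_lipid = sample(1:4, 1),
                      mean_nt_mw = runif(1, 320, 345),
                      dope_mw = runif(1, 700, 800),
                      cholesterol_mw = runif(1, 350, 420),
                      mpeg_dmg_mw = runif(1, 2000, 3000),
                      np_ratio = runif(1, 2, 8))
    r <- lpp_recipe(runif(1, 1, 500), cfg)
    chk <- lpp_check_recipe(r)
    expect_equal(chk$np_ratio, cfg$np_ratio, tolerance = 1e-9)
    expect_equal(unname(chk$mole_fractions[names(cfg$mole_fractions)]),
                 unname(cfg$mole_fractions), tolerance = 1e-9)
  }
})

test_that("responder calls apply the fold and absolute thresholds", {
  tab <- data.frame(
    group = "g", peptide_id = c("p1", "p1", "p2", "p3", "neg", "neg"),
    replicate = c(1, 2, 1, 1, 1, 2),
    spot_count = c(45, 55, 5, 9, 5, 5),
    cells_per_well = 250000L,
    is_negative_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    is_positive_control = FALSE)
  rc <- call_responders(tab)
  # mean 50 vs neg 5: responder (50 >= 10 and 45 >= 10)
  expect_true(rc$is_responder[rc$peptide_id == "p1"])
  expect_equal(rc$normalized_spots[rc$peptide_id == "p1"], 45)
  # mean equal to neg mean: normalized 0, non-responder
  expect_false(rc$is_responder[rc$peptide_id == "p2"])
  expect_equal(rc$normalized_spots[rc$peptide_id == "p2"], 0)

  # neg 0, mean 9: passes the fold rule but fails the absolute threshold
  tab0 <- tab
  tab0$spot_count[tab0$is_negative_control] <- 0
  rc0 <- call_responders(tab0)
  expect_false(rc0$is_responder[rc0$peptide_id == "p3"])

  # missing negative control errors with the group name
  tab_no_neg <- tab[!tab$is_negative_control, ]
  expect_error(call_responders(tab_no_neg), "'g'")
})

test_that("raising a peptide's spot counts never flips responder to non-responder", {
  set.seed(151)
  for (i in 1:50) {
    neg <- runif(1, 0, 20)
    m <- runif(1, 0, 120)
    tab <- data.frame(group = "g", peptide_id = c("p", "neg"),
                      replicate = 1, spot_count = c(m, neg),
                      cells_per_well = 250000L,
                      is_negative_control = c(FALSE, TRUE),
                      is_positive_control = FALSE)
    before <- call_responders(tab)$is_responder
    tab$spot_count[1] <- m + runif(1, 0, 100)
    after <- call_responders(tab)$is_responder
    expect_false(before && !after)
  }
})

test_that("responder rates reproduce the study's printed percentages", {
  expect_equal(responder_rate(10, 19)$percent, 52.6)
  expect_equal(responder_rate(26, 60)$percent, 43.3)
  expect_equal(responder_rate(0, 7)$percent, 0)
  r <- responder_rate(10, 19)
  # exact rate times n recovers the numerator before rounding
  expect_equal(r$percent_exact * r$n_eval / 100, 10)
  # Clopper-Pearson interval agrees with the exact binomial test
  ci <- binom.test(10, 19)$conf.int
  expect_equal(r$ci_low, 100 * ci[1])
  expect_equal(r$ci_high, 100 * ci[2])
  expect_error(responder_rate(5, 0), "n_eval")
  expect_error(responder_rate(9, 5), "n_resp")
})

test_that("tumor volume and TGI follow the caliper formulas", {
  expect_equal(tumor_volume(10, 8), 320)
  expect_equal(tumor_volume(10, 0), 0)
  expect_warning(v <- tumor_volume(8, 10), "swap")
  expect_equal(v, 320)
  expect_error(tumor_volume(-1, 0), "negative")

  # homogeneous of degree 3 under uniform scaling
  set.seed(161)
  for (i in 1:20) {
    L <- runif(1, 5, 20); W <- runif(1, 0, L); k <- runif(1, 0.1, 4)
    expect_equal(tumor_volume(k * L, k * W), k^3 * tumor_volume(L, W))
  }

  expect_equal(tgi(100, 100), 0)
  expect_equal(tgi(19.7, 100), 80.3)
  expect_error(tgi(10, 0), "positive")
})
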