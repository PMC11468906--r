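#' Configuration for the lipopolyplex formulation calculator
#'
#' Component molar masses and formulation constants. The lipid shell uses an
#' ionizable lipid, DOPE, cholesterol, and mPEG-DMG at molar fractions
#' 40 : 15 : 43.5 : 1.5 (percent), with the amine-to-phosphate (N:P) ratio
#' fixed at 4.8:1, mRNA:protamine solution volumes at 5:1, and
#' aqueous:ethanol mixing at 3:1. The ionizable lipid is proprietary, so its
#' molar mass is a required field; one ionizable amine per lipid and a mean
#' nucleotide molar mass of 330 g/mol are the defaults.
#'
#' @param ionizable_mw molar mass of the ionizable lipid (g/mol); required.
#' @param amines_per_lipid ionizable amines per lipid molecule.
#' @param mean_nt_mw mean molar mass per RNA nucleotide (g/mol).
#' @param dope_mw,cholesterol_mw,mpeg_dmg_mw lipid molar masses (g/mol).
#' @param np_ratio amine:phosphate molar ratio.
#' @param mole_fractions lipid mole percentages (must sum to 100).
#' @param protamine_volume_ratio mRNA:protamine solution volume ratio.
#' @param aqueous_ethanol_ratio aqueous:ethanol volume ratio.
#' @param mrna_conc_ug_ul working mRNA concentration for volume bookkeeping.
#' @return list of class `lpp_config`.
#' @export
lpp_config <- function(ionizable_mw,
                       amines_per_lipid = 1,
                       mean_nt_mw = 330,
                       dope_mw = 744.03,
                       cholesterol_mw = 386.65,
                       mpeg_dmg_mw = 2509.2,
                       np_ratio = 4.8,
                       mole_fractions = c(ionizable = 40, dope = 15,
                                          cholesterol = 43.5, mpeg_dmg = 1.5),
                       protamine_volume_ratio = 5,
                       aqueous_ethanol_ratio = 3,
                       mrna_conc_ug_ul = 0.5) {
  mws <- c(ionizable = ionizable_mw, dope = dope_mw,
           cholesterol = cholesterol_mw, mpeg_dmg = mpeg_dmg_mw,
           mean_nt = mean_nt_mw)
  if (any(mws <= 0)) stop("molar masses must be positive", call. = FALSE)
  if (amines_per_lipid <= 0) stop("amines_per_lipid must be positive",
                                  call. = FALSE)
  if (abs(sum(mole_fractions) - 100) > 1e-9)
    stop("lipid mole fractions must sum to 100", call. = FALSE)
  structure(list(ionizable_mw = ionizable_mw,
                 amines_per_lipid = amines_per_lipid,
                 mean_nt_mw = mean_nt_mw, dope_mw = dope_mw,
                 cholesterol_mw = cholesterol_mw, mpeg_dmg_mw = mpeg_dmg_mw,
                 np_ratio = np_ratio, mole_fractions = mole_fractions,
                 protamine_volume_ratio = protamine_volume_ratio,
                 aqueous_ethanol_ratio = aqueous_ethanol_ratio,
                 mrna_conc_ug_ul = mrna_conc_ug_ul),
            class = "lpp_config")
}

#' Per-batch lipopolyplex recipe from the mRNA mass
#'
#' Everything follows from the mRNA mass by closed-form arithmetic:
#' phosphate moles = mass / mean nucleotide molar mass; ionizable-lipid moles
#' = N:P ratio x phosphate moles / amines per lipid; the other lipids scale
#' from the ionizable lipid's 40 mol% by the configured mole fractions;
#' masses are moles x molar mass. Volumes derive from the working mRNA
#' concentration and the 5:1 (mRNA:protamine, v/v) and 3:1 (aqueous:ethanol)
#' ratios. Mole fractions and the N:P ratio recomputed from the emitted
#' masses reproduce the configuration exactly.
#'
#' @param mrna_mass_ug mRNA mass in micrograms (>= 0).
#' @param config an [lpp_config()].
#' @return list of class `lpp_recipe`: `mrna_mass_ug`, `phosphate_umol`,
#'   `component_umol`, `component_masses_ug` (ionizable, dope, cholesterol,
#'   mpeg_dmg), `volumes_ul` (mrna, protamine, aqueous, ethanol), `np_ratio`,
#'   `mole_fractions`, `config`.
#' @export
lpp_recipe <- function(mrna_mass_ug, config) {
  if (!inherits(config, "lpp_config")) stop("config must be an lpp_config",
                                            call. = FALSE)
  if (mrna_mass_ug < 0) stop("mRNA mass must be >= 0", call. = FALSE)
  phosphate_umol <- mrna_mass_ug / config$mean_nt_mw
  ionizable_umol <- config$np_ratio * phosphate_umol / config$amines_per_lipid
  frac <- config$mole_fractions
  total_umol <- ionizable_umol / (frac[["ionizable"]] / 100)
  umol <- total_umol * frac / 100
  mws <- c(ionizable = config$ionizable_mw, dope = config$dope_mw,
           cholesterol = config$cholesterol_mw, mpeg_dmg = config$mpeg_dmg_mw)
  masses <- umol * mws[names(umol)]
  v_mrna <- mrna_mass_ug / config$mrna_conc_ug_ul
  v_prot <- v_mrna / config$protamine_volume_ratio
  v_aq <- v_mrna + v_prot
  v_eth <- v_aq / config$aqueous_ethanol_ratio
  structure(list(mrna_mass_ug = mrna_mass_ug,
                 phosphate_umol = phosphate_umol,
                 component_umol = umol,
                 component_masses_ug = masses,
                 volumes_ul = c(mrna = v_mrna, protamine = v_prot,
                                aqueous = v_aq, ethanol = v_eth),
                 np_ratio = config$np_ratio,
                 mole_fractions = frac,
                 config = config),
            class = "lpp_recipe")
}

#' Back-compute mole fractions and N:P ratio from emitted masses
#'
#' Inverts [lpp_recipe()]: converts the per-component masses back to moles
#' with the configured molar masses and reports each lipid's mole percentage
#' and the amine:phosphate ratio. Used as the recipe's round-trip check.
#'
#' @param recipe an `lpp_recipe`.
#' @return list `mole_fractions` (percent) and `np_ratio`.
#' @export
lpp_check_recipe <- function(recipe) {
  cfg <- recipe$config
  mws <- c(ionizable = cfg$ionizable_mw, dope = cfg$dope_mw,
           cholesterol = cfg$cholesterol_mw, mpeg_dmg = cfg$mpeg_dmg_mw)
  umol <- recipe$component_masses_ug / mws[names(recipe$component_masses_ug)]
  fractions <- 100 * umol / sum(umol)
  amine_umol <- umol[["ionizable"]] * cfg$amines_per_lipid
  phosphate_umol <- recipe$mrna_mass_ug / cfg$mean_nt_mw
  list(mole_fractions = fractions,
       np_ratio = if (phosphate_umol > 0) amine_umol / phosphate_umol
                  else NA_real_)
}

#' Write a recipe report (YAML or TSV)
#' @param recipe an `lpp_recipe`.
#' @param path output file; extension `.yaml`/`.yml` selects YAML, else TSV.
#' @return `path`, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  if (grepl("\\.ya?ml$", path)) {
    out <- recipe[c("mrna_mass_ug", "phosphate_umol", "np_ratio")]
    out$component_umol <- as.list(recipe$component_umol)
    out$component_masses_ug <- as.list(recipe$component_masses_ug)
    out$volumes_ul <- as.list(recipe$volumes_ul)
    out$mole_fractions <- as.list(recipe$mole_fractions)
    yaml::write_yaml(out, path)
  } else {
    df <- data.frame(component = names(recipe$component_masses_ug),
                     umol = as.numeric(recipe$component_umol),
                     mass_ug = as.numeric(recipe$component_masses_ug))
    con <- file(path, "w")
    writeLines(sprintf("# mrna_mass_ug=%g np_ratio=%g", recipe$mrna_mass_ug,
                       recipe$np_ratio), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Call ELISpot responders
#'
#' Per group, the negative-control mean is subtracted from each peptide's
#' mean spot count (`normalized = max(0, mean - negative mean)`); a peptide
#' is a responder when its mean is at least `fold_threshold` times the
#' negative-control mean and its normalized count is at least
#' `abs_threshold` spots per well. This 2x / 10-spot rule is a standard
#' ELISpot convention, configurable and echoed in the output.
#'
#' @param table ELISpot data.frame ([read_elispot()] columns).
#' @param fold_threshold fold-over-negative threshold F (default 2).
#' @param abs_threshold absolute normalized threshold A in spots/well
#'   (default 10).
#' @return data.frame: `group`, `peptide_id`, `mean_spots`,
#'   `neg_control_mean`, `normalized_spots`, `is_responder`, plus the rule
#'   parameters as attributes `fold_threshold`, `abs_threshold`.
#' @export
call_responders <- function(table, fold_threshold = 2, abs_threshold = 10) {
  if (any(table$spot_count < 0)) stop("negative spot_count", call. = FALSE)
  rows <- list()
  for (g in unique(table$group)) {
    tg <- table[table$group == g, ]
    neg <- tg$spot_count[tg$is_negative_control]
    if (!length(neg)) stop("group '", g, "' lacks a negative control",
                           call. = FALSE)
    neg_mean <- mean(neg)
    peptides <- unique(tg$peptide_id[!tg$is_negative_control &
                                     !tg$is_positive_control])
    for (p in peptides) {
      m <- mean(tg$spot_count[tg$peptide_id == p & !tg$is_negative_control &
                              !tg$is_positive_control])
      norm <- max(0, m - neg_mean)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, peptide_id = p, mean_spots = m, neg_control_mean = neg_mean,
        normalized_spots = norm,
        is_responder = (m >= fold_threshold * neg_mean) && (norm >= abs_threshold),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "abs_threshold") <- abs_threshold
  out
}

#' Responder rate with exact binomial confidence interval
#'
#' `100 * n_responders / n_evaluable`, rounded to one decimal as reported,
#' with the Clopper-Pearson 95% interval.
#'
#' @param n_resp number of responding peptides.
#' @param n_eval number of evaluable peptides (>= 1).
#' @param conf_level confidence level (default 0.95).
#' @return list `percent` (one decimal), `percent_exact`, `ci_low`, `ci_high`
#'   (percent), `n_resp`, `n_eval`.
#' @export
#' @examples
#' responder_rate(10, 19)$percent  # 52.6
#' responder_rate(26, 60)$percent  # 43.3
responder_rate <- function(n_resp, n_eval, conf_level = 0.95) {
  if (n_eval < 1) stop("n_eval must be >= 1", call. = FALSE)
  if (n_resp < 0 || n_resp > n_eval)
    stop("n_resp must lie in [0, n_eval]", call. = FALSE)
  ci <- binom.test(n_resp, n_eval, conf.level = conf_level)$conf.int
  pct <- 100 * n_resp / n_eval
  list(percent = round(pct, 1), percent_exact = pct,
       ci_low = 100 * ci[1], ci_high = 100 * ci[2],
       n_resp = n_resp, n_eval = n_eval)
}

#' Tumor volume from caliper measurements
#'
#' `V = 1/2 x Length x Width^2` (mm^3). If width exceeds length the two are
#' swapped, with a warning, per the caliper convention that length is the
#' longer axis.
#'
#' @param length_mm,width_mm caliper measurements in mm (non-negative).
#' @return volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("negative caliper measurement", call. = FALSE)
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length; swapping per convention")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Tumor growth inhibition
#'
#' `TGI = 100 * (1 - treated / control)` on tumor-burden group means.
#'
#' @param mean_treated,mean_control group means (control > 0).
#' @return TGI in percent.
#' @export
tgi <- function(mean_treated, mean_control) {
  if (any(mean_control <= 0)) stop("control mean must be positive",
                                   call. = FALSE)
  if (any(mean_treated < 0)) stop("treated mean must be >= 0", call. = FALSE)
  100 * (1 - mean_treated / mean_control)
}
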