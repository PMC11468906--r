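#' Configuration for an end-to-end design run
#'
#' A flat, fully serializable parameter set: the emitted manifest contains
#' every field and [replay_manifest()] reproduces the run from it.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving every random stage.
#' @param simulate generate a synthetic cohort (`TRUE`) or read the four
#'   input files from `inputs`.
#' @param n_transcripts,n_variants synthetic cohort size.
#' @param cohort named list of [cohort_params()] overrides (primitives only).
#' @param inputs named list of paths (`cds`, `variants`, `expression`, `hla`)
#'   when `simulate = FALSE`.
#' @param top_n number of neoantigens selected into the construct.
#' @param weights named composite-score weights (see [score_weights()]).
#' @param filters named list of hard-filter thresholds.
#' @param agretopicity_cap agretopicity for frameshift candidates.
#' @param construct named list of [construct_spec()] overrides.
#' @param pair_scores,min_hairpin energy model parameters.
#' @param lambda codon-design trade-off weight.
#' @param codon_method `"design"` (joint MFE/CAI optimization) or
#'   `"max_cai"` (naive most-frequent-codon reverse translation).
#' @param max_exact_nt,window_codons,overlap_codons design geometry.
#' @param mrna_mass_ug,ionizable_mw,amines_per_lipid,mean_nt_mw formulation
#'   batch parameters.
#' @param responder_fold,responder_abs ELISpot responder rule.
#' @param elispot optional path to an ELISpot TSV to analyze.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       simulate = TRUE,
                       n_transcripts = 30L,
                       n_variants = 40L,
                       cohort = list(),
                       inputs = list(),
                       top_n = 20L,
                       weights = as.list(score_weights()$weights),
                       filters = score_weights()$filters,
                       agretopicity_cap = 16,
                       construct = list(),
                       pair_scores = list(AU = -1, UA = -1, GC = -2, CG = -2,
                                          GU = -0.5, UG = -0.5),
                       min_hairpin = 3L,
                       lambda = 1,
                       codon_method = c("design", "max_cai"),
                       max_exact_nt = 300L,
                       window_codons = 60L,
                       overlap_codons = 20L,
                       mrna_mass_ug = 100,
                       ionizable_mw = 710,
                       amines_per_lipid = 1,
                       mean_nt_mw = 330,
                       responder_fold = 2,
                       responder_abs = 10,
                       elispot = NULL) {
  codon_method <- match.arg(codon_method)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              n_transcripts = as.integer(n_transcripts),
              n_variants = as.integer(n_variants),
              cohort = cohort, inputs = inputs, top_n = as.integer(top_n),
              weights = weights, filters = filters,
              agretopicity_cap = agretopicity_cap, construct = construct,
              pair_scores = pair_scores, min_hairpin = as.integer(min_hairpin),
              lambda = lambda, codon_method = codon_method,
              max_exact_nt = as.integer(max_exact_nt),
              window_codons = as.integer(window_codons),
              overlap_codons = as.integer(overlap_codons),
              mrna_mass_ug = mrna_mass_ug, ionizable_mw = ionizable_mw,
              amines_per_lipid = amines_per_lipid, mean_nt_mw = mean_nt_mw,
              responder_fold = responder_fold, responder_abs = responder_abs,
              elispot = elispot)
  class(cfg) <- "run_config"
  cfg
}

# hash of the configuration, stamped into the manifest
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small rolling hash; stdlib-only and stable across platforms
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full in-silico vaccine-design pipeline
#'
#' Chains simulate/read, peptide extraction, ranking, construct assembly,
#' codon design, and formulation arithmetic, writing every artifact plus a
#' manifest under `config$out_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return list (invisible): `cohort`, `peptides`, `ranking`, `orf`,
#'   `construct`, `design_metrics`, `recipe`, `responders` (or NULL),
#'   `manifest_path`, `paths`.
#' @export
run_design <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  ## ---- inputs ----
  if (isTRUE(config$simulate)) {
    cohort <- generate_cohort(config$seed, config$n_transcripts,
                              config$n_variants,
                              do.call(cohort_params, config$cohort))
    paths$inputs <- write_cohort(cohort, file.path(config$out_dir, "inputs"))
  } else {
    need <- c("cds", "variants", "expression", "hla")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop("stage inputs: missing paths: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    transcripts <- read_cds_fasta(config$inputs$cds)
    cohort <- list(transcripts = transcripts,
                   variants = read_variant_table(config$inputs$variants,
                                                 transcripts),
                   expression = read_expression_table(config$inputs$expression),
                   hla_alleles = read_hla_list(config$inputs$hla),
                   pwm_set = NULL, seed = config$seed)
    class(cohort) <- "neovax_cohort"
  }
  pwm_set <- cohort$pwm_set %||%
    make_toy_pwm_set(cohort$hla_alleles, seed = config$seed + 1L)
  predictor <- make_toy_predictor(pwm_set)
  allele_info <- pwm_set_lengths(pwm_set)

  ## ---- peptides ----
  peptides <- peptides_from_cohort(cohort$transcripts, cohort$variants)
  if (nrow(peptides) == 0L)
    stop("stage peptides: no usable (non-synonymous) variants", call. = FALSE)
  paths$peptides <- write_peptides(peptides,
                                   file.path(config$out_dir, "peptides"))

  ## ---- ranking ----
  w <- score_weights(weights = unlist(config$weights),
                     max_vaf_normal_dna = config$filters$max_vaf_normal_dna,
                     min_vaf_tumor_dna = config$filters$min_vaf_tumor_dna,
                     min_expr_tpm = config$filters$min_expr_tpm,
                     max_best_mut_affinity_nM = config$filters$max_best_mut_affinity_nM,
                     agretopicity_cap = config$agretopicity_cap)
  features <- build_feature_vectors(peptides, cohort$expression, allele_info,
                                    predictor, w)
  ranking <- rank_and_select(features, w, config$top_n)
  paths$ranking <- write_ranking(ranking, file.path(config$out_dir,
                                                    "candidates"))
  if (nrow(ranking$selected) == 0L)
    stop("stage rank: no candidate passed the hard filters (see ",
         paths$ranking["attrition"], ")", call. = FALSE)

  ## ---- construct assembly + codon design ----
  spec <- do.call(construct_spec, config$construct)
  model <- energy_model(unlist(config$pair_scores), config$min_hairpin)
  usage <- read_codon_usage()
  sel_pep <- setNames(ranking$selected$mut_peptide, ranking$selected$id)
  orf <- assemble_orf(sel_pep, spec)
  if (config$codon_method == "design") {
    des <- design(orf$orf_aa, usage, model, config$lambda,
                  config$max_exact_nt, config$window_codons,
                  config$overlap_codons)
    codon_fn <- function(p) des$rna_codons
    metrics <- data.frame(mode = des$mode, mfe_proxy = des$mfe_proxy,
                          cai = des$cai, lambda = des$lambda,
                          objective = des$objective,
                          orf_aa_len = nchar(orf$orf_aa))
    des_structure <- des$structure
  } else {
    rna_cds <- reverse_translate_max_cai(orf$orf_aa, usage)
    codon_fn <- function(p) rna_cds
    fold <- fold_mfe(rna_cds, model)
    metrics <- data.frame(mode = "max_cai", mfe_proxy = fold$score,
                          cai = cai(rna_cds, usage), lambda = NA_real_,
                          objective = NA_real_,
                          orf_aa_len = nchar(orf$orf_aa))
    des_structure <- fold$structure
  }
  construct <- build_mrna(orf, spec, codon_fn, usage)
  paths$construct <- c(
    fasta = write_construct(construct,
                            file.path(config$out_dir, "construct.fasta"),
                            "fasta"),
    genbank = write_construct(construct,
                              file.path(config$out_dir, "construct.gb"),
                              "genbank"),
    regions = write_construct(construct,
                              file.path(config$out_dir, "construct_regions.tsv"),
                              "tsv"))
  paths$design_metrics <- file.path(config$out_dir, "design_metrics.tsv")
  write.table(metrics, paths$design_metrics, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$structure <- file.path(config$out_dir, "orf_structure.txt")
  writeLines(des_structure, paths$structure)

  ## ---- formulation ----
  recipe <- lpp_recipe(config$mrna_mass_ug,
                       lpp_config(ionizable_mw = config$ionizable_mw,
                                  amines_per_lipid = config$amines_per_lipid,
                                  mean_nt_mw = config$mean_nt_mw))
  paths$recipe <- write_recipe(recipe, file.path(config$out_dir,
                                                 "recipe.yaml"))

  ## ---- immunoassay stats (optional) ----
  responders <- NULL
  if (!is.null(config$elispot)) {
    responders <- call_responders(read_elispot(config$elispot),
                                  config$responder_fold, config$responder_abs)
    paths$responders <- file.path(config$out_dir, "responders.tsv")
    write.table(responders, paths$responders, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ## ---- manifest ----
  manifest <- list(
    package = "neovax",
    version = as.character(utils::packageVersion("neovax")),
    config_hash = .config_hash(config),
    config = unclass(config)
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(cohort = cohort, peptides = peptides, ranking = ranking,
                 orf = orf, construct = construct, design_metrics = metrics,
                 recipe = recipe, responders = responders,
                 manifest_path = paths$manifest, paths = paths))
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by [run_design()].
#' @param out_dir optional new output directory (defaults to the recorded
#'   one).
#' @return the [run_design()] result, invisibly.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  # jsonlite collapses empty named lists; restore expected types
  cfg$cohort <- as.list(cfg$cohort)
  cfg$inputs <- as.list(cfg$inputs)
  cfg$construct <- as.list(cfg$construct)
  cfg$weights <- as.list(cfg$weights)
  cfg$filters <- as.list(cfg$filters)
  cfg$pair_scores <- as.list(cfg$pair_scores)
  class(cfg) <- "run_config"
  run_design(cfg)
}
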