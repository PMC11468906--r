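#' Enumerate and score mutation-spanning sub-peptides
#'
#' Within a candidate window, all class I sub-peptides (8-11-mers) and class
#' II sub-peptides (15-mers) that contain the mutant residue are scored
#' against every allele; the best (lowest) affinity per class is returned.
#' Wild-type affinities come from the same coordinates on the wild-type
#' window. Frameshift candidates have no wild-type counterpart: the wild-type
#' best is reported absent.
#'
#' @param pair a `peptide_pair` (or any list with `mut_peptide`,
#'   `wt_peptide`, `mutant_offset`, `variant_class`).
#' @param allele_info data.frame with columns `allele`, `class` (`"I"` or
#'   `"II"`), `length` — e.g. [pwm_set_lengths()].
#' @param predictor function `(peptides, allele) -> affinity nM vector`.
#' @return list with `best_mut_affinity_nM`, `best_wt_affinity_nM` (NA when
#'   no wild-type window exists), `by_class` (data.frame per class), and
#'   `n_windows` (count of scored mutant sub-peptides, per allele).
#' @export
scan_subpeptides <- function(pair, allele_info, predictor) {
  n <- nchar(pair$mut_peptide)
  m <- pair$mutant_offset
  wt_ok <- !is.na(pair$wt_peptide) && !identical(pair$variant_class, "frameshift")
  wt_len <- if (wt_ok) nchar(pair$wt_peptide) else 0L

  windows_for <- function(L) {
    if (L > n) return(integer(0))
    lo <- max(1L, m - L + 1L)
    hi <- min(m, n - L + 1L)
    if (lo > hi) integer(0) else lo:hi
  }

  by_class <- list()
  n_windows <- 0L
  for (cls in unique(allele_info$class)) {
    info_c <- allele_info[allele_info$class == cls, , drop = FALSE]
    lens <- if (cls == "I") intersect(8:11, unique(info_c$length))
            else intersect(15L, unique(info_c$length))
    best_mut <- Inf; best_wt <- Inf; any_wt <- FALSE
    for (al in unique(info_c$allele)) {
      al_lens <- intersect(lens, info_c$length[info_c$allele == al])
      for (L in al_lens) {
        starts <- windows_for(L)
        if (!length(starts)) next
        mut_subs <- substring(pair$mut_peptide, starts, starts + L - 1L)
        n_windows <- n_windows + length(mut_subs)
        best_mut <- min(best_mut, predictor(mut_subs, al))
        if (wt_ok) {
          keep <- starts + L - 1L <= wt_len
          if (any(keep)) {
            wt_subs <- substring(pair$wt_peptide, starts[keep],
                                 starts[keep] + L - 1L)
            best_wt <- min(best_wt, predictor(wt_subs, al))
            any_wt <- TRUE
          }
        }
      }
    }
    by_class[[cls]] <- data.frame(
      class = cls,
      best_mut_affinity_nM = if (is.finite(best_mut)) best_mut else NA_real_,
      best_wt_affinity_nM = if (any_wt) best_wt else NA_real_,
      stringsAsFactors = FALSE)
  }
  by_class <- do.call(rbind, by_class)
  rownames(by_class) <- NULL
  list(
    best_mut_affinity_nM = suppressWarnings(min(by_class$best_mut_affinity_nM,
                                                na.rm = TRUE)),
    best_wt_affinity_nM = if (all(is.na(by_class$best_wt_affinity_nM)))
      NA_real_ else min(by_class$best_wt_affinity_nM, na.rm = TRUE),
    by_class = by_class,
    n_windows = n_windows
  )
}

#' Default composite-score weights and hard filters
#'
#' These weights are this package's documented, non-canonical defaults (the
#' weighting used by the original proprietary ranker is not public): binding
#' affinity 0.30, agretopicity 0.15, expression 0.15, RNA VAF 0.15, tumor-DNA
#' VAF 0.10, binding stability 0.05, immunogenicity 0.05, germline absence
#' 0.05. Hard filters follow common field practice: germline VAF at most
#' 0.02, tumor-DNA VAF at least 0.05, expression at least 1 TPM, best mutant
#' affinity at most 500 nM. Everything is configurable.
#'
#' @param weights named non-negative weights; normalized to sum to 1.
#' @param max_vaf_normal_dna,min_vaf_tumor_dna,min_expr_tpm,max_best_mut_affinity_nM
#'   hard-filter thresholds.
#' @param agretopicity_cap agretopicity value assigned when no wild-type
#'   affinity exists (frameshifts); default 16 saturates the transform.
#' @return list of class `score_weights`.
#' @export
score_weights <- function(weights = c(affinity = 0.30, agretopicity = 0.15,
                                      expression = 0.15, vaf_rna = 0.15,
                                      vaf_dna = 0.10, stability = 0.05,
                                      immunogenicity = 0.05, germline = 0.05),
                          max_vaf_normal_dna = 0.02,
                          min_vaf_tumor_dna = 0.05,
                          min_expr_tpm = 1,
                          max_best_mut_affinity_nM = 500,
                          agretopicity_cap = 16) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) stop("at least one positive weight", call. = FALSE)
  need <- c("affinity", "agretopicity", "expression", "vaf_rna", "vaf_dna",
            "stability", "immunogenicity", "germline")
  full <- setNames(numeric(length(need)), need)
  full[names(weights)] <- weights
  structure(list(weights = full / sum(full),
                 filters = list(
                   max_vaf_normal_dna = max_vaf_normal_dna,
                   min_vaf_tumor_dna = min_vaf_tumor_dna,
                   min_expr_tpm = min_expr_tpm,
                   max_best_mut_affinity_nM = max_best_mut_affinity_nM),
                 agretopicity_cap = agretopicity_cap),
            class = "score_weights")
}

#' Assemble per-candidate feature vectors
#'
#' Joins expression to the peptide table, scores mutation-spanning
#' sub-peptides against all alleles, and computes agretopicity (best
#' wild-type affinity over best mutant affinity; frameshifts get the
#' configured cap). Stability and immunogenicity are taken from optional
#' named vectors (by candidate `id`) and are otherwise NA, which the scorer
#' treats as neutral.
#'
#' @param peptides data.frame from [peptides_from_cohort()].
#' @param expression data.frame with `transcript_id`, `tpm`.
#' @param allele_info data.frame as in [scan_subpeptides()].
#' @param predictor affinity predictor function.
#' @param weights a `score_weights` (for the agretopicity cap).
#' @param stability,immunogenicity optional named numeric vectors keyed by id.
#' @return data.frame: peptides plus `expr_tpm`, `best_mut_affinity_nM`,
#'   `best_wt_affinity_nM`, `agretopicity`, `stability_halflife_h`,
#'   `immunogenicity_score`.
#' @export
build_feature_vectors <- function(peptides, expression, allele_info, predictor,
                                  weights = score_weights(),
                                  stability = NULL, immunogenicity = NULL) {
  tpm <- expression$tpm[match(peptides$transcript_id,
                              expression$transcript_id)]
  if (anyNA(tpm))
    stop("transcripts missing from expression table: ",
         paste(unique(peptides$transcript_id[is.na(tpm)]), collapse = ", "),
         call. = FALSE)
  scans <- lapply(seq_len(nrow(peptides)), function(i)
    scan_subpeptides(peptides[i, ], allele_info, predictor))
  best_mut <- vapply(scans, `[[`, 0, "best_mut_affinity_nM")
  best_wt <- vapply(scans, `[[`, 0, "best_wt_affinity_nM")
  agre <- ifelse(is.na(best_wt), weights$agretopicity_cap, best_wt / best_mut)
  out <- peptides
  out$expr_tpm <- tpm
  out$best_mut_affinity_nM <- best_mut
  out$best_wt_affinity_nM <- best_wt
  out$agretopicity <- agre
  out$stability_halflife_h <- if (is.null(stability)) NA_real_
                              else unname(stability[out$id])
  out$immunogenicity_score <- if (is.null(immunogenicity)) NA_real_
                              else unname(immunogenicity[out$id])
  out
}

#' Per-feature pool context for normalization
#'
#' Min and max of every min-max-normalized feature over the candidate pool.
#'
#' @param features data.frame from [build_feature_vectors()].
#' @return named list of `c(min, max)` pairs.
#' @export
make_pool_context <- function(features) {
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(0, 0) else range(x)
  }
  list(expr_tpm = rng(features$expr_tpm),
       vaf_tumor_rna = rng(features$vaf_tumor_rna),
       vaf_tumor_dna = rng(features$vaf_tumor_dna),
       vaf_normal_dna = rng(features$vaf_normal_dna),
       stability_halflife_h = rng(features$stability_halflife_h))
}

# min-max normalize with the documented degenerate-pool convention:
# a feature constant across the pool contributes 0.5 for every candidate
.minmax <- function(x, lim) {
  out <- ifelse(is.na(x), 0.5,
                if (diff(lim) <= 0) 0.5 else (x - lim[1]) / (lim[2] - lim[1]))
  pmin(1, pmax(0, out))
}

#' Composite neoantigen score
#'
#' Each feature is mapped to `[0, 1]` and combined linearly with the
#' configured weights: affinities through `max(0, 1 - log(aff)/log(50000))`,
#' agretopicity through `min(1, log2(ratio + 1)/4)`, VAFs, TPM and stability
#' min-max within the candidate pool (constant features count 0.5),
#' immunogenicity used as-is, and germline VAF contributing as one minus its
#' normalized value. Missing stability/immunogenicity count as neutral 0.5.
#'
#' @param features one or more feature rows ([build_feature_vectors()]).
#' @param weights a `score_weights`.
#' @param pool pool context from [make_pool_context()]; defaults to the pool
#'   spanned by `features` itself.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
composite_score <- function(features, weights = score_weights(),
                            pool = make_pool_context(features)) {
  aff_norm <- function(a) pmin(1, pmax(0, 1 - log(a) / log(50000)))
  f <- cbind(
    affinity = aff_norm(features$best_mut_affinity_nM),
    agretopicity = pmin(1, log2(features$agretopicity + 1) / 4),
    expression = .minmax(features$expr_tpm, pool$expr_tpm),
    vaf_rna = .minmax(features$vaf_tumor_rna, pool$vaf_tumor_rna),
    vaf_dna = .minmax(features$vaf_tumor_dna, pool$vaf_tumor_dna),
    stability = .minmax(features$stability_halflife_h,
                        pool$stability_halflife_h),
    immunogenicity = ifelse(is.na(features$immunogenicity_score), 0.5,
                            pmin(1, pmax(0, features$immunogenicity_score))),
    germline = 1 - .minmax(features$vaf_normal_dna, pool$vaf_normal_dna)
  )
  as.numeric(f %*% weights$weights[colnames(f)])
}

#' Filter, score, rank, and select the top candidates
#'
#' Candidates failing any hard filter are excluded with a machine-readable
#' reason listing every violated threshold. Survivors are scored with the
#' pool context of the surviving set, sorted by score (descending) with ties
#' broken by higher tumor-DNA VAF, then lower best mutant affinity, then
#' lexicographically smaller mutant peptide, and the top `top_n` are returned
#' in rank order.
#'
#' @param features data.frame from [build_feature_vectors()].
#' @param weights a `score_weights`.
#' @param top_n maximal number of selected candidates (default 20).
#' @return list of class `neovax_ranking`: `selected` (features +
#'   `composite_score` + `rank`), `attrition` (data.frame `id`, `reason`),
#'   `n_input`, `n_pass`.
#' @export
rank_and_select <- function(features, weights = score_weights(), top_n = 20L) {
  fl <- weights$filters
  reasons <- lapply(seq_len(nrow(features)), function(i) {
    r <- character(0)
    x <- features[i, ]
    if (x$vaf_normal_dna > fl$max_vaf_normal_dna)
      r <- c(r, sprintf("vaf_normal_dna=%.4g>max_vaf_normal_dna=%.4g",
                        x$vaf_normal_dna, fl$max_vaf_normal_dna))
    if (x$vaf_tumor_dna < fl$min_vaf_tumor_dna)
      r <- c(r, sprintf("vaf_tumor_dna=%.4g<min_vaf_tumor_dna=%.4g",
                        x$vaf_tumor_dna, fl$min_vaf_tumor_dna))
    if (x$expr_tpm < fl$min_expr_tpm)
      r <- c(r, sprintf("expr_tpm=%.4g<min_expr_tpm=%.4g",
                        x$expr_tpm, fl$min_expr_tpm))
    if (x$best_mut_affinity_nM > fl$max_best_mut_affinity_nM)
      r <- c(r, sprintf("best_mut_affinity_nM=%.4g>max_best_mut_affinity_nM=%.4g",
                        x$best_mut_affinity_nM, fl$max_best_mut_affinity_nM))
    r
  })
  fail <- lengths(reasons) > 0L
  attrition <- data.frame(
    id = features$id[fail],
    reason = vapply(reasons[fail], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  surv <- features[!fail, , drop = FALSE]
  if (nrow(surv) == 0L) {
    sel <- cbind(surv, composite_score = numeric(0), rank = integer(0))
    return(structure(list(selected = sel, attrition = attrition,
                          n_input = nrow(features), n_pass = 0L),
                     class = "neovax_ranking"))
  }
  surv$composite_score <- composite_score(surv, weights)
  ord <- order(-surv$composite_score, -surv$vaf_tumor_dna,
               surv$best_mut_affinity_nM, surv$mut_peptide,
               method = "radix")
  surv <- surv[ord, , drop = FALSE]
  sel <- utils::head(surv, top_n)
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  structure(list(selected = sel, attrition = attrition,
                 n_input = nrow(features), n_pass = nrow(surv)),
            class = "neovax_ranking")
}

#' Write ranked candidates and the filter-attrition log
#'
#' @param ranking a `neovax_ranking`.
#' @param prefix output path prefix (`<prefix>_ranked.tsv`,
#'   `<prefix>_attrition.tsv`).
#' @return named vector of paths, invisibly.
#' @export
write_ranking <- function(ranking, prefix) {
  paths <- c(ranked = paste0(prefix, "_ranked.tsv"),
             attrition = paste0(prefix, "_attrition.tsv"))
  write.table(ranking$selected, paths["ranked"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ranking$attrition, paths["attrition"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
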