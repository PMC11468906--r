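# Independent brute-force oracles. These deliberately avoid the package's
# dynamic programs: folding enumerates every nested structure explicitly,
# design enumerates every codon combination, and translation goes through
# seqinr's independent codon table.

# minimal folding score by explicit enumeration of all nested structures
brute_fold <- function(rna, model = energy_model()) {
  v <- strsplit(toupper(chartr("T", "U", rna)), "")[[1]]
  pm <- model$pair_matrix
  h <- model$min_hairpin
  n <- length(v)
  # all structures on [i, j] as lists of pair matrices (unambiguous
  # decomposition: rightmost base unpaired, or paired with some k)
  structs <- function(i, j) {
    if (j - i < h + 1) return(list(matrix(integer(0), ncol = 2)))
    out <- structs(i, j - 1)
    for (k in i:(j - h - 1)) {
      if (is.finite(pm[v[k], v[j]])) {
        for (L in structs(i, k - 1)) for (Rp in structs(k + 1, j - 1))
          out[[length(out) + 1L]] <- rbind(L, Rp, c(k, j))
      }
    }
    out
  }
  if (n < h + 2) return(0)
  all_s <- structs(1, n)
  min(vapply(all_s, function(s) {
    if (nrow(s) == 0) return(0)
    sum(pm[cbind(v[s[, 1]], v[s[, 2]])])
  }, 0))
}

# minimal joint objective by explicit product over all codon combinations
brute_design_objective <- function(peptide, usage, model, lambda) {
  aa <- strsplit(peptide, "")[[1]]
  sets <- lapply(aa, function(a) usage[usage$amino_acid == a, ])
  idx <- do.call(expand.grid, lapply(sets, function(s) seq_len(nrow(s))))
  best <- Inf
  for (r in seq_len(nrow(idx))) {
    cods <- mapply(function(s, i) s$codon[i], sets, as.integer(idx[r, ]))
    ws <- mapply(function(s, i) s$w[i], sets, as.integer(idx[r, ]))
    obj <- fold_mfe(paste(cods, collapse = ""), model)$score -
      lambda * sum(log(ws))
    if (obj < best) best <- obj
  }
  best
}

# independent translation (seqinr's own codon table), DNA input
oracle_translate <- function(dna) {
  aa <- seqinr::translate(strsplit(tolower(dna), "")[[1]])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

# brute-force enumeration of mutation-spanning sub-peptide windows
brute_windows <- function(n, m, lengths) {
  out <- list()
  for (L in lengths) {
    if (L > n) next
    for (s in 1:(n - L + 1)) if (s <= m && m <= s + L - 1)
      out[[length(out) + 1L]] <- c(start = s, len = L)
  }
  out
}

# small deterministic class-I-only PWM set shared across ranking tests
toy_ranking_model <- function(alleles = c("K1", "K2"), seed = 99) {
  make_toy_pwm_set(alleles, seed = seed)
}

`%+%` <- function(a, b) paste0(a, b)

# builds a candidate feature row directly, bypassing the sequence machinery
feature_row <- function(id, vaf_dna = 0.3, vaf_norm = 0, vaf_rna = 0.3,
                        tpm = 10, mut_aff = 50, wt_aff = 5000,
                        peptide = strrep("A", 27)) {
  data.frame(id = id, transcript_id = id, cds_pos = 1L, ref = "A", alt = "C",
             variant_class = "missense", mut_peptide = peptide,
             wt_peptide = peptide, window_start = 1L, mutant_offset = 14L,
             vaf_tumor_dna = vaf_dna, vaf_normal_dna = vaf_norm,
             vaf_tumor_rna = vaf_rna, expr_tpm = tpm,
             best_mut_affinity_nM = mut_aff, best_wt_affinity_nM = wt_aff,
             agretopicity = wt_aff / mut_aff,
             stability_halflife_h = NA_real_,
             immunogenicity_score = NA_real_,
             stringsAsFactors = FALSE)
}

random_peptide <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
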