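#' Base-pair energy model for the folding proxy
#'
#' A Nussinov-style pair-score model: each admissible pair contributes a
#' negative score (defaults: GC/CG -2, AU/UA -1, GU/UG -0.5) and any pair must
#' enclose at least `min_hairpin` bases. This model deliberately trades
#' thermodynamic fidelity for exhaustiveness: small instances can be verified
#' against brute-force enumeration, and the joint codon-design DP is exact
#' under it. A nearest-neighbor scorer can be plugged in for re-scoring, not
#' for the DP.
#'
#' @param pair_scores named numeric vector over the admissible pairs
#'   `AU, UA, GC, CG, GU, UG`; all must be negative.
#' @param min_hairpin minimal number of enclosed bases (>= 3).
#' @return list of class `energy_model` with a 4x4 score matrix (`Inf` marks
#'   forbidden pairs; base order A, C, G, U).
#' @export
energy_model <- function(pair_scores = c(AU = -1, UA = -1, GC = -2, CG = -2,
                                         GU = -0.5, UG = -0.5),
                         min_hairpin = 3L) {
  allowed <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (!all(names(pair_scores) %in% allowed))
    stop("pair scores allowed only for ", paste(allowed, collapse = ", "),
         call. = FALSE)
  if (any(pair_scores >= 0)) stop("pair scores must be negative", call. = FALSE)
  if (min_hairpin < 3L) stop("min_hairpin must be >= 3", call. = FALSE)
  m <- matrix(Inf, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (p in names(pair_scores))
    m[substr(p, 1, 1), substr(p, 2, 2)] <- pair_scores[[p]]
  structure(list(pair_matrix = m, pair_scores = pair_scores,
                 min_hairpin = as.integer(min_hairpin)),
            class = "energy_model")
}

#' Minimum folding score of an RNA under the pair-score model
#'
#' O(n^3) Nussinov-style dynamic program returning the minimal sum of pair
#' scores over nested structures and one optimal structure in dot-bracket
#' notation. The score is always <= 0; an empty string scores 0.
#'
#' @param rna RNA string (DNA input is transliterated).
#' @param model an [energy_model()].
#' @return list `score`, `structure`.
#' @export
#' @examples
#' fold_mfe("GGGAAACCC")$score  # -6: three GC pairs
fold_mfe <- function(rna, model = energy_model()) {
  rna <- dna_to_rna(rna)
  nussinov_fold_cpp(rna, model$pair_matrix, model$min_hairpin)
}

#' Jointly optimize folding energy and codon adaptation
#'
#' Chooses codons for `peptide` minimizing
#' `fold_score(sequence) - lambda * sum(log w(codon))`
#' over all synonymous codon choices. Up to `max_exact_nt` coding nucleotides
#' the optimum is exact: a Nussinov recursion over the codon lattice, where
#' each sequence position carries the set of codon-automaton states and the
#' codon choice is tracked consistently. Longer peptides are designed in
#' overlapping windows stitched at codon boundaries and re-scored globally;
#' the result is then flagged approximate.
#'
#' Ties on the objective are broken toward higher CAI; remaining ties resolve
#' through a fixed deterministic traceback order, so identical inputs always
#' give identical output.
#'
#' @param peptide amino-acid string (canonical residues).
#' @param usage a `codon_usage` table.
#' @param model an [energy_model()].
#' @param lambda non-negative weight of the codon-adaptation term (default 1).
#' @param max_exact_nt longest coding length designed exactly (default 300).
#' @param window_codons,overlap_codons windowed-mode geometry (defaults 60/20).
#' @return list of class `design_result`: `rna_codons`, `mfe_proxy`,
#'   `structure`, `cai`, `lambda`, `objective`, `mode` (`"exact"` or
#'   `"windowed"`).
#' @export
design <- function(peptide, usage = read_codon_usage(),
                   model = energy_model(), lambda = 1,
                   max_exact_nt = 300L, window_codons = 60L,
                   overlap_codons = 20L) {
  if (!nzchar(peptide)) stop("peptide must be non-empty", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  n <- nchar(peptide)
  if (3L * n <= max_exact_nt) {
    rna <- .design_exact(peptide, usage, model, lambda)
    mode <- "exact"
  } else {
    step <- window_codons - overlap_codons
    if (step < 1L) stop("window_codons must exceed overlap_codons", call. = FALSE)
    starts <- seq(1L, n, by = step)
    starts <- starts[starts <= n]
    pieces <- character(0)
    done <- 0L
    for (s in starts) {
      if (done >= n) break
      e <- min(n, s + window_codons - 1L)
      wrna <- .design_exact(substr(peptide, s, e), usage, model, lambda)
      keep_from <- done - s + 2L          # codons after the already-emitted ones
      pieces <- c(pieces, substr(wrna, 3L * (keep_from - 1L) + 1L, nchar(wrna)))
      done <- e
    }
    rna <- paste(pieces, collapse = "")
    mode <- "windowed"
  }
  stopifnot(nchar(rna) == 3L * n)
  check <- translate_nt(rna, to_first_stop = FALSE)
  if (as.character(check) != toupper(peptide))
    stop("internal: designed sequence does not code for the peptide",
         call. = FALSE)
  fold <- fold_mfe(rna, model)
  sum_logw <- sum(.logw_lookup(codon_split(rna), usage))
  structure(list(rna_codons = rna,
                 mfe_proxy = fold$score,
                 structure = fold$structure,
                 cai = exp(sum_logw / n),
                 lambda = lambda,
                 objective = fold$score - lambda * sum_logw,
                 mode = mode),
            class = "design_result")
}

.design_exact <- function(peptide, usage, model, lambda) {
  choices <- codon_choices(peptide, usage)
  codon_sets <- lapply(choices, function(x) x$codon)
  logw <- unlist(lapply(choices, function(x) log(x$w)), use.names = FALSE)
  sizes <- vapply(choices, nrow, 0L)
  res <- lattice_design_cpp(codon_sets, logw, sizes,
                            model$pair_matrix, model$min_hairpin, lambda)
  res$rna
}
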