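#' Build a toy position-weight-matrix binding model
#'
#' A deterministic, seeded stand-in for an external peptide-MHC binding
#' predictor, used for tests and synthetic cohorts. Each allele gets one PWM
#' per supported peptide length: class I alleles score 8-11-mers, class II
#' alleles 15-mers. Class II is recognized by common label substrings
#' (`I-A`/`I-E`/`IAb`/`DR`/`DP`/`DQ`); everything else is class I.
#'
#' @param alleles character vector of allele labels (opaque, e.g. `H-2-Kb`).
#' @param seed integer seed; identical seeds give identical models.
#' @return object of class `toy_pwm_set`.
#' @export
make_toy_pwm_set <- function(alleles, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- list()
  for (al in alleles) {
    cls <- if (grepl("I-?A|I-?E|DR|DP|DQ", al)) "II" else "I"
    lens <- if (cls == "I") 8:11 else 15L
    pwms <- lapply(lens, function(L) {
      m <- matrix(rnorm(20L * L), nrow = 20L,
                  dimnames = list(AA_CANONICAL, NULL))
      m
    })
    names(pwms) <- as.character(lens)
    out[[al]] <- list(class = cls, pwms = pwms)
  }
  structure(list(alleles = out), class = "toy_pwm_set")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Alleles and peptide lengths supported by a PWM set
#' @param pwm_set a `toy_pwm_set`.
#' @return data.frame with columns `allele`, `class`, `length`.
#' @export
pwm_set_lengths <- function(pwm_set) {
  do.call(rbind, lapply(names(pwm_set$alleles), function(al) {
    a <- pwm_set$alleles[[al]]
    data.frame(allele = al, class = a$class,
               length = as.integer(names(a$pwms)),
               stringsAsFactors = FALSE)
  }))
}

#' Highest-scoring peptide of a toy PWM
#' @param pwm_set a `toy_pwm_set`.
#' @param allele allele label.
#' @param length peptide length.
#' @return amino-acid string achieving the maximal PWM score (affinity 1 nM).
#' @export
pwm_consensus <- function(pwm_set, allele, length = 9L) {
  a <- pwm_set$alleles[[allele]]
  if (is.null(a)) stop("no PWM for allele '", allele, "'; available: ",
                       paste(names(pwm_set$alleles), collapse = ", "),
                       call. = FALSE)
  m <- a$pwms[[as.character(length)]]
  if (is.null(m)) stop("allele '", allele, "' has no PWM of length ", length,
                       call. = FALSE)
  paste(rownames(m)[apply(m, 2L, which.max)], collapse = "")
}

#' Score peptides against a toy PWM model
#'
#' The raw PWM score is min-max normalized per matrix to `s` in `[0, 1]`
#' (sum of per-position minima maps to 0, maxima to 1), and the affinity is
#' `50000^(1 - s)` nM: a consensus peptide scores 1 nM, the worst possible
#' peptide 50,000 nM. Deterministic.
#'
#' @param peptide amino-acid string (vectorized).
#' @param allele allele label present in `pwm_set`.
#' @param pwm_set a `toy_pwm_set`.
#' @return data.frame with columns `peptide`, `allele`, `affinity_nM`,
#'   `score_norm`.
#' @export
toy_binding_predictor <- function(peptide, allele, pwm_set) {
  a <- pwm_set$alleles[[allele]]
  if (is.null(a)) stop("no PWM for allele '", allele, "'; available: ",
                       paste(names(pwm_set$alleles), collapse = ", "),
                       call. = FALSE)
  s <- vapply(peptide, function(p) {
    L <- nchar(p)
    m <- a$pwms[[as.character(L)]]
    if (is.null(m))
      stop("allele '", allele, "' has no PWM of length ", L,
           " (supported: ", paste(names(a$pwms), collapse = ", "), ")",
           call. = FALSE)
    aa <- strsplit(p, "")[[1]]
    if (!all(aa %in% AA_CANONICAL))
      stop("non-canonical residue in peptide '", p, "'", call. = FALSE)
    raw <- sum(m[cbind(match(aa, rownames(m)), seq_len(L))])
    lo <- sum(apply(m, 2L, min)); hi <- sum(apply(m, 2L, max))
    if (hi > lo) (raw - lo) / (hi - lo) else 1
  }, 0)
  data.frame(peptide = peptide, allele = allele,
             affinity_nM = 50000^(1 - s), score_norm = s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Turn a PWM set into a predictor function
#'
#' The returned closure has signature `function(peptides, allele)` and returns
#' a vector of affinities in nM — the pluggable interface that
#' [scan_subpeptides()] expects.
#'
#' @param pwm_set a `toy_pwm_set`.
#' @return function `(peptides, allele) -> numeric affinities (nM)`.
#' @export
make_toy_predictor <- function(pwm_set) {
  force(pwm_set)
  function(peptides, allele)
    toy_binding_predictor(peptides, allele, pwm_set)$affinity_nM
}

#' Read external binding predictions (NetMHCpan-style TSV)
#'
#' Minimally requires columns `peptide`, `allele`, `affinity_nM`; an optional
#' `percentile_rank` column is kept and extra columns are ignored.
#'
#' @param path TSV file.
#' @return data.frame of predictions.
#' @export
read_binding_tsv <- function(path) {
  b <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "affinity_nM")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("binding table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(b$affinity_nM <= 0)) stop("affinity_nM must be positive", call. = FALSE)
  if ("percentile_rank" %in% names(b) &&
      any(b$percentile_rank < 0 | b$percentile_rank > 100, na.rm = TRUE))
    stop("percentile_rank outside [0,100]", call. = FALSE)
  keep <- intersect(c("peptide", "allele", "affinity_nM", "percentile_rank",
                      "stability_halflife_h"), names(b))
  b[keep]
}

#' Turn an external prediction table into a predictor function
#'
#' Peptide/allele pairs absent from the table get `default_nM` (a weak,
#' filter-failing affinity) rather than an error, so partial external output
#' can still drive a ranking run.
#'
#' @param binding data.frame from [read_binding_tsv()].
#' @param default_nM affinity assigned to unlisted pairs (default 50000).
#' @return function `(peptides, allele) -> numeric affinities (nM)`.
#' @export
make_table_predictor <- function(binding, default_nM = 50000) {
  key <- paste(binding$peptide, binding$allele, sep = "\r")
  aff <- setNames(binding$affinity_nM, key)
  function(peptides, allele) {
    v <- aff[paste(peptides, allele, sep = "\r")]
    v[is.na(v)] <- default_nM
    unname(v)
  }
}
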