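#' Alignment scoring parameters
#'
#' BLASTN-like defaults: match +1, mismatch -2, and affine gaps costing
#' `gap_open + L * gap_extend` for a gap of length L. Ambiguous bases (N)
#' never count as a match and score as mismatches.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening cost (>= 0), charged once per gap.
#' @param gap_extend Gap extension cost (>= 0), charged per gap column.
#' @return A list of class `phgs_scoring`.
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap_open = 3L,
                          gap_extend = 1L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "phgs_scoring")
}

#' Local alignment of queries against a subject set
#'
#' Seed-and-extend local aligner: exact k-mer seeds select candidate subjects
#' and diagonals, and candidates are aligned with affine-gap Smith-Waterman
#' restricted to a band around the seed diagonals. Query/subject pairs whose
#' full dynamic-programming matrix is small (`max_cells_full` cells or fewer)
#' are aligned exhaustively without seeding, so small problems are exact.
#' Both strands are always searched; hits on the minus strand report query
#' coordinates on the original (forward) query.
#'
#' @param queries Tibble with columns `id`, `seq`, or a named character vector.
#' @param subjects Tibble with columns `id`, `seq`, or a named character vector.
#' @param scoring An [align_scoring()] object.
#' @param k Seed k-mer length (>= 8).
#' @param min_score Minimum raw score for a reported hit.
#' @param max_cells_full Total DP cell budget (`2 * sum(query lengths) *
#'   sum(subject lengths)`) under which the whole problem is aligned with
#'   full (unbanded, seed-free) dynamic programming; larger problems use
#'   seed-and-extend throughout.
#' @param band_extra Half-width added around seed diagonals for the banded
#'   extension (tolerates that many net inserted/deleted bases away from the
#'   seed diagonal).
#' @param seed_step Stride between query positions probed for seeds (1 probes
#'   every k-mer; the default 3 trades a little seed sensitivity for speed).
#' @param evalue_k Karlin-Altschul prefactor K for e-values.
#' @param lambda Karlin-Altschul lambda; `NULL` computes it numerically from
#'   the scoring parameters via [karlin_lambda()].
#' @param best_only Keep only the best hit per query (ties broken by lower
#'   e-value, then lexicographic subject id).
#' @return A tibble of hits: `query_id`, `subject_id`, `score`,
#'   `percent_identity` (all alignment columns in the denominator, gaps
#'   included), `aligned_length`, `e_value`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open), `strand`. Empty query or subject sets give
#'   an empty tibble.
#' @export
align_local <- function(queries, subjects, scoring = align_scoring(),
                        k = 11L, min_score = 30L, max_cells_full = 2e7,
                        band_extra = 4L, seed_step = 3L, evalue_k = 0.1,
                        lambda = NULL, best_only = FALSE) {
  queries <- as_seq_tibble(queries)
  subjects <- as_seq_tibble(subjects)
  stopifnot(k >= 8L)
  empty <- tibble(
    query_id = character(), subject_id = character(), score = integer(),
    percent_identity = numeric(), aligned_length = integer(),
    e_value = numeric(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), strand = character()
  )
  if (nrow(queries) == 0L || nrow(subjects) == 0L) return(empty)
  raw <- cpp_align_batch(queries$seq, subjects$seq,
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(k),
                         as.integer(min_score), max_cells_full,
                         as.integer(band_extra), as.integer(seed_step))
  if (nrow(raw) == 0L) return(empty)
  lambda <- lambda %||% karlin_lambda(scoring)
  db_len <- sum(nchar(subjects$seq))
  qlen <- nchar(queries$seq)[raw$query]
  hits <- tibble(
    query_id = queries$id[raw$query],
    subject_id = subjects$id[raw$subject],
    score = raw$score,
    percent_identity = 100 * raw$matches / raw$columns,
    aligned_length = raw$columns,
    e_value = estimate_evalue(raw$score,
                              evalue_params(K = evalue_k, lambda = lambda,
                                            m = qlen, n = db_len)),
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    strand = ifelse(raw$strand_sign > 0, "+", "-")
  )
  if (best_only) {
    hits <- hits |>
      arrange(.data$query_id, .data$e_value, .data$subject_id) |>
      distinct(.data$query_id, .keep_all = TRUE)
  }
  hits
}

#' Karlin-Altschul e-value parameters
#'
#' @param K Prefactor (> 0).
#' @param lambda Score scale (> 0).
#' @param m Query length in bases (>= 1); vectorised.
#' @param n Total database length in bases (>= 1).
#' @return A list of class `phgs_evalue_params`.
#' @export
evalue_params <- function(K, lambda, m, n) {
  stopifnot(K > 0, lambda > 0, all(m >= 1), n >= 1)
  structure(list(K = K, lambda = lambda, m = m, n = n),
            class = "phgs_evalue_params")
}

#' Karlin-Altschul e-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct local
#' alignments with score at least S between a random query of length m and a
#' random database of total length n. Monotone decreasing in S and linear in
#' both m and n.
#'
#' @param score Raw alignment score(s).
#' @param params An [evalue_params()] object.
#' @return Numeric e-value(s).
#' @export
estimate_evalue <- function(score, params) {
  stopifnot(inherits(params, "phgs_evalue_params"))
  params$K * params$m * params$n * exp(-params$lambda * score)
}

#' Ungapped Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` numerically for uniform
#' base frequencies (p = 1/4), the positive root of the ungapped score scale.
#'
#' @param scoring An [align_scoring()] object (only match/mismatch are used).
#' @return lambda (> 0).
#' @export
karlin_lambda <- function(scoring = align_scoring()) {
  f <- function(l) {
    0.25 * exp(l * scoring$match) + 0.75 * exp(l * scoring$mismatch) - 1
  }
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

as_seq_tibble <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  if (!all(c("id", "seq") %in% names(x))) {
    abort("sequence sets must be tibbles with columns 'id' and 'seq'")
  }
  x[, c("id", "seq")]
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
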