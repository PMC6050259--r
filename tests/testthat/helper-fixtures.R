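# Shared fixtures: everything is generated in code, no stored data.

random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A small, fast two-group cohort used by unit tests (not the study preset).
tiny_cohort_config <- function(seed = 1L, n_cases = 3L, n_controls = 3L,
                               depth = 8) {
  sim_config(
    n_cases = n_cases, n_controls = n_controls,
    genera = list(
      genus_spec("Lactococcus", "Streptococcaceae", genome_length = 1500L,
                 n_markers = 3L, marker_length = 200L),
      genus_spec("Bacteroides", "Bacteroidaceae", genome_length = 1500L,
                 n_markers = 3L, marker_length = 200L)
    ),
    phages = list(
      phage_spec("Lactococcus phage c2", "Lactococcus", "lytic",
                 "Siphoviridae", genome_length = 800L),
      phage_spec("Lactococcus phage TP901-1", "Lactococcus", "temperate",
                 "Siphoviridae", genome_length = 800L),
      phage_spec("Bacteroides phage b1", "Bacteroides", "lytic",
                 "Podoviridae", genome_length = 800L)
    ),
    base_abundance = tibble::tibble(
      taxon = c("Lactococcus", "Bacteroides", "Lactococcus phage c2",
                "Lactococcus phage TP901-1", "Bacteroides phage b1"),
      mu = log(c(0.4, 0.6, 0.3, 0.3, 0.4)),
      sigma = 0.4
    ),
    depth = depth, seed = seed
  )
}

# Long abundance tibble from a named matrix-like specification:
# make_abundance(list(s1 = c(a = 1, b = 2), s2 = c(a = 0, b = 3)))
make_abundance <- function(per_sample, value = "abundance") {
  out <- purrr::imap_dfr(per_sample, function(v, s) {
    tibble::tibble(taxon = names(v), sample = s, x = unname(v))
  })
  names(out)[3L] <- value
  out
}

# Biostrings local-alignment oracle: best score over both strands.
sw_oracle_score <- function(q, s, match = 1, mismatch = -2,
                            gap_open = 3, gap_extension = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  sc <- function(qq) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      qq, s, type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extension))
  }
  max(sc(q), sc(revcomp(q)))
}
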