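#' Classify contigs against a phage genome database
#'
#' Contigs longer than `min_length` bases (strictly) are aligned to the phage
#' database; a contig is assigned to the phage of its best hit (lowest
#' e-value, ties broken by lexicographic phage id) when the hit's e-value is
#' below `e_max` and its aligned length exceeds `min_frac` of the contig
#' length (both strict inequalities). Contigs failing any threshold are left
#' unassigned and absent from the result.
#'
#' @param contigs Tibble with columns `id`, `seq`.
#' @param phage_db Tibble with columns `phage_id`, `seq` (annotations ignored
#'   here).
#' @param e_max E-value threshold (hits must be strictly below).
#' @param min_length Minimum contig length in bases (strictly above).
#' @param min_frac Minimum aligned fraction of contig length (strictly above).
#' @param ... Passed to [align_local()] (scoring, seeding, e-value model).
#' @return A tibble `contig_id`, `phage_id`, `score`, `e_value`,
#'   `percent_identity`, `aligned_length`, `contig_length`.
#' @export
classify_contigs <- function(contigs, phage_db, e_max = 1e-5,
                             min_length = 200L, min_frac = 0.5, ...) {
  stopifnot(e_max > 0, min_length > 0, min_frac > 0, nrow(phage_db) > 0)
  keep <- nchar(contigs$seq) > min_length
  contigs <- contigs[keep, , drop = FALSE]
  empty <- tibble(contig_id = character(), phage_id = character(),
                  score = integer(), e_value = numeric(),
                  percent_identity = numeric(), aligned_length = integer(),
                  contig_length = integer())
  if (nrow(contigs) == 0L) return(empty)
  db <- tibble(id = phage_db$phage_id, seq = phage_db$seq)
  hits <- align_local(contigs[, c("id", "seq")], db, best_only = TRUE, ...)
  if (nrow(hits) == 0L) return(empty)
  hits |>
    mutate(contig_length = nchar(contigs$seq[match(.data$query_id, contigs$id)])) |>
    filter(.data$e_value < e_max,
           .data$aligned_length > min_frac * .data$contig_length) |>
    select(contig_id = "query_id", phage_id = "subject_id", "score",
           "e_value", "percent_identity", "aligned_length", "contig_length")
}

#' Recruit reads to phage-classified contigs
#'
#' Re-maps all reads against the contigs that received a phage assignment;
#' each read is assigned to at most one contig (best score; ties broken by
#' lower e-value then lexicographic contig id) and unmapped reads are
#' dropped. Identity and aligned length are retained per read for the
#' detection threshold.
#'
#' @param reads Tibble with columns `read_id`, `sample`, `seq`.
#' @param contigs Tibble with columns `id`, `seq`, restricted to assigned
#'   contigs (see [classify_contigs()]).
#' @param min_score Minimum alignment score to recruit a read.
#' @param ... Passed to [align_local()].
#' @return A tibble `read_id`, `sample`, `contig_id`, `score`,
#'   `percent_identity`, `aligned_length`.
#' @export
recruit_reads <- function(reads, contigs, min_score = 40L, ...) {
  empty <- tibble(read_id = character(), sample = character(),
                  contig_id = character(), score = integer(),
                  percent_identity = numeric(), aligned_length = integer())
  if (nrow(contigs) == 0L || nrow(reads) == 0L) return(empty)
  hits <- align_local(
    tibble(id = reads$read_id, seq = reads$seq),
    contigs[, c("id", "seq")],
    min_score = min_score, best_only = TRUE, ...
  )
  if (nrow(hits) == 0L) return(empty)
  hits |>
    mutate(sample = reads$sample[match(.data$query_id, reads$read_id)]) |>
    select(read_id = "query_id", "sample", contig_id = "subject_id",
           "score", "percent_identity", "aligned_length")
}

#' Combine recruited reads into per-phage counts
#'
#' The count of a phage in a sample is the number of reads recruited to any
#' contig assigned to that phage in that sample. Read-level identity and
#' aligned length are retained so [apply_detection_threshold()] can be applied
#' afterwards. Phages with no assigned contig are absent from the table.
#'
#' @param read_assignments Output of [recruit_reads()].
#' @param contig_assignments Output of [classify_contigs()].
#' @return An object of class `phgs_count_table`: a list with `counts`
#'   (tibble `taxon`, `sample`, `count`) and `reads` (read-level support
#'   tibble with `taxon`).
#' @export
count_phage_abundance <- function(read_assignments, contig_assignments) {
  reads <- read_assignments |>
    inner_join(contig_assignments[, c("contig_id", "phage_id")],
               by = "contig_id") |>
    rename(taxon = "phage_id")
  new_count_table(reads)
}

new_count_table <- function(reads) {
  counts <- reads |>
    dplyr::count(.data$taxon, .data$sample, name = "count") |>
    arrange(.data$taxon, .data$sample)
  structure(list(counts = counts, reads = reads), class = "phgs_count_table")
}

#' @export
print.phgs_count_table <- function(x, ...) {
  cat(sprintf("<phgs_count_table> %d taxa x %d samples, %d supporting reads\n",
              dplyr::n_distinct(x$counts$taxon),
              dplyr::n_distinct(x$counts$sample), nrow(x$reads)))
  print(x$counts, ...)
  invisible(x)
}

#' Apply the phage detection threshold
#'
#' A phage is detected in a sample only if at least `min_reads` reads support
#' it with identity strictly above `min_identity` percent over strictly more
#' than `min_aligned` bases; non-qualifying reads are discarded and
#' taxon/sample cells supported by fewer than `min_reads` qualifying reads
#' are zeroed (removed). Idempotent.
#'
#' @param x A `phgs_count_table` from [count_phage_abundance()].
#' @param min_reads Minimum qualifying reads per taxon and sample.
#' @param min_identity Percent identity bound (strict).
#' @param min_aligned Aligned length bound in bases (strict); set
#'   `apply_length_rule = FALSE` to disable for reads shorter than the bound.
#' @param apply_length_rule Whether to enforce the aligned-length clause.
#' @return A filtered `phgs_count_table`.
#' @export
apply_detection_threshold <- function(x, min_reads = 2L, min_identity = 90,
                                      min_aligned = 100L,
                                      apply_length_rule = TRUE) {
  stopifnot(inherits(x, "phgs_count_table"))
  reads <- x$reads |> filter(.data$percent_identity > min_identity)
  if (apply_length_rule) {
    reads <- reads |> filter(.data$aligned_length > min_aligned)
  }
  reads <- reads |>
    group_by(.data$taxon, .data$sample) |>
    filter(n() >= min_reads) |>
    ungroup()
  new_count_table(reads)
}

#' Normalize a count table to per-sample relative abundance
#'
#' @param x A `phgs_count_table` or a long counts tibble (`taxon`, `sample`,
#'   `count`).
#' @param samples Optional full sample vector so samples with zero counts are
#'   retained (as all-zero columns, with a warning).
#' @return Long tibble `taxon`, `sample`, `abundance`; per-sample sums are 1
#'   (all-zero samples are emitted as zeros with a warning).
#' @export
relative_abundance <- function(x, samples = NULL) {
  counts <- if (inherits(x, "phgs_count_table")) x$counts else x
  if (!is.null(samples)) {
    missing <- setdiff(samples, counts$sample)
    if (length(missing)) {
      filler <- if (nrow(counts)) counts$taxon[1L] else "none"
      counts <- bind_rows(counts,
                          tibble(taxon = filler, sample = missing, count = 0))
    }
  }
  out <- counts |>
    group_by(.data$sample) |>
    mutate(total = sum(.data$count)) |>
    ungroup()
  zero <- unique(out$sample[out$total == 0])
  if (length(zero)) {
    warn(sprintf("all-zero sample(s) kept as zeros: %s",
                 paste(zero, collapse = ", ")))
  }
  out |>
    mutate(abundance = ifelse(.data$total > 0, .data$count / .data$total, 0)) |>
    select("taxon", "sample", "abundance")
}

#' Remove taxa below an abundance floor in every sample
#'
#' A taxon survives iff its relative abundance reaches `floor` in at least
#' one sample. Idempotent.
#'
#' @param tbl Long relative-abundance tibble (`taxon`, `sample`, `abundance`).
#' @param floor Abundance floor (default 1e-4).
#' @return The filtered tibble.
#' @export
prevalence_filter <- function(tbl, floor = 1e-4) {
  if (nrow(tbl) == 0L) return(tbl)
  tbl |>
    group_by(.data$taxon) |>
    filter(max(.data$abundance) >= floor) |>
    ungroup()
}

#' Per-group presence and exclusivity screen
#'
#' A species is *present* in a group when at least `min_samples` samples of
#' that group have relative abundance at or above `min_abund`; it is
#' *exclusive* to a group when present there and in no other group.
#'
#' @param tbl Long relative-abundance tibble (`taxon`, `sample`, `abundance`).
#' @param metadata Tibble `sample_id`, `group`.
#' @param min_abund Presence abundance threshold (default 1e-4, i.e. 0.01%).
#' @param min_samples Minimum samples per group (default 2).
#' @return Tibble `taxon`, `group`, `n_detected`, `present`, `exclusive`.
#' @export
group_presence_screen <- function(tbl, metadata, min_abund = 1e-4,
                                  min_samples = 2L) {
  check_metadata(metadata, unique(tbl$sample))
  screen <- tbl |>
    left_join(metadata, by = c(sample = "sample_id")) |>
    group_by(.data$taxon, .data$group) |>
    summarise(n_detected = sum(.data$abundance >= min_abund), .groups = "drop") |>
    tidyr::complete(taxon = unique(tbl$taxon),
                    group = unique(metadata$group),
                    fill = list(n_detected = 0L)) |>
    mutate(present = .data$n_detected >= min_samples) |>
    group_by(.data$taxon) |>
    mutate(exclusive = .data$present & sum(.data$present) == 1L) |>
    ungroup() |>
    arrange(.data$taxon, .data$group)
  screen
}

#' Aggregate a phage abundance table to family level
#'
#' Family abundance is the sum of member phage abundances; phages without a
#' family annotation are pooled into `"unclassified"`.
#'
#' @param tbl Long abundance tibble (`taxon`, `sample`, value column).
#' @param phage_db Tibble with columns `phage_id`, `family`.
#' @return Long tibble with family-level taxa.
#' @export
aggregate_by_family <- function(tbl, phage_db) {
  value <- abundance_value_col(tbl)
  fam <- phage_db$family[match(tbl$taxon, phage_db$phage_id)]
  fam[is.na(fam) | fam == ""] <- "unclassified"
  tbl |>
    mutate(taxon = fam) |>
    group_by(.data$taxon, .data$sample) |>
    summarise(dplyr::across(dplyr::all_of(value), sum), .groups = "drop") |>
    arrange(.data$taxon, .data$sample)
}

#' Quantify phage abundance from contigs and reads
#'
#' Convenience wrapper running the full custom quantification chain:
#' [classify_contigs()] on contigs > 200 bases against the phage database
#' (e-value < 1e-5, aligned length > 50% of contig length), [recruit_reads()]
#' of all reads to the assigned contigs, [count_phage_abundance()],
#' [apply_detection_threshold()] (2 reads, identity > 90%, aligned length
#' > 100 bases), [relative_abundance()] and [prevalence_filter()].
#'
#' @param contigs,reads,phage_db See the individual steps.
#' @param e_max,min_contig,min_frac Contig classification thresholds.
#' @param min_reads,min_identity,min_aligned Detection thresholds.
#' @param prevalence_floor Floor for [prevalence_filter()].
#' @param min_score Read recruitment score threshold.
#' @return A list with `contig_assignments`, `counts` (thresholded
#'   `phgs_count_table`), and `abundance` (filtered relative table).
#' @export
quantify_phages <- function(contigs, reads, phage_db, e_max = 1e-5,
                            min_contig = 200L, min_frac = 0.5,
                            min_reads = 2L, min_identity = 90,
                            min_aligned = 100L, prevalence_floor = 1e-4,
                            min_score = 40L) {
  ca <- classify_contigs(contigs, phage_db, e_max = e_max,
                         min_length = min_contig, min_frac = min_frac)
  assigned <- contigs |> filter(.data$id %in% ca$contig_id)
  ra <- recruit_reads(reads, assigned, min_score = min_score)
  counts <- count_phage_abundance(ra, ca) |>
    apply_detection_threshold(min_reads = min_reads,
                              min_identity = min_identity,
                              min_aligned = min_aligned)
  abundance <- relative_abundance(counts, samples = unique(reads$sample)) |>
    prevalence_filter(floor = prevalence_floor)
  list(contig_assignments = ca, counts = counts, abundance = abundance)
}
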