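#' Profile bacterial relative abundance from clade-specific markers
#'
#' A simplified marker-gene profiler: reads are aligned to the marker
#' database, reads hitting markers of more than one genus are discarded
#' (clade-specific markers should not share reads), and each remaining read
#' contributes its aligned bases to its best marker. A clade's abundance is
#' proportional to its mean per-base marker coverage (total aligned bases on
#' the clade's markers divided by total marker length), normalized to sum 1
#' per sample. The family table sums member genera.
#'
#' @param reads Tibble `read_id`, `sample`, `seq`.
#' @param marker_db Tibble `marker_id`, `genus`, `family`, `seq` (see
#'   [simulate_cohort()]'s `marker_db`, or build from FASTA + clade TSV).
#' @param min_score Minimum alignment score for a read-marker hit.
#' @param ... Passed to [align_local()].
#' @return Long tibble `rank` (`"genus"`/`"family"`), `taxon`, `sample`,
#'   `abundance`; per-sample genus abundances sum to 1 and family abundances
#'   are exact sums of member genera. Empty (with a warning) when no read
#'   maps.
#' @export
profile_markers <- function(reads, marker_db, min_score = 40L, ...) {
  stopifnot(nrow(marker_db) > 0)
  empty <- tibble(rank = character(), taxon = character(),
                  sample = character(), abundance = numeric())
  if (nrow(reads) == 0L) {
    warn("no reads supplied; empty profile")
    return(empty)
  }
  hits <- align_local(
    tibble(id = reads$read_id, seq = reads$seq),
    tibble(id = marker_db$marker_id, seq = marker_db$seq),
    min_score = min_score, ...
  )
  if (nrow(hits) == 0L) {
    warn("no read maps to any marker; empty profile")
    return(empty)
  }
  hits <- hits |>
    mutate(genus = marker_db$genus[match(.data$subject_id, marker_db$marker_id)])
  multi <- hits |>
    distinct(.data$query_id, .data$genus) |>
    dplyr::count(.data$query_id) |>
    filter(.data$n > 1L)
  hits <- hits |>
    anti_join(multi, by = "query_id") |>
    arrange(.data$query_id, .data$e_value, .data$subject_id) |>
    distinct(.data$query_id, .keep_all = TRUE) |>
    mutate(sample = reads$sample[match(.data$query_id, reads$read_id)])

  marker_len <- marker_db |>
    group_by(.data$genus, .data$family) |>
    summarise(total_len = sum(nchar(.data$seq)), .groups = "drop")

  cov <- hits |>
    group_by(.data$sample, .data$genus) |>
    summarise(aligned_bases = sum(.data$aligned_length), .groups = "drop") |>
    left_join(marker_len, by = "genus") |>
    mutate(coverage = .data$aligned_bases / .data$total_len)

  genus_tbl <- cov |>
    group_by(.data$sample) |>
    mutate(abundance = .data$coverage / sum(.data$coverage)) |>
    ungroup() |>
    select(taxon = "genus", "sample", "abundance", "family")

  family_tbl <- genus_tbl |>
    group_by(taxon = .data$family, .data$sample) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop")

  bind_rows(
    genus_tbl |> mutate(rank = "genus") |> select("rank", "taxon", "sample", "abundance"),
    family_tbl |> mutate(rank = "family") |> select("rank", "taxon", "sample", "abundance")
  ) |>
    arrange(.data$rank, .data$taxon, .data$sample)
}

#' Load an externally produced taxonomic profile
#'
#' Adapter for MetaPhlAn-style tabular profiles: rows are clade strings
#' (`k__...|p__...|g__...`), columns are samples, values are relative
#' abundances in percent (or fractions). Values are normalized to fractions
#' per sample within each rank. Clade strings without the requested rank are
#' assigned to their nearest (deepest) named rank and flagged.
#'
#' @param path Path to a TSV whose first column is the clade string.
#' @param rank Rank letter to extract (`"g"` for genus, `"f"` for family...).
#' @return Long tibble `taxon`, `sample`, `abundance`, `clade`,
#'   `rank_fallback` (TRUE when the requested rank was absent and the nearest
#'   named rank was used).
#' @export
load_external_profile <- function(path, rank = "g") {
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  names(wide)[1L] <- "clade"
  if (anyDuplicated(wide$clade)) {
    abort(sprintf("duplicate clade rows in profile '%s'", path))
  }
  vals <- wide[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, TRUE))) {
    abort(sprintf("non-numeric abundance cells in profile '%s'", path))
  }
  parsed <- parse_clade(wide$clade, rank)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(clade = wide$clade,
                            taxon = parsed$taxon,
                            rank_fallback = parsed$fallback),
                     vals),
    -c("clade", "taxon", "rank_fallback"),
    names_to = "sample", values_to = "abundance"
  )
  long |>
    group_by(.data$sample) |>
    mutate(abundance = .data$abundance / sum(.data$abundance)) |>
    ungroup() |>
    select("taxon", "sample", "abundance", "clade", "rank_fallback")
}

# Clade string parsing rules: ranks are pipe-separated "<letter>__<name>"
# fields; the requested rank's name is returned, else the deepest named rank
# with fallback = TRUE.
parse_clade <- function(clades, rank) {
  taxon <- character(length(clades))
  fallback <- logical(length(clades))
  want <- paste0("^", rank, "__")
  for (i in seq_along(clades)) {
    parts <- strsplit(clades[i], "|", fixed = TRUE)[[1L]]
    hit <- grep(want, parts, value = TRUE)
    named <- parts[nchar(sub("^[a-z]__", "", parts)) > 0]
    if (length(hit) && nchar(sub("^[a-z]__", "", hit[1L])) > 0) {
      taxon[i] <- sub("^[a-z]__", "", hit[1L])
    } else if (length(named)) {
      taxon[i] <- sub("^[a-z]__", "", named[length(named)])
      fallback[i] <- TRUE
    } else {
      taxon[i] <- clades[i]
      fallback[i] <- TRUE
    }
  }
  list(taxon = taxon, fallback = fallback)
}

#' Write a genus/family profile as a MetaPhlAn-style TSV
#'
#' @param profile Output of [profile_markers()].
#' @param path Output path.
#' @param marker_db Marker database used, for family lookup in clade strings.
#' @param meta Header metadata, see [write_phagoscope_tsv()].
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, marker_db = NULL,
                              meta = character()) {
  gen <- profile |> filter(.data$rank == "genus")
  clade <- if (!is.null(marker_db)) {
    fam <- marker_db$family[match(gen$taxon, marker_db$genus)]
    sprintf("k__Bacteria|f__%s|g__%s", fam, gen$taxon)
  } else {
    sprintf("g__%s", gen$taxon)
  }
  wide <- gen |>
    mutate(clade = clade) |>
    select("clade", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "abundance",
                       values_fill = 0)
  write_phagoscope_tsv(wide, path, meta = meta)
}
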