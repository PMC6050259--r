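#' Shipped lactococcal phage lifestyle table
#'
#' Pattern-based lifestyle assignments for *Lactococcus* phages: the c2 and
#' 936 groups (including named dairy isolates such as sk1, bIL67, phi7, CB13,
#' jj50 and 645) are strictly virulent (lytic); the P335 group and the
#' bIL285-like prophages of *L. lactis* IL1403 are temperate. Users can
#' override with their own TSV (`phage_pattern`, `lifestyle`, `provenance`).
#'
#' @param path Optional path to a custom lifestyle TSV.
#' @return Tibble `phage_pattern`, `lifestyle`, `provenance`.
#' @export
lifestyle_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lactococcus_lifestyle.tsv",
                                package = "phagoscope")
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("phage_pattern", "lifestyle") %in% names(tb)),
            all(tb$lifestyle %in% c("lytic", "temperate")))
  tb
}

#' Cluster a phage abundance table by bacterial host genus
#'
#' Host-genus abundance is the sum of member phage abundances. The host comes
#' from the database's `host_genus` annotation; when that is empty the host is
#' derived from the phage naming convention ("<Genus> phage <name>"), and
#' phages with neither are pooled into `"unassigned_host"`. Total abundance
#' is conserved exactly.
#'
#' @param tbl Long phage abundance tibble (`taxon`, `sample`, value column).
#' @param phage_db Tibble with `phage_id` and (possibly empty) `host_genus`.
#' @return Long tibble with host genera as taxa.
#' @export
cluster_by_host <- function(tbl, phage_db) {
  value <- abundance_value_col(tbl)
  host <- phage_db$host_genus[match(tbl$taxon, phage_db$phage_id)]
  from_name <- stringr::str_match(tbl$taxon, "^(\\S+)\\s+phage\\b")[, 2L]
  host <- dplyr::coalesce(dplyr::na_if(host, ""), from_name, "unassigned_host")
  tbl |>
    mutate(taxon = host) |>
    group_by(.data$taxon, .data$sample) |>
    summarise(dplyr::across(dplyr::all_of(value), sum), .groups = "drop") |>
    arrange(.data$taxon, .data$sample)
}

#' Phage/bacteria ratio ("lytic potential") per host genus
#'
#' For each host genus, the ratio `R = A_phage / A_host` of the summed
#' relative abundance of the genus's phages to the relative abundance of the
#' genus itself, per sample and per group (group-level R uses group mean
#' abundances). `R = 1` (log10 R = 0) is the signature of a stably
#' integrated prophage; `R < 1` suggests the prophage is absent from part of
#' the host population; `R > 1` indicates partially lytic behavior. Zero
#' abundances give a status of `host_absent`, `phage_absent` or `both_absent`
#' with no finite R.
#'
#' @param phage_host_tbl Host-clustered phage relative abundance
#'   ([cluster_by_host()] output, `taxon` = host genus).
#' @param bacteria_tbl Bacterial genus relative abundance (`taxon`, `sample`,
#'   `abundance`).
#' @param metadata Tibble `sample_id`, `group`. Samples must agree between
#'   the two tables; a sample present in only one is an error.
#' @return A tibble of class `phgs_ratio`: `host_genus`, `level`
#'   (`"sample"`/`"group"`), `unit` (sample id or group label), `a_phage`,
#'   `a_host`, `ratio`, `log10_ratio`, `status`.
#' @export
phage_bacteria_ratio <- function(phage_host_tbl, bacteria_tbl, metadata) {
  s_p <- unique(phage_host_tbl$sample)
  s_b <- unique(bacteria_tbl$sample)
  if (length(setdiff(s_p, s_b)) || length(setdiff(s_b, s_p))) {
    abort(sprintf("sample sets differ between tables: %s",
                  paste(union(setdiff(s_p, s_b), setdiff(s_b, s_p)),
                        collapse = ", ")))
  }
  check_metadata(metadata, s_p)
  hosts <- intersect(unique(phage_host_tbl$taxon), unique(bacteria_tbl$taxon))

  grid_sample <- tidyr::expand_grid(host_genus = hosts, sample = s_p)
  per_sample <- grid_sample |>
    left_join(phage_host_tbl |> rename(host_genus = "taxon",
                                       a_phage = "abundance"),
              by = c("host_genus", "sample")) |>
    left_join(bacteria_tbl |> rename(host_genus = "taxon",
                                     a_host = "abundance"),
              by = c("host_genus", "sample")) |>
    mutate(a_phage = dplyr::coalesce(.data$a_phage, 0),
           a_host = dplyr::coalesce(.data$a_host, 0),
           level = "sample") |>
    rename(unit = "sample")

  per_group <- per_sample |>
    left_join(metadata, by = c(unit = "sample_id")) |>
    group_by(.data$host_genus, .data$group) |>
    summarise(a_phage = mean(.data$a_phage), a_host = mean(.data$a_host),
              .groups = "drop") |>
    mutate(level = "group") |>
    rename(unit = "group")

  bind_rows(per_sample, per_group) |>
    mutate(
      status = dplyr::case_when(
        .data$a_phage > 0 & .data$a_host > 0 ~ "defined",
        .data$a_phage > 0 ~ "host_absent",
        .data$a_host > 0 ~ "phage_absent",
        TRUE ~ "both_absent"
      ),
      ratio = ifelse(.data$status == "defined",
                     .data$a_phage / .data$a_host, NA_real_),
      log10_ratio = log10(.data$ratio)
    ) |>
    select("host_genus", "level", "unit", "a_phage", "a_host", "ratio",
           "log10_ratio", "status") |>
    structure(class = c("phgs_ratio", "tbl_df", "tbl", "data.frame"))
}

#' Classify phages into lytic / temperate / unknown lifestyles
#'
#' Matches phage ids against the lifestyle table's patterns (fixed substring,
#' case-insensitive; first matching row wins, rows tried in table order).
#' Unmatched phages are `"unknown"` and are excluded from the lytic/temperate
#' abundance sums with a warning. When an abundance table and metadata are
#' given, per-group lifestyle abundance sums (mean over each group's samples)
#' are included; lytic + temperate + unknown sums equal the total abundance
#' of the classified phages.
#'
#' @param phage_ids Character vector of phage ids, or a long abundance tibble
#'   (`taxon`, `sample`, `abundance`).
#' @param lifestyle Lifestyle table ([lifestyle_table()] by default).
#' @param metadata Optional `sample_id`/`group` tibble for group sums.
#' @return A list of class `phgs_lifestyle`: `assignments` (tibble
#'   `phage_id`, `lifestyle`, `pattern`) and, with abundances supplied,
#'   `group_abundance` (tibble `group`, `lifestyle`, `abundance`).
#' @export
classify_lifestyle <- function(phage_ids, lifestyle = lifestyle_table(),
                               metadata = NULL) {
  tbl <- NULL
  if (is.data.frame(phage_ids)) {
    tbl <- phage_ids
    phage_ids <- unique(tbl$taxon)
  }
  # patterns match as standalone tokens so e.g. "c2" does not hit "Tuc2009"
  esc <- gsub("([][{}()+*^$|\\\\?.#-])", "\\\\\\1",
              tolower(lifestyle$phage_pattern))
  pat <- paste0("(^|[^a-z0-9])", esc, "($|[^a-z0-9])")
  assign_one <- function(id) {
    hit <- which(vapply(pat, function(p) grepl(p, tolower(id)), TRUE))
    if (length(hit)) {
      c(lifestyle$lifestyle[hit[1L]], lifestyle$phage_pattern[hit[1L]])
    } else {
      c("unknown", NA_character_)
    }
  }
  ass <- vapply(phage_ids, assign_one, character(2L))
  assignments <- tibble(phage_id = phage_ids, lifestyle = ass[1L, ],
                        pattern = ass[2L, ])
  if (any(assignments$lifestyle == "unknown")) {
    warn(sprintf("phage(s) not in lifestyle table, classified unknown: %s",
                 paste(assignments$phage_id[assignments$lifestyle == "unknown"],
                       collapse = ", ")))
  }
  out <- list(assignments = assignments)
  if (!is.null(tbl) && !is.null(metadata)) {
    check_metadata(metadata, unique(tbl$sample))
    out$group_abundance <- tbl |>
      left_join(assignments, by = c(taxon = "phage_id")) |>
      left_join(metadata, by = c(sample = "sample_id")) |>
      group_by(.data$sample, .data$group, .data$lifestyle) |>
      summarise(abundance = sum(.data$abundance), .groups = "drop") |>
      group_by(.data$group, .data$lifestyle) |>
      summarise(abundance = mean(.data$abundance), .groups = "drop")
  }
  structure(out, class = "phgs_lifestyle")
}

#' @export
print.phgs_lifestyle <- function(x, ...) {
  cat("<phgs_lifestyle>\n")
  print(dplyr::count(x$assignments, .data$lifestyle), ...)
  if (!is.null(x$group_abundance)) print(x$group_abundance, ...)
  invisible(x)
}

#' Group fold change of a taxon with bootstrap confidence interval
#'
#' `fold = mean(numerator group) / mean(denominator group)` of the taxon's
#' per-sample abundance, with a seeded percentile bootstrap CI over samples
#' (resampling within groups). A zero denominator-group mean gives status
#' `"infinite"` with only the CI lower bound reported.
#'
#' @param tbl Long abundance tibble (`taxon`, `sample`, `abundance`).
#' @param metadata Tibble `sample_id`, `group`.
#' @param taxon Taxon to test.
#' @param numerator_group,denominator_group Group labels; the conventional
#'   depletion fold is control over case.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Tibble `taxon`, `mean_numerator`, `mean_denominator`, `fold`,
#'   `ci_lower`, `ci_upper`, `status`.
#' @export
group_fold_change <- function(tbl, metadata, taxon, numerator_group,
                              denominator_group, n_boot = 1000L,
                              conf = 0.95, seed = 1L) {
  check_metadata(metadata)
  samples <- metadata$sample_id
  x <- tbl |> filter(.data$taxon == !!taxon)
  ab <- setNames(rep(0, length(samples)), samples)
  ab[x$sample] <- x$abundance
  num <- ab[metadata$sample_id[metadata$group == numerator_group]]
  den <- ab[metadata$sample_id[metadata$group == denominator_group]]
  if (!length(num) || !length(den)) {
    abort("both groups must have at least one sample")
  }
  fold_of <- function(a, b) mean(a) / mean(b)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      fold_of(num[sample.int(length(num), replace = TRUE)],
              den[sample.int(length(den), replace = TRUE)])
    }, numeric(1L))
  })
  alpha <- (1 - conf) / 2
  finite <- is.finite(boots)
  status <- if (mean(den) == 0) "infinite" else "defined"
  tibble(
    taxon = taxon,
    mean_numerator = mean(num),
    mean_denominator = mean(den),
    fold = fold_of(num, den),
    ci_lower = unname(quantile(boots[finite], alpha, na.rm = TRUE)),
    ci_upper = if (status == "defined") {
      unname(quantile(boots[finite], 1 - alpha, na.rm = TRUE))
    } else {
      NA_real_
    },
    status = status
  )
}

#' Per-phage log10 case/control abundance ratio
#'
#' `log10((case mean + eps) / (control mean + eps))` per phage, with the
#' pseudocount `eps` defaulting to half the smallest nonzero abundance in the
#' table. Positive values are up in cases, negative down, zero equal.
#'
#' @param tbl Long phage abundance tibble (`taxon`, `sample`, `abundance`).
#' @param metadata Tibble `sample_id`, `group`.
#' @param case_group,control_group Group labels.
#' @param pseudocount Pseudocount eps; `NULL` for the default policy.
#' @return Tibble `taxon`, `case_mean`, `control_mean`, `log10_ratio`,
#'   `direction` (`"up"`/`"down"`/`"equal"`).
#' @export
lifestyle_log_ratio <- function(tbl, metadata, case_group, control_group,
                                pseudocount = NULL) {
  check_metadata(metadata, unique(tbl$sample))
  eps <- pseudocount %||% (min(tbl$abundance[tbl$abundance > 0]) / 2)
  full <- tidyr::expand_grid(taxon = unique(tbl$taxon),
                             sample = metadata$sample_id) |>
    left_join(tbl, by = c("taxon", "sample")) |>
    mutate(abundance = dplyr::coalesce(.data$abundance, 0)) |>
    left_join(metadata, by = c(sample = "sample_id"))
  full |>
    group_by(.data$taxon) |>
    summarise(
      case_mean = mean(.data$abundance[.data$group == case_group]),
      control_mean = mean(.data$abundance[.data$group == control_group]),
      .groups = "drop"
    ) |>
    mutate(
      log10_ratio = log10((.data$case_mean + eps) / (.data$control_mean + eps)),
      direction = dplyr::case_when(
        .data$log10_ratio > 0 ~ "up",
        .data$log10_ratio < 0 ~ "down",
        TRUE ~ "equal"
      )
    )
}
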