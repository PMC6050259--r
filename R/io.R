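#' Read a FASTA file into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a tidy
#' two-column tibble so sequence sets compose with dplyr verbs.
#'
#' @param path Path to a FASTA file (free line wrapping).
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x))
  )
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id` and `seq`, or a named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(id = names(x), seq = unname(x))
  }
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a 4-line Sanger FASTQ file into a tibble
#'
#' Parses the fixed 4-line-per-record dialect and validates record structure,
#' reporting the offending line number for truncated records, bad record
#' markers, and sequence/quality length mismatches.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record at line %d in '%s'", (n %/% 4L) * 4L + 1L, path))
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort(sprintf("FASTQ record does not start with '@' at line %d in '%s'",
                  idx[bad_hdr[1L]], path))
  }
  plus <- lines[idx + 2L]
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    abort(sprintf("FASTQ separator line is not '+' at line %d in '%s'",
                  idx[bad_plus[1L]] + 2L, path))
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    abort(sprintf("quality length differs from sequence length at line %d in '%s'",
                  idx[mism[1L]] + 3L, path))
  }
  tibble(
    id = sub("\\s.*$", "", sub("^@", "", hdr)),
    seq = seqs,
    qual = quals
  )
}

#' Write reads to a 4-line Sanger FASTQ file
#'
#' @param x A tibble with columns `id`, `seq` and optionally `qual`. Missing
#'   qualities are written as constant Q37 (`"F"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("qual" %in% names(x)) x$qual else strrep("F", nchar(x$seq))
  out <- character(4L * nrow(x))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", x$id)
  out[seq(2L, length(out), by = 4L)] <- x$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Write a table as TSV with a provenance header
#'
#' All interchange files carry `#`-prefixed header lines recording the package
#' version and, when supplied, the seed and configuration hash of the run.
#' Coordinates in all interchange files are 0-based half-open.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named character vector of extra `key=value` pairs for the header.
#' @return `path`, invisibly.
#' @export
write_phagoscope_tsv <- function(x, path, meta = character()) {
  hdr <- c(
    sprintf("# phagoscope %s", as.character(packageVersion("phagoscope"))),
    if (length(meta)) sprintf("# %s=%s", names(meta), unname(meta)),
    "# coordinates=0-based half-open"
  )
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_phagoscope_tsv()]
#'
#' @param path Input path.
#' @param ... Passed to [readr::read_tsv()].
#' @return A tibble.
#' @export
read_phagoscope_tsv <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write an abundance table to wide TSV (taxa rows, sample columns)
#'
#' @param tbl Long abundance tibble with columns `taxon`, `sample`, and one
#'   value column (`count` or `abundance`).
#' @param path Output path.
#' @param meta Header metadata, see [write_phagoscope_tsv()].
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(tbl, path, meta = character()) {
  value <- abundance_value_col(tbl)
  wide <- tidyr::pivot_wider(
    tbl[, c("taxon", "sample", value)],
    names_from = "sample", values_from = dplyr::all_of(value), values_fill = 0
  )
  write_phagoscope_tsv(wide, path, meta = meta)
}

#' Read a wide abundance TSV back into long form
#'
#' @param path Input path.
#' @param value Name for the value column (`"abundance"` or `"count"`).
#' @return Long tibble with columns `taxon`, `sample`, and `value`.
#' @export
read_abundance_tsv <- function(path, value = "abundance") {
  wide <- read_phagoscope_tsv(path)
  tidyr::pivot_longer(wide, -"taxon", names_to = "sample", values_to = value)
}

#' Read tabular BLAST results (outfmt 6)
#'
#' Maps the standard 12 columns to [align_local()]'s hit schema so externally
#' produced BLAST runs can be slotted into [classify_contigs()]. Column
#' mapping: qseqid/sseqid -> query_id/subject_id, pident -> percent_identity,
#' length -> aligned_length, qstart/qend/sstart/send -> 0-based half-open
#' spans (outfmt 6 is 1-based closed; subject coordinates are reported
#' ascending with strand derived from their order), bitscore -> score,
#' evalue -> e_value.
#'
#' @param path Path to a 12-column tab-separated BLAST outfmt 6 file.
#' @return A tibble of alignment hits.
#' @export
read_blast6 <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "aligned_length",
            "mismatches", "gap_openings", "q_start", "q_end", "s_start",
            "s_end", "e_value", "score")
  x <- readr::read_tsv(path, col_names = cols, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  strand <- ifelse(x$s_start <= x$s_end, "+", "-")
  s_lo <- pmin(x$s_start, x$s_end)
  s_hi <- pmax(x$s_start, x$s_end)
  tibble(
    query_id = x$query_id,
    subject_id = x$subject_id,
    percent_identity = x$percent_identity,
    aligned_length = x$aligned_length,
    score = x$score,
    e_value = x$e_value,
    q_start = x$q_start - 1L,
    q_end = x$q_end,
    s_start = s_lo - 1L,
    s_end = s_hi,
    strand = strand
  )
}

#' Read alignments from a SAM file
#'
#' Adapter for externally produced mappings (e.g. Bowtie2). Requires the
#' Rsamtools package. Mapped records are returned with the recruited
#' subject (reference) and an identity estimate from the NM tag when present.
#'
#' @param path Path to a SAM file with a header.
#' @return A tibble with columns `query_id`, `subject_id`, `s_start` (0-based),
#'   `aligned_length`, `percent_identity` (NA when NM is absent), `strand`.
#' @export
read_sam_hits <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("read_sam_hits() requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  cig <- rec$cigar
  aln_len <- unname(vapply(cig, cigar_aligned_length, numeric(1)))
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_real_, length(cig))
  tibble(
    query_id = rec$qname,
    subject_id = as.character(rec$rname),
    s_start = rec$pos - 1L,
    aligned_length = aln_len,
    percent_identity = ifelse(is.na(nm), NA_real_,
                              100 * (aln_len - nm) / aln_len),
    strand = as.character(rec$strand)
  )
}

cigar_aligned_length <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (ops[1L] == -1L) return(NA_real_)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.numeric(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "=", "X", "I", "D")])
}

abundance_value_col <- function(tbl) {
  cand <- intersect(c("abundance", "count", "value"), names(tbl))
  if (!length(cand)) {
    abort("abundance table must have an 'abundance', 'count' or 'value' column")
  }
  cand[[1L]]
}

#' Convert a long abundance tibble to a taxa-by-samples matrix
#'
#' @param tbl Long tibble with `taxon`, `sample` and a value column.
#' @param value Value column name; defaults to the first of
#'   `abundance`, `count`, `value` present.
#' @return A numeric matrix, taxa in rows, samples in columns.
#' @export
abundance_matrix <- function(tbl, value = NULL) {
  value <- value %||% abundance_value_col(tbl)
  wide <- tidyr::pivot_wider(
    tbl[, c("taxon", "sample", value)],
    names_from = "sample", values_from = dplyr::all_of(value), values_fill = 0
  )
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$taxon
  m
}

#' Convert a taxa-by-samples matrix to a long abundance tibble
#'
#' @param m Numeric matrix with taxa rownames and sample colnames.
#' @param value Name of the value column in the result.
#' @return A long tibble with `taxon`, `sample`, and the value column.
#' @export
as_abundance_tibble <- function(m, value = "abundance") {
  taxa <- rownames(m) %||% as.character(seq_len(nrow(m)))
  samples <- colnames(m) %||% as.character(seq_len(ncol(m)))
  out <- tibble(
    taxon = rep(taxa, times = ncol(m)),
    sample = rep(samples, each = nrow(m)),
    v = as.numeric(m)
  )
  names(out)[3L] <- value
  out
}

check_metadata <- function(metadata, samples = NULL) {
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("metadata must have columns 'sample_id' and 'group'")
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, metadata$sample_id)
    if (length(missing)) {
      abort(sprintf("samples missing from metadata: %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
  }
  invisible(metadata)
}
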