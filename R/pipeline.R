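#' Pipeline run configuration
#'
#' Collects all stage thresholds, the seed, and either a simulation preset
#' (the synthetic cohort becomes the pipeline input) or paths to existing
#' inputs. Thresholds are validated against their documented ranges.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed, recorded in every output header.
#' @param simulate `NULL`, or a [sim_config()] to generate the inputs.
#' @param inputs `NULL`, or a named list of paths: `contigs_fasta`,
#'   `reads_tsv` (two columns `sample`, `fastq`), `phage_db_fasta`,
#'   `phage_db_tsv` (`phage_id`, `family`, `host_genus`, `lifestyle`),
#'   `marker_db_fasta`, `marker_db_tsv` (`marker_id`, `clade`),
#'   `metadata_tsv`.
#' @param e_max,min_contig,min_frac Contig classification thresholds.
#' @param min_reads,min_identity,min_aligned Detection thresholds.
#' @param prevalence_floor Abundance floor for taxon removal.
#' @param min_score Read mapping score threshold.
#' @param n_permutations PERMANOVA permutations.
#' @param contig_args Arguments for [emit_contigs()] in simulate mode.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `phgs_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = NULL, inputs = NULL,
                       e_max = 1e-5, min_contig = 200L, min_frac = 0.5,
                       min_reads = 2L, min_identity = 90, min_aligned = 100L,
                       prevalence_floor = 1e-4, min_score = 40L,
                       n_permutations = 999L, contig_args = list(),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(simulate) && is.null(inputs)) {
    abort("run_config needs either a simulation config or input paths")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "phgs_sim_config"))
  if (e_max <= 0) abort("e_max must be positive")
  if (min_contig <= 0) abort("min_contig must be positive")
  if (min_frac <= 0 || min_frac > 1) abort("min_frac must be in (0, 1]")
  if (min_reads < 1) abort("min_reads must be >= 1")
  if (min_identity < 0 || min_identity >= 100) {
    abort("min_identity must be in [0, 100)")
  }
  if (min_aligned < 0) abort("min_aligned must be non-negative")
  if (prevalence_floor < 0 || prevalence_floor >= 1) {
    abort("prevalence_floor must be in [0, 1)")
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
    inputs = inputs, e_max = e_max, min_contig = as.integer(min_contig),
    min_frac = min_frac, min_reads = as.integer(min_reads),
    min_identity = min_identity, min_aligned = as.integer(min_aligned),
    prevalence_floor = prevalence_floor, min_score = as.integer(min_score),
    n_permutations = as.integer(n_permutations), contig_args = contig_args,
    log_level = log_level
  ), class = "phgs_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys are the arguments of [run_config()]; the
#' `simulate` key takes a preset name (`pd_cohort` or `prophage_cohort`) plus
#' that preset's arguments. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `phgs_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "log_level")
  extra <- setdiff(names(y), c(known, "log_level"))
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(y$simulate)) {
    preset <- y$simulate$preset %||% "pd_cohort"
    args <- y$simulate[setdiff(names(y$simulate), "preset")]
    y$simulate <- switch(preset,
      pd_cohort = do.call(pd_cohort_config, args),
      prophage_cohort = do.call(prophage_cohort_config, args),
      abort(sprintf("unknown simulate preset '%s'", preset))
    )
  }
  do.call(run_config, y)
}

#' Run the full phagobiota analysis pipeline
#'
#' Stage order is fixed: simulate (or load inputs), quantify phages, profile
#' bacteria, diversity statistics, lytic potential. Every stage writes its
#' report files under `out_dir` with provenance headers; a failure aborts
#' with a manifest of the stages completed so far. Re-running with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return A `phgs_run_manifest`: tibble `stage`, `file`, `md5`, with the
#'   tool version, seed and config hash as attributes (also written to
#'   `manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "phgs_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  meta_hdr <- c(seed = as.character(config$seed), config_md5 = cfg_hash)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  files <- tibble(stage = character(), file = character())
  emit <- function(stage, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- bind_rows(files, tibble(stage = stage, file = name))
    path
  }
  finish <- function(completed) {
    manifest <- files |>
      mutate(md5 = unname(tools::md5sum(file.path(config$out_dir, .data$file))))
    attr(manifest, "version") <- as.character(packageVersion("phagoscope"))
    attr(manifest, "seed") <- config$seed
    attr(manifest, "config_md5") <- cfg_hash
    attr(manifest, "completed_stages") <- completed
    class(manifest) <- c("phgs_run_manifest", class(manifest))
    write_phagoscope_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                         meta = c(meta_hdr, stages = paste(completed,
                                                           collapse = ",")))
    manifest
  }
  completed <- character()
  run_stage <- function(name, fn) {
    say("stage %s", name)
    tryCatch(fn(), error = function(e) {
      finish(completed)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- stage: inputs -------------------------------------------------------
  dat <- run_stage("inputs", function() {
    if (!is.null(config$simulate)) {
      cohort <- simulate_cohort(config$simulate,
                                contig_args = config$contig_args)
      emit("inputs", "reads.fastq",
           function(p) write_fastq(cohort$reads |>
                                     mutate(id = .data$read_id), p))
      emit("inputs", "contigs.fasta", function(p) {
        write_fasta(cohort$contigs[, c("id", "seq")], p)
      })
      emit("inputs", "read_origin.tsv", function(p) {
        write_phagoscope_tsv(cohort$origin, p, meta = meta_hdr)
      })
      emit("inputs", "true_abundance_bacteria.tsv", function(p) {
        write_abundance_tsv(cohort$truth$bacteria, p, meta = meta_hdr)
      })
      emit("inputs", "true_abundance_phage.tsv", function(p) {
        write_abundance_tsv(cohort$truth$phage, p, meta = meta_hdr)
      })
      emit("inputs", "metadata.tsv", function(p) {
        write_phagoscope_tsv(cohort$truth$metadata, p, meta = meta_hdr)
      })
      list(reads = cohort$reads, contigs = cohort$contigs,
           phage_db = cohort$phage_db, marker_db = cohort$marker_db,
           metadata = cohort$truth$metadata, truth = cohort$truth)
    } else {
      load_pipeline_inputs(config$inputs)
    }
  })
  completed <- c(completed, "inputs")

  # --- stage: quantify -----------------------------------------------------
  quant <- run_stage("quantify", function() {
    q <- quantify_phages(
      dat$contigs, dat$reads, dat$phage_db,
      e_max = config$e_max, min_contig = config$min_contig,
      min_frac = config$min_frac, min_reads = config$min_reads,
      min_identity = config$min_identity, min_aligned = config$min_aligned,
      prevalence_floor = config$prevalence_floor,
      min_score = config$min_score
    )
    emit("quantify", "contig_assignments.tsv", function(p) {
      write_phagoscope_tsv(q$contig_assignments, p, meta = meta_hdr)
    })
    emit("quantify", "phage_counts.tsv", function(p) {
      write_abundance_tsv(q$counts$counts, p, meta = meta_hdr)
    })
    emit("quantify", "phage_abundance.tsv", function(p) {
      write_abundance_tsv(q$abundance, p, meta = meta_hdr)
    })
    q
  })
  completed <- c(completed, "quantify")

  # --- stage: profile ------------------------------------------------------
  profile <- run_stage("profile", function() {
    pr <- profile_markers(dat$reads, dat$marker_db,
                          min_score = config$min_score)
    emit("profile", "bacteria_profile.tsv", function(p) {
      write_phagoscope_tsv(pr, p, meta = meta_hdr)
    })
    pr
  })
  completed <- c(completed, "profile")

  # --- stage: diversity ----------------------------------------------------
  div <- run_stage("diversity", function() {
    counts <- quant$counts$counts
    out <- list()
    if (nrow(counts)) {
      out$alpha <- alpha_diversity(counts)
      emit("diversity", "alpha_diversity_phage.tsv", function(p) {
        write_phagoscope_tsv(out$alpha, p, meta = meta_hdr)
      })
      rel <- quant$abundance
      if (dplyr::n_distinct(rel$sample) >= 3L &&
          dplyr::n_distinct(rel$taxon) >= 2L) {
        bc <- bray_curtis(rel)
        sp <- spearman_dissimilarity(rel)
        ord <- pcoa(bc)
        emit("diversity", "bray_curtis_phage.tsv", function(p) {
          write_phagoscope_tsv(dist_to_tibble(bc), p, meta = meta_hdr)
        })
        emit("diversity", "spearman_dissimilarity_phage.tsv", function(p) {
          write_phagoscope_tsv(dist_to_tibble(sp), p, meta = meta_hdr)
        })
        emit("diversity", "pcoa_phage.tsv", function(p) {
          write_phagoscope_tsv(tidy(ord), p, meta = meta_hdr)
        })
        md <- dat$metadata |>
          filter(.data$sample_id %in% labels(bc))
        tests <- list()
        if (dplyr::n_distinct(md$group) >= 2L && all(table(md$group) >= 2L)) {
          tests$permanova_bray_curtis <- permanova(
            bc, md, n_permutations = config$n_permutations,
            seed = config$seed
          )
        }
        for (idx in c("ace", "chao1", "shannon", "simpson", "inv_simpson")) {
          vals <- tibble(sample = out$alpha$sample,
                         value = out$alpha[[idx]])
          vals <- vals |> filter(.data$sample %in% md$sample_id)
          if (dplyr::n_distinct(md$group) == 2L) {
            tests[[paste0("mann_whitney_", idx)]] <-
              group_compare(vals, md, method = "mann_whitney")
            tests[[paste0("anova_", idx)]] <-
              group_compare(vals, md, method = "anova")
          }
        }
        out$tests <- purrr::imap_dfr(tests, function(t, nm) {
          tidy(t) |> mutate(test = nm, .before = 1L)
        })
        emit("diversity", "tests.tsv", function(p) {
          write_phagoscope_tsv(out$tests, p, meta = meta_hdr)
        })
        out$ordination <- ord
      }
    }
    out
  })
  completed <- c(completed, "diversity")

  # --- stage: lytic potential ---------------------------------------------
  run_stage("lytic_potential", function() {
    rel <- quant$abundance
    if (!nrow(rel)) return(invisible(NULL))
    genus_prof <- profile |>
      filter(.data$rank == "genus") |>
      select("taxon", "sample", "abundance")
    hosts <- cluster_by_host(rel, dat$phage_db)
    shared <- intersect(unique(hosts$sample), unique(genus_prof$sample))
    ratios <- phage_bacteria_ratio(
      hosts |> filter(.data$sample %in% shared),
      genus_prof |> filter(.data$sample %in% shared),
      dat$metadata
    )
    emit("lytic_potential", "ratio_report.tsv", function(p) {
      write_phagoscope_tsv(as_tibble(ratios), p, meta = meta_hdr)
    })
    ls <- classify_lifestyle(rel, metadata = dat$metadata)
    emit("lytic_potential", "lifestyle_assignments.tsv", function(p) {
      write_phagoscope_tsv(ls$assignments, p, meta = meta_hdr)
    })
    if (!is.null(ls$group_abundance)) {
      emit("lytic_potential", "lifestyle_group_abundance.tsv", function(p) {
        write_phagoscope_tsv(ls$group_abundance, p, meta = meta_hdr)
      })
    }
    groups <- unique(dat$metadata$group)
    if (length(groups) == 2L) {
      fc <- purrr::map_dfr(unique(genus_prof$taxon), function(tx) {
        group_fold_change(genus_prof, dat$metadata, tx,
                          numerator_group = groups[2L],
                          denominator_group = groups[1L],
                          seed = config$seed)
      })
      emit("lytic_potential", "fold_change.tsv", function(p) {
        write_phagoscope_tsv(fc, p, meta = meta_hdr)
      })
      lr <- lifestyle_log_ratio(rel, dat$metadata,
                                case_group = groups[1L],
                                control_group = groups[2L])
      emit("lytic_potential", "lifestyle_log_ratio.tsv", function(p) {
        write_phagoscope_tsv(lr, p, meta = meta_hdr)
      })
    }
    invisible(NULL)
  })
  completed <- c(completed, "lytic_potential")

  finish(completed)
}

load_pipeline_inputs <- function(inputs) {
  need <- c("contigs_fasta", "reads_tsv", "phage_db_fasta", "phage_db_tsv",
            "marker_db_fasta", "marker_db_tsv", "metadata_tsv")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    abort(sprintf("missing input path(s): %s", paste(missing, collapse = ", ")))
  }
  for (p in unlist(inputs[need])) {
    if (!file.exists(p)) abort(sprintf("input file does not exist: %s", p))
  }
  contigs <- read_fasta(inputs$contigs_fasta)
  reads_map <- read_phagoscope_tsv(inputs$reads_tsv)
  reads <- purrr::map2_dfr(reads_map$sample, reads_map$fastq, function(s, f) {
    read_fastq(f) |> mutate(read_id = .data$id, sample = s)
  })
  phage_seq <- read_fasta(inputs$phage_db_fasta)
  phage_ann <- read_phagoscope_tsv(inputs$phage_db_tsv)
  phage_db <- phage_ann |>
    mutate(seq = phage_seq$seq[match(.data$phage_id, phage_seq$id)])
  if (anyNA(phage_db$seq)) abort("phage_db_tsv names phages absent from FASTA")
  marker_seq <- read_fasta(inputs$marker_db_fasta)
  marker_ann <- read_phagoscope_tsv(inputs$marker_db_tsv)
  parsed_g <- parse_clade(marker_ann$clade, "g")
  parsed_f <- parse_clade(marker_ann$clade, "f")
  marker_db <- marker_ann |>
    mutate(genus = parsed_g$taxon, family = parsed_f$taxon,
           seq = marker_seq$seq[match(.data$marker_id, marker_seq$id)])
  if (anyNA(marker_db$seq)) abort("marker_db_tsv names markers absent from FASTA")
  metadata <- read_phagoscope_tsv(inputs$metadata_tsv)
  check_metadata(metadata, unique(reads$sample))
  list(reads = reads[, c("read_id", "sample", "seq")], contigs = contigs,
       phage_db = phage_db, marker_db = marker_db, metadata = metadata)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

dist_to_tibble <- function(d) {
  m <- as.matrix(d)
  dplyr::bind_cols(tibble(sample = rownames(m)), as_tibble(m))
}
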