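#' Generate bacterial and phage genomes for a simulated cohort
#'
#' Bacterial genomes are uniform-random A/C/G/T backbones with clade-specific
#' marker loci embedded at evenly spaced, non-overlapping offsets; marker
#' uniqueness across genera is enforced by rejection sampling (a marker is
#' redrawn if it occurs anywhere outside its own genome). Phage genomes are
#' independent random sequences. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   * `bacteria`: tibble `id`, `genus`, `family`, `seq`.
#'   * `markers`: tibble `marker_id`, `genome_id`, `genus`, `family`,
#'     `start`, `end` (0-based half-open), `seq`.
#'   * `phages`: tibble `id`, `host_genus`, `lifestyle`, `family`, `seq`
#'     (the phage genome database with annotations).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "phgs_sim_config"))
  withr::with_seed(config$seed, {
    bact <- purrr::map(config$genera, function(g) {
      purrr::map(seq_len(g$n_species), function(sp) {
        list(
          id = sprintf("%s_sp%d", gsub(" ", "_", g$name), sp),
          genus = g$name, family = g$family,
          seq = random_dna(g$genome_length),
          spec = g
        )
      })
    }) |> purrr::flatten()

    # embed markers: evenly spaced, non-overlapping
    markers <- list()
    for (i in seq_along(bact)) {
      g <- bact[[i]]$spec
      gap <- (g$genome_length - g$n_markers * g$marker_length) %/%
        (g$n_markers + 1L)
      starts <- gap + (seq_len(g$n_markers) - 1L) * (g$marker_length + gap)
      for (j in seq_len(g$n_markers)) {
        markers[[length(markers) + 1L]] <- list(
          marker_id = sprintf("%s_m%d", bact[[i]]$id, j),
          genome_index = i, start = starts[j],
          end = starts[j] + g$marker_length,
          seq = random_dna(g$marker_length)
        )
      }
    }
    for (mk in markers) {
      i <- mk$genome_index
      substr(bact[[i]]$seq, mk$start + 1L, mk$end) <- mk$seq
    }
    # rejection sampling: redraw any marker found outside its own genome
    for (round in seq_len(100L)) {
      clean <- TRUE
      for (t in seq_along(markers)) {
        mk <- markers[[t]]
        others <- vapply(bact[-mk$genome_index], `[[`, "", "seq")
        extra <- any(grepl(mk$seq, others, fixed = TRUE)) ||
          sum(gregexpr(mk$seq, bact[[mk$genome_index]]$seq,
                       fixed = TRUE)[[1L]] > 0) > 1L
        if (extra) {
          clean <- FALSE
          markers[[t]]$seq <- random_dna(nchar(mk$seq))
          substr(bact[[mk$genome_index]]$seq, mk$start + 1L, mk$end) <-
            markers[[t]]$seq
        }
      }
      if (clean) break
    }

    phage <- purrr::map(config$phages, function(p) {
      list(id = p$name, host_genus = p$host_genus, lifestyle = p$lifestyle,
           family = p$family, seq = random_dna(p$genome_length))
    })

    list(
      bacteria = tibble(
        id = vapply(bact, `[[`, "", "id"),
        genus = vapply(bact, `[[`, "", "genus"),
        family = vapply(bact, `[[`, "", "family"),
        seq = vapply(bact, `[[`, "", "seq")
      ),
      markers = tibble(
        marker_id = vapply(markers, `[[`, "", "marker_id"),
        genome_id = vapply(markers, function(m) bact[[m$genome_index]]$id, ""),
        genus = vapply(markers, function(m) bact[[m$genome_index]]$genus, ""),
        family = vapply(markers, function(m) bact[[m$genome_index]]$family, ""),
        start = vapply(markers, `[[`, 0L, "start"),
        end = vapply(markers, `[[`, 0L, "end"),
        seq = vapply(markers, `[[`, "", "seq")
      ),
      phages = tibble(
        id = vapply(phage, `[[`, "", "id"),
        host_genus = vapply(phage, `[[`, "", "host_genus"),
        lifestyle = vapply(phage, `[[`, "", "lifestyle"),
        family = vapply(phage, `[[`, "", "family"),
        seq = vapply(phage, `[[`, "", "seq")
      )
    )
  })
}

#' Integrate temperate phages as prophages into their host genomes
#'
#' Each temperate phage is inserted verbatim once into every species genome of
#' its host genus at a uniform random offset; the host genome grows by exactly
#' the phage genome length per insertion. Lytic phages are never inserted.
#'
#' @param genomes Output of [generate_genomes()].
#' @param seed Integer seed for insertion offsets.
#' @return `genomes` with modified `bacteria$seq`, marker coordinates shifted
#'   past insertion points, and an added `placements` tibble
#'   (`host_genome_id`, `phage_id`, `offset`, 0-based).
#' @export
integrate_prophages <- function(genomes, seed = 1L) {
  temperate <- genomes$phages |> filter(.data$lifestyle == "temperate")
  placements <- tibble(host_genome_id = character(), phage_id = character(),
                       offset = integer())
  bact <- genomes$bacteria
  markers <- genomes$markers
  if (nrow(temperate)) {
    missing <- setdiff(temperate$host_genus, bact$genus)
    if (length(missing)) {
      abort(sprintf("temperate phage host genus has no genome: %s",
                    paste(missing, collapse = ", ")))
    }
    withr::with_seed(seed, {
      for (p in seq_len(nrow(temperate))) {
        hosts <- which(bact$genus == temperate$host_genus[p])
        for (h in hosts) {
          len <- nchar(bact$seq[h])
          mk_here <- markers[markers$genome_id == bact$id[h], ]
          repeat {
            # uniform in [0, len], rejecting offsets inside a marker locus
            off <- sample.int(len + 1L, 1L) - 1L
            if (!any(off > mk_here$start & off < mk_here$end)) break
          }
          bact$seq[h] <- paste0(
            substr(bact$seq[h], 1L, off),
            temperate$seq[p],
            substr(bact$seq[h], off + 1L, len)
          )
          ins_len <- nchar(temperate$seq[p])
          shift <- markers$genome_id == bact$id[h] & markers$start >= off
          markers$start[shift] <- markers$start[shift] + ins_len
          markers$end[shift] <- markers$end[shift] + ins_len
          placements <- bind_rows(placements, tibble(
            host_genome_id = bact$id[h], phage_id = temperate$id[p],
            offset = off
          ))
        }
      }
    })
  }
  genomes$bacteria <- bact
  genomes$markers <- markers
  genomes$placements <- placements
  genomes
}

#' Draw true per-sample abundances for the cohort
#'
#' Abundances are independent log-normal per taxon, multiplied by the
#' configured case effects in the case group, then closed (sum-to-one) per
#' sample separately within the bacterial and phage domains. In
#' `"host_coupled"` mode the phage table mirrors the host genus table (split
#' equally across a host's phages) instead of being drawn independently.
#'
#' @param config A [sim_config()].
#' @return A list with `bacteria` and `phage` long tibbles (`taxon`, `sample`,
#'   `abundance`, per-sample sum 1 within each domain) and `metadata`
#'   (`sample_id`, `group`).
#' @export
sample_abundances <- function(config) {
  stopifnot(inherits(config, "phgs_sim_config"))
  labs <- config$group_labels
  metadata <- tibble(
    sample_id = c(sprintf("%s_%02d", make.names(labs[["case"]]),
                          seq_len(config$n_cases)),
                  sprintf("%s_%02d", make.names(labs[["control"]]),
                          seq_len(config$n_controls))),
    group = c(rep(labs[["case"]], config$n_cases),
              rep(labs[["control"]], config$n_controls))
  )
  genus_names <- vapply(config$genera, `[[`, "", "name")
  phage_names <- vapply(config$phages, `[[`, "", "name")

  draw_domain <- function(taxa) {
    ab <- config$base_abundance[match(taxa, config$base_abundance$taxon), ]
    raw <- matrix(0, nrow = length(taxa), ncol = nrow(metadata),
                  dimnames = list(taxa, metadata$sample_id))
    for (t in seq_along(taxa)) {
      eff <- ifelse(metadata$group == labs[["case"]],
                    config$case_effects[taxa[t]] %|na|% 1, 1)
      raw[t, ] <- rlnorm(nrow(metadata), ab$mu[t], ab$sigma[t]) * eff
    }
    sweep(raw, 2L, colSums(raw), "/")
  }

  withr::with_seed(config$seed + 1L, {
    bact <- draw_domain(genus_names)
    if (config$phage_abundance_mode == "host_coupled") {
      hosts <- vapply(config$phages, `[[`, "", "host_genus")
      share <- 1 / table(hosts)[hosts]
      phg <- bact[hosts, , drop = FALSE] * as.numeric(share)
      rownames(phg) <- phage_names
      phg <- sweep(phg, 2L, colSums(phg), "/")
    } else {
      phg <- draw_domain(phage_names)
    }
  })
  list(
    bacteria = as_abundance_tibble(bact),
    phage = as_abundance_tibble(phg),
    metadata = metadata
  )
}

#' Simulate shotgun reads from the cohort
#'
#' Per sample, the read count is Poisson with mean `depth * L / read_length`
#' where `L` is the summed length of all genomes in the pool; each read's
#' source genome is drawn with probability proportional to
#' `relative abundance x genome length`, weighted by the bacterial/free-phage
#' DNA split (`phage_dna_fraction`) and, for temperate phages, the
#' free-particle fraction. Reads from bacterial genomes cover integrated
#' prophages. Reads are reverse-complemented with probability 0.5 and carry
#' per-base substitution errors at the configured rate; qualities are constant
#' high (Q40).
#'
#' @param genomes Output of [integrate_prophages()] (or [generate_genomes()]
#'   when no phage is temperate).
#' @param truth Output of [sample_abundances()].
#' @param config The [sim_config()].
#' @return A list with `reads` (tibble `read_id`, `sample`, `seq`, `qual`) and
#'   `origin` (tibble `read_id`, `genome_id`).
#' @export
simulate_reads <- function(genomes, truth, config) {
  stopifnot(inherits(config, "phgs_sim_config"))
  bact <- genomes$bacteria
  phg <- genomes$phages
  pool <- tibble(
    genome_id = c(bact$id, phg$id),
    taxon = c(bact$genus, phg$id),
    domain = rep(c("bacteria", "phage"), c(nrow(bact), nrow(phg))),
    length = nchar(c(bact$seq, phg$seq)),
    seq = c(bact$seq, phg$seq)
  )
  # species share of genus abundance
  n_sp <- table(bact$genus)
  pool$split <- ifelse(pool$domain == "bacteria",
                       1 / as.numeric(n_sp[pool$taxon]), 1)
  free_frac <- ifelse(pool$domain == "phage" &
                        pool$genome_id %in% phg$id[phg$lifestyle == "temperate"],
                      config$free_particle_fraction, 1)
  mass <- ifelse(pool$domain == "phage", config$phage_dna_fraction,
                 1 - config$phage_dna_fraction)
  L_total <- sum(pool$length)
  ab_b <- abundance_matrix(truth$bacteria)
  ab_p <- abundance_matrix(truth$phage)
  samples <- truth$metadata$sample_id

  withr::with_seed(config$seed + 2L, {
    out <- vector("list", length(samples))
    for (s in seq_along(samples)) {
      rel <- numeric(nrow(pool))
      is_b <- pool$domain == "bacteria"
      rel[is_b] <- ab_b[pool$taxon[is_b], samples[s]]
      if (any(!is_b)) rel[!is_b] <- ab_p[pool$taxon[!is_b], samples[s]]
      w <- mass * rel * pool$split * pool$length * free_frac
      n_reads <- rpois(1L, config$depth * L_total / config$read_length)
      if (n_reads == 0L) next
      gi <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = w)
      too_short <- pool$length[gi] < config$read_length
      if (any(too_short)) {
        abort(sprintf("read_length %d exceeds genome length of '%s'",
                      config$read_length,
                      pool$genome_id[gi[which(too_short)[1L]]]))
      }
      pos <- floor(runif(n_reads) * (pool$length[gi] - config$read_length + 1L))
      rc <- runif(n_reads) < 0.5
      seqs <- cpp_extract_reads(pool$seq, gi, as.integer(pos),
                                config$read_length, rc)
      out[[s]] <- tibble(
        read_id = sprintf("%s_r%06d", samples[s], seq_len(n_reads)),
        sample = samples[s],
        seq = seqs,
        genome_id = pool$genome_id[gi]
      )
    }
    reads <- bind_rows(out)
    # substitutions are applied after all sampling so the read layout is
    # identical across error rates under the same seed
    if (config$substitution_error_rate > 0 && nrow(reads)) {
      reads$seq <- cpp_mutate_seqs(reads$seq, config$substitution_error_rate)
    }
  })
  qual <- strrep("I", config$read_length)
  list(
    reads = tibble(read_id = reads$read_id, sample = reads$sample,
                   seq = reads$seq, qual = qual),
    origin = tibble(read_id = reads$read_id, genome_id = reads$genome_id)
  )
}

#' Emit simulated assembly contigs from the genome pool
#'
#' Stands in for a de novo assembler at desk scale: every genome (bacterial
#' genomes including integrated prophages, and phage genomes) is tiled with
#' overlapping fragments of uniform random length, optionally perturbed with
#' substitution errors; a few additional sub-200-base fragments are emitted so
#' downstream contig length filters are exercised. Deterministic for a fixed
#' seed.
#'
#' @param genomes Output of [integrate_prophages()] or [generate_genomes()].
#' @param min_length,max_length Fragment length bounds (> 0).
#' @param overlap Overlap in bases between successive tiles.
#' @param error_rate Per-base substitution rate applied to fragments.
#' @param n_short Number of extra short (< 200 bases) fragments of length
#'   100-199, emulating sub-threshold assembly artifacts.
#' @param seed Integer seed.
#' @return A tibble `id`, `seq`, plus truth columns `source_genome`, `start`,
#'   `end` (0-based half-open) that downstream quantification must not use.
#' @export
emit_contigs <- function(genomes, min_length = 500L, max_length = 2500L,
                         overlap = 200L, error_rate = 0, n_short = 6L,
                         seed = 1L) {
  stopifnot(min_length > 0, max_length >= min_length, overlap >= 0)
  all_g <- tibble(
    id = c(genomes$bacteria$id, genomes$phages$id),
    seq = c(genomes$bacteria$seq, genomes$phages$seq)
  )
  withr::with_seed(seed, {
    frags <- list()
    for (g in seq_len(nrow(all_g))) {
      L <- nchar(all_g$seq[g])
      if (L <= min_length) {
        frags[[length(frags) + 1L]] <- list(g = g, start = 0L, end = L)
        next
      }
      pos <- 0L
      while (pos < L) {
        len <- sample(seq.int(min_length, max_length), 1L)
        end <- min(pos + len, L)
        if (end == L && end - pos < min_length) {
          # re-anchor the short natural tail so genome ends stay covered
          frags[[length(frags) + 1L]] <-
            list(g = g, start = L - min_length, end = L)
          break
        }
        frags[[length(frags) + 1L]] <- list(g = g, start = pos, end = end)
        pos <- pos + max(end - pos - overlap, ceiling(min_length / 2))
      }
    }
    if (n_short > 0L) {
      for (i in seq_len(n_short)) {
        g <- sample.int(nrow(all_g), 1L)
        len <- sample(seq.int(100L, 199L), 1L)
        L <- nchar(all_g$seq[g])
        if (len > L) next
        start <- sample.int(L - len + 1L, 1L) - 1L
        frags[[length(frags) + 1L]] <- list(g = g, start = start,
                                            end = start + len)
      }
    }
    seqs <- vapply(frags, function(f) {
      substr(all_g$seq[f$g], f$start + 1L, f$end)
    }, "")
    if (error_rate > 0) seqs <- cpp_mutate_seqs(seqs, error_rate)
  })
  tibble(
    id = sprintf("ctg_%05d", seq_along(frags)),
    seq = seqs,
    source_genome = all_g$id[vapply(frags, `[[`, 0L, "g")],
    start = as.integer(vapply(frags, function(f) as.numeric(f$start), 0)),
    end = as.integer(vapply(frags, function(f) as.numeric(f$end), 0))
  )
}

#' Simulate a complete two-group cohort with ground truth
#'
#' Runs [generate_genomes()], [integrate_prophages()], [sample_abundances()],
#' [simulate_reads()] and [emit_contigs()] in order.
#'
#' @param config A [sim_config()].
#' @param contig_args List of arguments forwarded to [emit_contigs()].
#' @return A list with `genomes` (incl. `placements`), `truth` (true abundance
#'   tables + metadata), `reads`, `origin`, `contigs`, `phage_db` (tibble
#'   `phage_id`, `family`, `host_genus`, `lifestyle`, `seq`), and `marker_db`
#'   (tibble `marker_id`, `clade`, `genus`, `family`, `seq`).
#' @export
simulate_cohort <- function(config, contig_args = list()) {
  genomes <- generate_genomes(config)
  genomes <- integrate_prophages(genomes, seed = config$seed + 10L)
  truth <- sample_abundances(config)
  rd <- simulate_reads(genomes, truth, config)
  contigs <- do.call(emit_contigs, c(list(genomes = genomes),
                                     contig_args,
                                     list(seed = config$seed + 20L)))
  list(
    genomes = genomes,
    truth = truth,
    reads = rd$reads,
    origin = rd$origin,
    contigs = contigs,
    phage_db = genomes$phages |>
      rename(phage_id = "id") |>
      select("phage_id", "family", "host_genus", "lifestyle", "seq"),
    marker_db = genomes$markers |>
      mutate(clade = sprintf("k__Bacteria|f__%s|g__%s",
                             .data$family, .data$genus)) |>
      select("marker_id", "clade", "genus", "family", "seq")
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
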