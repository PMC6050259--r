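#' Bacterial genus specification for the cohort simulator
#'
#' @param name Genus name (unique across the configuration).
#' @param family Bacterial family the genus belongs to.
#' @param n_species Number of species genomes to simulate for the genus.
#' @param genome_length Genome length in bases (per species).
#' @param n_markers Number of clade-specific marker loci embedded per genome.
#' @param marker_length Marker length in bases.
#' @return A list of class `phgs_genus_spec`.
#' @export
genus_spec <- function(name, family, n_species = 1L, genome_length = 2000L,
                       n_markers = 4L, marker_length = 250L) {
  stopifnot(genome_length > 0, n_species >= 1, n_markers >= 1,
            marker_length > 0,
            n_markers * marker_length <= genome_length)
  structure(list(name = name, family = family,
                 n_species = as.integer(n_species),
                 genome_length = as.integer(genome_length),
                 n_markers = as.integer(n_markers),
                 marker_length = as.integer(marker_length)),
            class = "phgs_genus_spec")
}

#' Phage specification for the cohort simulator
#'
#' @param name Phage name (unique across the configuration).
#' @param host_genus Bacterial host genus name.
#' @param lifestyle `"lytic"` or `"temperate"`. Temperate phages are embedded
#'   as prophages in their host genomes and contribute free particles at the
#'   configured free-particle fraction; lytic phages exist only as free
#'   particles.
#' @param family Phage family (e.g. `"Siphoviridae"`), or `NA`.
#' @param genome_length Genome length in bases.
#' @return A list of class `phgs_phage_spec`.
#' @export
phage_spec <- function(name, host_genus, lifestyle, family = NA_character_,
                       genome_length = 1000L) {
  lifestyle <- match.arg(lifestyle, c("lytic", "temperate"))
  stopifnot(genome_length > 0)
  structure(list(name = name, host_genus = host_genus, lifestyle = lifestyle,
                 family = family, genome_length = as.integer(genome_length)),
            class = "phgs_phage_spec")
}

#' Simulation configuration for a two-group synthetic cohort
#'
#' Defines the cohort layout (group sizes), the community (genera and their
#' phages), the per-taxon log-normal abundance model, multiplicative case
#' effects, and sequencing parameters. All simulator outputs are a pure
#' function of this configuration, including the seed.
#'
#' @param n_cases,n_controls Group sizes (>= 1).
#' @param genera List of [genus_spec()] objects.
#' @param phages List of [phage_spec()] objects.
#' @param base_abundance Tibble with columns `taxon`, `mu`, `sigma`: log-normal
#'   parameters of the pre-normalization abundance of every genus and phage.
#' @param case_effects Named numeric vector of multiplicative factors (> 0)
#'   applied to the named taxa in the case group.
#' @param read_length Read length in bases.
#' @param substitution_error_rate Per-base substitution error rate in `[0, 1)`.
#' @param depth Mean sequencing coverage over the pooled genome length.
#' @param phage_dna_fraction Fraction of sequenced DNA drawn from free phage
#'   particles (the remainder is bacterial, which includes integrated
#'   prophages).
#' @param free_particle_fraction Fraction of a temperate phage's abundance
#'   present as free particles (its integrated copies travel with the host
#'   genome regardless).
#' @param phage_abundance_mode `"independent"` draws phage abundances from
#'   `base_abundance`; `"host_coupled"` sets each phage's relative abundance
#'   equal to its host genus's relative abundance (split equally across a
#'   host's phages), the pure-prophage scenario.
#' @param group_labels Named character vector with entries `case` and
#'   `control` used as group labels in metadata.
#' @param seed Integer seed.
#' @return A list of class `phgs_sim_config`.
#' @export
sim_config <- function(n_cases, n_controls, genera, phages, base_abundance,
                       case_effects = numeric(), read_length = 150L,
                       substitution_error_rate = 0.005, depth = 10,
                       phage_dna_fraction = 0.08,
                       free_particle_fraction = 0.5,
                       phage_abundance_mode = c("independent", "host_coupled"),
                       group_labels = c(case = "PD", control = "control"),
                       seed = 1L) {
  phage_abundance_mode <- match.arg(phage_abundance_mode)
  stopifnot(n_cases >= 1, n_controls >= 1, read_length > 0,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            depth > 0, phage_dna_fraction >= 0, phage_dna_fraction < 1,
            free_particle_fraction >= 0, free_particle_fraction <= 1,
            all(c("case", "control") %in% names(group_labels)))
  genus_names <- vapply(genera, `[[`, "", "name")
  phage_names <- vapply(phages, `[[`, "", "name")
  taxa <- c(genus_names, phage_names)
  if (anyDuplicated(taxa)) {
    abort(sprintf("duplicate taxon names in configuration: %s",
                  paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  missing_hosts <- setdiff(vapply(phages, `[[`, "", "host_genus"), genus_names)
  if (length(missing_hosts)) {
    abort(sprintf("phage host genus absent from configuration: %s",
                  paste(missing_hosts, collapse = ", ")))
  }
  need_ab <- if (phage_abundance_mode == "independent") taxa else genus_names
  missing_ab <- setdiff(need_ab, base_abundance$taxon)
  if (length(missing_ab)) {
    abort(sprintf("taxa missing from base_abundance: %s",
                  paste(missing_ab, collapse = ", ")))
  }
  if (length(case_effects)) {
    stopifnot(all(case_effects > 0), !is.null(names(case_effects)),
              all(names(case_effects) %in% taxa))
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    genera = genera, phages = phages,
    base_abundance = as_tibble(base_abundance),
    case_effects = case_effects,
    read_length = as.integer(read_length),
    substitution_error_rate = substitution_error_rate,
    depth = depth,
    phage_dna_fraction = phage_dna_fraction,
    free_particle_fraction = free_particle_fraction,
    phage_abundance_mode = phage_abundance_mode,
    group_labels = group_labels,
    seed = as.integer(seed)
  ), class = "phgs_sim_config")
}

#' Case-versus-control cohort preset with a depleted Lactococcus-like genus
#'
#' The default study-design preset: 31 cases and 28 controls; a gut-like
#' community of four genera in which *Lactococcus* is depleted 10-fold in the
#' case group while its strictly lytic dairy phages (c2-like and 936-like)
#' are boosted 10-fold; temperate phages (a P335-group lactococcal phage and
#' a lambda-like coliphage) are integrated as prophages in their hosts.
#' Genome sizes are desk-scale stand-ins, not realistic genome lengths.
#'
#' @param seed Integer seed.
#' @param n_cases,n_controls Group sizes.
#' @param host_depletion_factor Case-group multiplicative factor for the
#'   *Lactococcus*-like genus (default 0.1, a 10-fold depletion).
#' @param lytic_phage_boost Case-group factor for the lytic lactococcal
#'   phages (default 10).
#' @param depth Mean coverage.
#' @param substitution_error_rate Per-base substitution error rate.
#' @return A [sim_config()].
#' @export
pd_cohort_config <- function(seed = 1L, n_cases = 31L, n_controls = 28L,
                             host_depletion_factor = 0.1,
                             lytic_phage_boost = 10,
                             depth = 10, substitution_error_rate = 0.005) {
  genera <- list(
    genus_spec("Bacteroides", "Bacteroidaceae"),
    genus_spec("Prevotella", "Prevotellaceae"),
    genus_spec("Escherichia", "Enterobacteriaceae"),
    genus_spec("Lactococcus", "Streptococcaceae")
  )
  phages <- list(
    phage_spec("Lactococcus phage c2", "Lactococcus", "lytic", "Siphoviridae"),
    phage_spec("Lactococcus phage sk1", "Lactococcus", "lytic", "Siphoviridae"),
    phage_spec("Lactococcus phage TP901-1", "Lactococcus", "temperate",
               "Siphoviridae"),
    phage_spec("Bacteroides phage B124-14", "Bacteroides", "lytic",
               "Podoviridae"),
    phage_spec("Enterobacteria phage lambda", "Escherichia", "temperate",
               "Siphoviridae"),
    phage_spec("Enterobacteria phage T4", "Escherichia", "lytic", "Myoviridae")
  )
  base_abundance <- tibble(
    taxon = c("Bacteroides", "Prevotella", "Escherichia", "Lactococcus",
              "Lactococcus phage c2", "Lactococcus phage sk1",
              "Lactococcus phage TP901-1", "Bacteroides phage B124-14",
              "Enterobacteria phage lambda", "Enterobacteria phage T4"),
    mu = log(c(0.55, 0.20, 0.15, 0.10,
               0.10, 0.10, 0.15, 0.35, 0.15, 0.15)),
    sigma = 0.4
  )
  sim_config(
    n_cases = n_cases, n_controls = n_controls,
    genera = genera, phages = phages, base_abundance = base_abundance,
    case_effects = c(
      "Lactococcus" = host_depletion_factor,
      "Lactococcus phage c2" = lytic_phage_boost,
      "Lactococcus phage sk1" = lytic_phage_boost
    ),
    depth = depth, substitution_error_rate = substitution_error_rate,
    seed = seed
  )
}

#' Pure-prophage cohort preset
#'
#' Every genus carries exactly one temperate phage integrated as a prophage,
#' phage abundance is coupled to host abundance, and the free-particle
#' fraction is zero, so all phage reads arise from integrated copies. In this
#' scenario the phage/bacteria ratio of every host genus is 1 by construction
#' (log10 ratio 0, the "stably integrated" band).
#'
#' @param seed Integer seed.
#' @param n_cases,n_controls Group sizes.
#' @param depth Mean coverage.
#' @return A [sim_config()].
#' @export
prophage_cohort_config <- function(seed = 1L, n_cases = 10L, n_controls = 10L,
                                   depth = 10) {
  genera <- list(
    genus_spec("Bacteroides", "Bacteroidaceae"),
    genus_spec("Escherichia", "Enterobacteriaceae"),
    genus_spec("Lactococcus", "Streptococcaceae")
  )
  phages <- list(
    phage_spec("Bacteroides phage b1", "Bacteroides", "temperate",
               "Siphoviridae"),
    phage_spec("Enterobacteria phage lambda", "Escherichia", "temperate",
               "Siphoviridae"),
    phage_spec("Lactococcus phage TP901-1", "Lactococcus", "temperate",
               "Siphoviridae")
  )
  base_abundance <- tibble(
    taxon = c("Bacteroides", "Escherichia", "Lactococcus"),
    mu = log(c(0.5, 0.3, 0.2)),
    sigma = 0.4
  )
  sim_config(
    n_cases = n_cases, n_controls = n_controls,
    genera = genera, phages = phages, base_abundance = base_abundance,
    depth = depth, free_particle_fraction = 0,
    phage_abundance_mode = "host_coupled",
    seed = seed
  )
}
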