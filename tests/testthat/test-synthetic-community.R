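test_that("genome generation is deterministic and markers are genome-unique", {
  cfg <- tiny_cohort_config(seed = 5)
  g1 <- generate_genomes(cfg)
  g2 <- generate_genomes(cfg)
  expect_identical(g1, g2)

  expect_equal(nrow(g1$bacteria), 2L)
  expect_true(all(grepl("^[ACGT]+$", g1$bacteria$seq)))
  expect_true(all(grepl("^[ACGT]+$", g1$phages$seq)))
  # every marker is an exact substring of its genome, at its coordinates
  for (i in seq_len(nrow(g1$markers))) {
    mk <- g1$markers[i, ]
    gseq <- g1$bacteria$seq[g1$bacteria$id == mk$genome_id]
    expect_identical(substr(gseq, mk$start + 1L, mk$end), mk$seq)
  }
  # exhaustive substring search: zero full-length matches in other genera
  for (i in seq_len(nrow(g1$markers))) {
    mk <- g1$markers[i, ]
    others <- g1$bacteria$seq[g1$bacteria$genus != mk$genus]
    expect_false(any(grepl(mk$seq, others, fixed = TRUE)))
  }
})

test_that("duplicate taxon names are a configuration error", {
  expect_error(
    sim_config(
      n_cases = 1, n_controls = 1,
      genera = list(genus_spec("A", "fA"), genus_spec("A", "fA")),
      phages = list(),
      base_abundance = tibble::tibble(taxon = "A", mu = 0, sigma = 1)
    ),
    "duplicate taxon"
  )
})

test_that("prophage integration grows hosts by the phage length, verbatim", {
  cfg <- tiny_cohort_config(seed = 6)
  g <- generate_genomes(cfg)
  before <- nchar(g$bacteria$seq)
  names(before) <- g$bacteria$id
  gi <- integrate_prophages(g, seed = 3)
  after <- nchar(gi$bacteria$seq)
  names(after) <- gi$bacteria$id

  temperate <- g$phages[g$phages$lifestyle == "temperate", ]
  expect_equal(nrow(gi$placements), nrow(temperate))
  for (i in seq_len(nrow(gi$placements))) {
    pl <- gi$placements[i, ]
    phage_seq <- g$phages$seq[g$phages$id == pl$phage_id]
    host_seq <- gi$bacteria$seq[gi$bacteria$id == pl$host_genome_id]
    expect_true(grepl(phage_seq, host_seq, fixed = TRUE))
    expect_gte(pl$offset, 0L)
    expect_lte(pl$offset, before[[pl$host_genome_id]])
  }
  grown <- tapply(nchar(temperate$seq), gi$placements$host_genome_id, sum)
  for (id in gi$bacteria$id) {
    expect_equal(after[[id]] - before[[id]],
                 if (id %in% names(grown)) unname(grown[[id]]) else 0L)
  }
  # lytic phages are never inserted
  lytic <- g$phages$seq[g$phages$lifestyle == "lytic"]
  expect_false(any(vapply(lytic, function(s) {
    any(grepl(s, gi$bacteria$seq, fixed = TRUE))
  }, TRUE)))
  # marker coordinates remain correct after insertion shifts
  for (i in seq_len(nrow(gi$markers))) {
    mk <- gi$markers[i, ]
    gseq <- gi$bacteria$seq[gi$bacteria$id == mk$genome_id]
    expect_identical(substr(gseq, mk$start + 1L, mk$end), mk$seq)
  }
})

test_that("integration without temperate phages is the identity", {
  cfg <- tiny_cohort_config(seed = 7)
  g <- generate_genomes(cfg)
  g$phages <- g$phages[g$phages$lifestyle == "lytic", ]
  gi <- integrate_prophages(g, seed = 1)
  expect_identical(gi$bacteria, g$bacteria)
  expect_equal(nrow(gi$placements), 0L)
})

test_that("a temperate phage without a host genome is an error", {
  cfg <- tiny_cohort_config(seed = 8)
  g <- generate_genomes(cfg)
  g$bacteria <- g$bacteria[g$bacteria$genus != "Lactococcus", ]
  expect_error(integrate_prophages(g, seed = 1), "no genome")
})

test_that("true abundances close to one per domain and encode case effects", {
  cfg <- tiny_cohort_config(seed = 9)
  tr <- sample_abundances(cfg)
  for (tbl in list(tr$bacteria, tr$phage)) {
    sums <- tapply(tbl$abundance, tbl$sample, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }

  # a 0.1 factor on a low-abundance genus is recovered as ~10x at n = 1000
  cfg10 <- sim_config(
    n_cases = 1000, n_controls = 1000,
    genera = list(genus_spec("L", "fL"), genus_spec("B", "fB")),
    phages = list(),
    base_abundance = tibble::tibble(taxon = c("L", "B"),
                                    mu = log(c(0.005, 0.995)), sigma = 0.4),
    case_effects = c(L = 0.1),
    seed = 42
  )
  tr10 <- sample_abundances(cfg10)
  md <- tr10$metadata
  l <- tr10$bacteria[tr10$bacteria$taxon == "L", ]
  grp <- md$group[match(l$sample, md$sample_id)]
  m_ctrl <- mean(l$abundance[grp == "control"])
  m_case <- mean(l$abundance[grp == "PD"])
  ratio <- m_ctrl / m_case
  # 3 Monte-Carlo standard errors of the ratio
  se <- ratio * sqrt(var(l$abundance[grp == "control"]) / m_ctrl^2 +
                       var(l$abundance[grp == "PD"]) / m_case^2) / sqrt(1000)
  expect_lt(abs(ratio - 10), 3 * se + 10 * 0.01) # 1% closure bias allowance
})

test_that("with all effects at one the groups are exchangeable", {
  rejections <- vapply(1:150, function(s) {
    cfg <- sim_config(
      n_cases = 10, n_controls = 10,
      genera = list(genus_spec("L", "fL"), genus_spec("B", "fB")),
      phages = list(),
      base_abundance = tibble::tibble(taxon = c("L", "B"),
                                      mu = log(c(0.3, 0.7)), sigma = 0.4),
      seed = s
    )
    tr <- sample_abundances(cfg)
    l <- tr$bacteria[tr$bacteria$taxon == "L", ]
    grp <- tr$metadata$group[match(l$sample, tr$metadata$sample_id)]
    stats::wilcox.test(l$abundance[grp == "PD"],
                       l$abundance[grp == "control"])$p.value < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.005)
  expect_lte(mean(rejections), 0.12)
})

test_that("a single taxon normalizes to abundance one everywhere", {
  cfg <- sim_config(
    n_cases = 2, n_controls = 2,
    genera = list(genus_spec("L", "fL")), phages = list(),
    base_abundance = tibble::tibble(taxon = "L", mu = 0, sigma = 1),
    seed = 1
  )
  tr <- sample_abundances(cfg)
  expect_true(all(tr$bacteria$abundance == 1))
})

test_that("read counts follow the depth model and errors hit the target rate", {
  cfg <- tiny_cohort_config(seed = 10, n_cases = 2, n_controls = 2, depth = 6)
  g <- integrate_prophages(generate_genomes(cfg), seed = 1)
  tr <- sample_abundances(cfg)
  rd <- simulate_reads(g, tr, cfg)
  # every emitted read id appears in the origin map
  expect_setequal(rd$reads$read_id, rd$origin$read_id)
  L <- sum(nchar(g$bacteria$seq)) + sum(nchar(g$phages$seq))
  lambda <- 4 * cfg$depth * L / cfg$read_length # 4 samples
  expect_lt(abs(nrow(rd$reads) - lambda), 3 * sqrt(lambda))

  # error rate 0: reads are exact substrings of their origin (up to revcomp)
  cfg0 <- tiny_cohort_config(seed = 10, n_cases = 1, n_controls = 1, depth = 2)
  cfg0$substitution_error_rate <- 0
  rd0 <- simulate_reads(g, sample_abundances(cfg0), cfg0)
  genomes <- c(setNames(g$bacteria$seq, g$bacteria$id),
               setNames(g$phages$seq, g$phages$id))
  ok <- vapply(seq_len(nrow(rd0$reads)), function(i) {
    gseq <- genomes[[rd0$origin$genome_id[i]]]
    s <- rd0$reads$seq[i]
    grepl(s, gseq, fixed = TRUE) || grepl(revcomp(s), gseq, fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))

  # error rate 0.01: mismatch fraction vs the error-free draw is binomial
  cfg1 <- cfg0
  cfg1$substitution_error_rate <- 0.01
  rd1 <- simulate_reads(g, sample_abundances(cfg1), cfg1)
  expect_identical(rd0$origin, rd1$origin) # same sampling stream
  n_bases <- sum(nchar(rd1$reads$seq))
  expect_gte(n_bases, 10000)
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, rd0$reads$seq, rd1$reads$seq))
  expect_lt(abs(mism / n_bases - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases))
})

test_that("oversized read lengths against short genomes are an error", {
  cfg <- tiny_cohort_config(seed = 11, n_cases = 1, n_controls = 1)
  cfg$read_length <- 900L # longer than the 800-base phage genomes
  g <- integrate_prophages(generate_genomes(cfg), seed = 1)
  expect_error(simulate_reads(g, sample_abundances(cfg), cfg),
               "read_length")
})

test_that("contig emission respects bounds, determinism and exactness", {
  cfg <- tiny_cohort_config(seed = 12)
  g <- integrate_prophages(generate_genomes(cfg), seed = 1)
  ct <- emit_contigs(g, min_length = 100L, max_length = 5000L, seed = 4)
  expect_true(all(nchar(ct$seq) >= 100 & nchar(ct$seq) <= 5000))
  ct2 <- emit_contigs(g, min_length = 100L, max_length = 5000L, seed = 4)
  expect_identical(ct, ct2)
  # default parameters include sub-200-base fragments for the length filter
  ct3 <- emit_contigs(g, seed = 5)
  expect_true(any(nchar(ct3$seq) < 200))
  # zero perturbation: every contig is an exact substring of one genome
  genomes <- c(setNames(g$bacteria$seq, g$bacteria$id),
               setNames(g$phages$seq, g$phages$id))
  ok <- vapply(seq_len(nrow(ct3)), function(i) {
    grepl(ct3$seq[i], genomes[[ct3$source_genome[i]]], fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))
})
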