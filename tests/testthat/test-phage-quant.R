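# Fixtures built from a two-phage database so contig/read thresholds can be
# exercised on known boundary cases.
make_phage_db <- function(seed = 21, len = 1000L) {
  withr::with_seed(seed, tibble::tibble(
    phage_id = c("phageA", "phageB"),
    family = c("Siphoviridae", "Podoviridae"),
    host_genus = c("Lactococcus", "Bacteroides"),
    lifestyle = c("lytic", "lytic"),
    seq = c(random_seq(len), random_seq(len))
  ))
}

test_that("contig classification enforces the length, e-value and fraction rules", {
  db <- make_phage_db()
  withr::local_seed(22)
  contigs <- tibble::tibble(
    id = c("short_perfect", "half_aligned", "good", "junk", "boundary_200"),
    seq = c(
      substr(db$seq[1], 1, 150),                      # 150 b, perfect hit
      paste0(substr(db$seq[1], 1, 140), random_seq(160)), # 300 b, ~140 aligned
      substr(db$seq[2], 301, 600),                    # 300 b, fully aligned
      random_seq(400),                                # no phage content
      substr(db$seq[1], 1, 200)                       # exactly 200 b
    )
  )
  ca <- classify_contigs(contigs, db)
  expect_identical(ca$contig_id, "good")
  expect_identical(ca$phage_id, "phageB")
  expect_lt(ca$e_value, 1e-5)
  expect_gt(ca$aligned_length, 0.5 * ca$contig_length)
  # 201 bases is the shortest accepted contig ("contigs >200 bp" is strict)
  c201 <- tibble::tibble(id = "c201", seq = substr(db$seq[1], 1, 201))
  expect_identical(classify_contigs(c201, db)$contig_id, "c201")
})

test_that("read recruitment is sensitive to true reads and rejects noise", {
  db <- make_phage_db(seed = 23)
  withr::local_seed(24)
  # contigs tiling phageA with overlap >= read length
  starts <- seq(1, 801, by = 100)
  contigs <- tibble::tibble(
    id = sprintf("tile%02d", seq_along(starts)),
    seq = vapply(starts, function(p) substr(db$seq[1], p, p + 199), "")
  )
  n <- 400L
  pos <- sample(1000 - 150 + 1, n, replace = TRUE)
  seqs <- vapply(pos, function(p) substr(db$seq[1], p, p + 149), "")
  rc <- sample(c(TRUE, FALSE), n, replace = TRUE)
  seqs[rc] <- revcomp(seqs[rc])
  seqs <- getFromNamespace("cpp_mutate_seqs", "phagoscope")(seqs, 0.005)
  reads <- tibble::tibble(read_id = sprintf("r%03d", seq_len(n)),
                          sample = "s1", seq = seqs)
  ra <- recruit_reads(reads, contigs)
  expect_gte(nrow(ra), 0.95 * n)
  expect_true(all(ra$score >= 40))
  expect_lte(dplyr::n_distinct(ra$read_id), n) # at most one contig per read
  expect_identical(anyDuplicated(ra$read_id), 0L)

  # reads from an unrelated random genome recruit nothing
  noise <- tibble::tibble(
    read_id = sprintf("n%03d", 1:200), sample = "s1",
    seq = vapply(1:200, function(i) random_seq(150), "")
  )
  expect_identical(nrow(recruit_reads(noise, contigs)), 0L)
  expect_identical(nrow(recruit_reads(reads, contigs[0, ])), 0L)
})

test_that("per-phage counts combine contig-level recruits with conservation", {
  ca <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                       phage_id = c("pA", "pA", "pB"))
  ra <- tibble::tibble(
    read_id = sprintf("r%d", 1:9),
    sample = rep("s1", 9),
    contig_id = c(rep("c1", 3), rep("c2", 4), rep("c3", 2)),
    score = 100L, percent_identity = 99, aligned_length = 150L
  )
  ct <- count_phage_abundance(ra, ca)
  counts <- abundance_matrix(ct$counts, "count")
  expect_equal(counts["pA", "s1"], 7)
  expect_equal(counts["pB", "s1"], 2)
  expect_equal(sum(counts), nrow(ra))
  # a phage with no assigned contig is absent
  expect_false("pC" %in% ct$counts$taxon)
})

test_that("the detection threshold keeps only well-supported phage calls", {
  ca <- tibble::tibble(contig_id = c("c1", "c2", "c3", "c4"),
                       phage_id = c("pA", "pB", "pC", "pD"))
  ra <- tibble::tibble(
    read_id = sprintf("r%d", 1:12),
    sample = "s1",
    contig_id = c("c1",                    # pA: 1 qualifying read
                  "c2", "c2",              # pB: 2 reads at 95% over 120
                  rep("c3", 5),            # pC: 5 reads at 85%
                  rep("c4", 4)),           # pD: boundary identities/lengths
    score = 100L,
    percent_identity = c(95, 95, 95, rep(85, 5), 90, 95, 95, 95),
    aligned_length = c(120L, 120L, 120L, rep(150L, 5), 150L, 100L, 150L, 150L)
  )
  ct <- apply_detection_threshold(count_phage_abundance(ra, ca))
  counts <- abundance_matrix(ct$counts, "count")
  expect_false("pA" %in% rownames(counts)) # 1 read is below the 2-read rule
  expect_equal(counts["pB", "s1"], 2)      # 95% over 120 bases qualifies
  expect_false("pC" %in% rownames(counts)) # 85% identity never qualifies
  # pD: identity exactly 90 and length exactly 100 are excluded (strict),
  # leaving exactly the two fully qualifying reads
  expect_equal(counts["pD", "s1"], 2)
  # idempotence
  ct2 <- apply_detection_threshold(ct)
  expect_identical(ct2$counts, ct$counts)
  # thresholding never increases any cell
  raw <- count_phage_abundance(ra, ca)$counts
  joined <- dplyr::left_join(raw, ct$counts, by = c("taxon", "sample"),
                             suffix = c("_raw", "_flt"))
  expect_true(all(dplyr::coalesce(joined$count_flt, 0L) <= joined$count_raw))
})

test_that("relative abundance closes to one and flags all-zero samples", {
  counts <- make_abundance(list(s1 = c(a = 2, b = 8)), value = "count")
  rel <- relative_abundance(counts)
  expect_equal(sort(rel$abundance), c(0.2, 0.8))
  single <- relative_abundance(make_abundance(list(s1 = c(a = 5)),
                                              value = "count"))
  expect_equal(single$abundance, 1)
  multi <- make_abundance(list(s1 = c(a = 3, b = 1), s2 = c(a = 2, b = 5)),
                          value = "count")
  rel2 <- relative_abundance(multi)
  expect_true(all(abs(tapply(rel2$abundance, rel2$sample, sum) - 1) < 1e-9))
  expect_warning(
    rel3 <- relative_abundance(counts, samples = c("s1", "s_empty")),
    "all-zero"
  )
  expect_equal(sum(rel3$abundance[rel3$sample == "s_empty"]), 0)
})

test_that("the prevalence floor removes taxa below 1e-4 in every sample", {
  tbl <- make_abundance(list(
    s1 = c(rare = 5e-5, kept = 1e-3, gone = 0),
    s2 = c(rare = 4e-5, kept = 0, gone = 9e-5)
  ))
  out <- prevalence_filter(tbl)
  expect_setequal(unique(out$taxon), "kept")
  expect_identical(prevalence_filter(out), out) # idempotent
  empty <- tbl[0, ]
  expect_identical(nrow(prevalence_filter(empty)), 0L)
})

test_that("the group screen applies the two-sample 0.01% presence rule", {
  md <- tibble::tibble(sample_id = c("c1", "c2", "c3", "p1", "p2", "p3"),
                       group = rep(c("control", "PD"), each = 3))
  tbl <- make_abundance(list(
    c1 = c(case_only = 0,    both = 3e-4, one_sample = 0,    ctrl_only = 2e-4),
    c2 = c(case_only = 0,    both = 2e-4, one_sample = 0,    ctrl_only = 2e-4),
    c3 = c(case_only = 0,    both = 0,    one_sample = 0,    ctrl_only = 0),
    p1 = c(case_only = 2e-4, both = 5e-4, one_sample = 2e-4, ctrl_only = 0),
    p2 = c(case_only = 2e-4, both = 2e-4, one_sample = 0,    ctrl_only = 0),
    p3 = c(case_only = 0,    both = 0,    one_sample = 0,    ctrl_only = 0)
  ))
  sc <- group_presence_screen(tbl, md)
  get <- function(tx, g, col) sc[[col]][sc$taxon == tx & sc$group == g]
  expect_true(get("case_only", "PD", "exclusive"))
  expect_false(get("case_only", "control", "present"))
  expect_true(get("ctrl_only", "control", "exclusive"))
  expect_false(get("one_sample", "PD", "present"))   # one sample is not enough
  expect_false(get("one_sample", "control", "present"))
  expect_true(get("both", "PD", "present") && get("both", "control", "present"))
  expect_false(any(sc$exclusive[sc$taxon == "both"]))
  expect_error(group_presence_screen(tbl, md[-1, ]), "missing from metadata")
})

test_that("family aggregation is additive, conserving and pools unannotated", {
  db <- tibble::tibble(phage_id = c("p1", "p2", "p3"),
                       family = c("Siphoviridae", "Siphoviridae", NA))
  tbl <- make_abundance(list(s1 = c(p1 = 0.3, p2 = 0.2, p3 = 0.5)))
  fam <- aggregate_by_family(tbl, db)
  expect_equal(fam$abundance[fam$taxon == "Siphoviridae"], 0.5)
  expect_equal(fam$abundance[fam$taxon == "unclassified"], 0.5)
  expect_equal(sum(fam$abundance), sum(tbl$abundance))
  all_un <- aggregate_by_family(tbl, dplyr::mutate(db, family = NA))
  expect_identical(unique(all_un$taxon), "unclassified")
  expect_equal(all_un$abundance, 1)
})

test_that("estimated phage abundances track the simulated truth", {
  # lytic-only cohort (clean free-particle quantification), equal genome sizes
  cfg <- sim_config(
    n_cases = 3, n_controls = 3,
    genera = list(genus_spec("Lactococcus", "Streptococcaceae",
                             genome_length = 1500L),
                  genus_spec("Bacteroides", "Bacteroidaceae",
                             genome_length = 1500L)),
    phages = list(
      phage_spec("Lactococcus phage c2", "Lactococcus", "lytic", "Siphoviridae"),
      phage_spec("Lactococcus phage sk1", "Lactococcus", "lytic", "Siphoviridae"),
      phage_spec("Bacteroides phage b1", "Bacteroides", "lytic", "Podoviridae"),
      phage_spec("Bacteroides phage b2", "Bacteroides", "lytic", "Myoviridae")
    ),
    base_abundance = tibble::tibble(
      taxon = c("Lactococcus", "Bacteroides",
                "Lactococcus phage c2", "Lactococcus phage sk1",
                "Bacteroides phage b1", "Bacteroides phage b2"),
      mu = log(c(0.5, 0.5, 0.45, 0.25, 0.2, 0.1)), sigma = 0.4
    ),
    depth = 8, phage_dna_fraction = 0.25, substitution_error_rate = 0.005,
    seed = 31
  )
  cohort <- simulate_cohort(cfg)
  q <- quantify_phages(cohort$contigs, cohort$reads, cohort$phage_db)
  truth <- cohort$truth$phage
  est <- q$abundance
  rho <- vapply(unique(truth$sample), function(s) {
    t_s <- truth[truth$sample == s, ]
    e_s <- est[est$sample == s, ]
    merged <- dplyr::left_join(t_s, e_s, by = c("taxon", "sample"),
                               suffix = c("_true", "_est"))
    merged$abundance_est[is.na(merged$abundance_est)] <- 0
    cor(merged$abundance_true, merged$abundance_est, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})
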