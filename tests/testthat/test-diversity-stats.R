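test_that("Shannon diversity matches closed forms and the vegan oracle", {
  expect_equal(shannon_index(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(7)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon_index(c(1, 2, 3)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "zero total")
  skip_if_not_installed("vegan")
  withr::local_seed(51)
  for (i in 1:5) {
    x <- rpois(20, 5)
    x[1] <- x[1] + 1
    expect_equal(shannon_index(x), unname(vegan::diversity(x, "shannon")))
  }
})

test_that("Simpson indices match closed forms and rescaling invariance", {
  s1 <- simpson_indices(c(5))
  expect_equal(s1$simpson, 0)
  expect_equal(s1$inv_simpson, 1)
  s4 <- simpson_indices(rep(3, 4))
  expect_equal(s4$simpson, 0.75)
  expect_equal(s4$inv_simpson, 4)
  s <- simpson_indices(c(1, 3))
  expect_equal(s$simpson, 0.375)
  expect_equal(s$inv_simpson, 1.6)
  # scale invariance via p_i
  a <- c(4, 9, 2, 11)
  expect_equal(simpson_indices(a), simpson_indices(10 * a))
  expect_equal(shannon_index(a), shannon_index(10 * a))
})

test_that("Chao1 uses the classic form with the doubleton-free fallback", {
  expect_equal(chao1_richness(c(3, 4, 5)), 3) # F1 = 0
  expect_equal(chao1_richness(c(1, 1, 2, 5, 6)), 5 + 4 / 2)
  expect_equal(chao1_richness(c(1, 1, 1, 3)), 4 + 3 * 2 / 2) # F2 = 0 fallback
  # never below observed richness
  withr::local_seed(52)
  for (i in 1:20) {
    x <- rpois(30, 2)
    expect_gte(chao1_richness(x), sum(x > 0))
  }
  expect_error(chao1_richness(c(1.5, 2)), "integer")
})

test_that("ACE matches its formula, degenerate fallback and vegan oracle", {
  expect_equal(ace_richness(c(15, 20, 30)), 3) # no rare taxa
  # hand evaluation for {1,1,2,12}: S_abund=1, S_rare=3, F1=2, N_rare=4,
  # C=0.5, gamma^2 = max(6 * 2/12 - 1, 0) = 0 -> 1 + 3/0.5 + 0 = 7
  expect_equal(ace_richness(c(1, 1, 2, 12)), 7)
  expect_warning(all_single <- ace_richness(c(1, 1, 1)), "Chao1")
  expect_equal(all_single, chao1_richness(c(1, 1, 1)))
  withr::local_seed(53)
  for (i in 1:20) {
    x <- rpois(30, 3)
    if (all(x == 0)) next
    r <- x[x > 0 & x <= 10]
    if (length(r) && sum(r) > 1 && sum(r == 1) < sum(r)) {
      expect_gte(ace_richness(x), sum(x > 0))
      skip_if_not_installed("vegan")
      expect_equal(ace_richness(x),
                   unname(vegan::estimateR(x)["S.ACE"]), tolerance = 1e-8)
    }
  }
})

test_that("alpha_diversity computes all indices per sample from counts", {
  tbl <- make_abundance(list(s1 = c(a = 10, b = 10, c = 10, d = 10),
                             s2 = c(a = 40, b = 0, c = 0, d = 0)),
                        value = "count")
  a <- alpha_diversity(tbl)
  expect_equal(a$shannon[a$sample == "s1"], log(4))
  expect_equal(a$shannon[a$sample == "s2"], 0)
  expect_equal(a$inv_simpson[a$sample == "s1"], 4)
  expect_equal(a$chao1[a$sample == "s2"], 1)
})

test_that("Bray-Curtis dissimilarity matches its formula and vegan", {
  tbl <- make_abundance(list(s1 = c(a = 2, b = 2), s2 = c(a = 1, b = 1),
                             s3 = c(a = 2, b = 2)))
  d <- as.matrix(bray_curtis(tbl))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 2 / 6)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  disjoint <- make_abundance(list(s1 = c(a = 1, b = 0), s2 = c(a = 0, b = 4)))
  expect_equal(as.matrix(bray_curtis(disjoint))["s1", "s2"], 1)
  expect_warning(z <- bray_curtis(make_abundance(
    list(s1 = c(a = 0), s2 = c(a = 0)))), "all-zero")
  expect_true(is.na(as.matrix(z)["s1", "s2"]))
  skip_if_not_installed("vegan")
  withr::local_seed(54)
  m <- matrix(rpois(60, 5), nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  mine <- as.matrix(bray_curtis(as_abundance_tibble(m)))
  ref <- as.matrix(vegan::vegdist(t(m), "bray"))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("Spearman dissimilarity maps rank agreement onto [0, 1]", {
  same_order <- make_abundance(list(s1 = c(a = 1, b = 2, c = 3),
                                    s2 = c(a = 10, b = 20, c = 30)))
  expect_equal(as.matrix(spearman_dissimilarity(same_order))["s1", "s2"], 0)
  reversed <- make_abundance(list(s1 = c(a = 1, b = 2, c = 3),
                                  s2 = c(a = 3, b = 2, c = 1)))
  expect_equal(as.matrix(spearman_dissimilarity(reversed))["s1", "s2"], 1)
  withr::local_seed(55)
  big <- make_abundance(list(s1 = runif(10000), s2 = runif(10000)) |>
                          lapply(function(v) setNames(v, paste0("t", 1:10000))))
  d <- as.matrix(spearman_dissimilarity(big))["s1", "s2"]
  expect_lt(abs(d - 0.5), 3 * 0.5 / sqrt(9999))
  expect_warning(spearman_dissimilarity(make_abundance(
    list(s1 = c(a = 1, b = 1), s2 = c(a = 1, b = 2)))), "constant")
  expect_error(spearman_dissimilarity(make_abundance(list(s1 = c(a = 1)))),
               "two taxa")
})

test_that("PCoA reproduces hand-computed and Euclidean geometries", {
  # two samples at distance 2: coordinates +-1 on one axis, eigenvalue 2
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(stats::as.dist(d2))
  expect_equal(sort(ord$coordinates$axis_1), c(-1, 1))
  expect_equal(ord$eigenvalues[1], 2)
  # all-zero matrix
  z <- pcoa(matrix(0, 3, 3))
  expect_true(all(abs(z$eigenvalues) < 1e-10))
  expect_true(all(z$coordinates[, -1] == 0))
  # equilateral triple at distance 1: two equal positive eigenvalues
  e3 <- matrix(1, 3, 3) - diag(3)
  orde <- pcoa(e3)
  pos <- orde$eigenvalues[orde$eigenvalues > 1e-10]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_equal(pos[1], 0.5, tolerance = 1e-9)
  # Euclidean reconstruction to 1e-8, and agreement with cmdscale
  withr::local_seed(56)
  pts <- matrix(rnorm(40), nrow = 8)
  d <- dist(pts)
  ordr <- pcoa(d)
  coords <- as.matrix(ordr$coordinates[, -1])
  expect_equal(as.matrix(dist(coords)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  ref <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(ordr$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-8)
  # coordinates are centered
  expect_true(all(abs(colMeans(coords)) < 1e-9))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Mann-Whitney p-values are exact by enumeration on small samples", {
  md <- tibble::tibble(sample_id = paste0("s", 1:4),
                       group = c("A", "A", "B", "B"))
  v1 <- tibble::tibble(sample = paste0("s", 1:4), value = c(1, 2, 3, 4))
  t1 <- group_compare(v1, md, method = "mann_whitney")
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1 / 3)
  v2 <- tibble::tibble(sample = paste0("s", 1:4), value = c(1, 3, 2, 4))
  t2 <- group_compare(v2, md, method = "mann_whitney")
  expect_equal(t2$statistic, 1)
  expect_equal(t2$p_value, 2 / 3)
  # exact branch agrees with wilcox.test's exact p on tie-free data
  withr::local_seed(57)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(100, n1 + n2)
    mdx <- tibble::tibble(sample_id = paste0("s", seq_len(n1 + n2)),
                          group = rep(c("A", "B"), c(n1, n2)))
    vx <- tibble::tibble(sample = mdx$sample_id, value = vals)
    mine <- group_compare(vx, mdx, method = "mann_whitney")
    ref <- stats::wilcox.test(vals[seq_len(n1)], vals[-seq_len(n1)],
                              exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal test", {
  withr::local_seed(58)
  for (i in 1:8) {
    v <- c(round(rnorm(15, 0, 2)), round(rnorm(16, 0.5, 2))) # plenty of ties
    md <- tibble::tibble(sample_id = paste0("s", 1:31),
                         group = rep(c("A", "B"), c(15, 16)))
    vx <- tibble::tibble(sample = md$sample_id, value = v)
    mine <- group_compare(vx, md, method = "mann_whitney")
    expect_identical(mine$method, "mann_whitney_normal")
    ref <- suppressWarnings(stats::wilcox.test(v[1:15], v[16:31],
                                               exact = FALSE, correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA is delegated with F = 0 for identical group means", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       group = rep(c("A", "B"), each = 3))
  v <- tibble::tibble(sample = md$sample_id, value = c(1, 2, 3, 1, 2, 3))
  t0 <- group_compare(v, md, method = "anova")
  expect_equal(t0$statistic, 0)
  expect_error(group_compare(v[1:3, ], md[c(1:3), ], method = "anova"),
               "two")
})

test_that("PERMANOVA matches brute-force enumeration and vegan on a toy", {
  withr::local_seed(59)
  pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 2), 3))
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       group = rep(c("g1", "g2"), each = 3))
  res <- permanova(d, md, n_permutations = 4999, seed = 2)

  # brute-force oracle: pseudo-F over all 20 group assignments
  m2 <- as.matrix(d)^2
  f_of <- function(lab) {
    n <- 6; g <- 2
    sst <- sum(m2[upper.tri(m2)]) / n
    ssw <- 0
    for (gg in unique(lab)) {
      idx <- which(lab == gg)
      ssw <- ssw + sum(m2[idx, idx][upper.tri(m2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  }
  obs <- f_of(md$group)
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("g2", 6); lab[idx] <- "g1"; f_of(lab)
  })
  p_exact <- mean(f_all >= obs - 1e-12)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.02)

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(d ~ group,
                        data = data.frame(group = md$group), permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA p-values are reproducible and floor at the add-one bound", {
  withr::local_seed(60)
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  rownames(pts) <- paste0("s", 1:8)
  md <- tibble::tibble(sample_id = paste0("s", 1:8),
                       group = rep(c("a", "b"), each = 4))
  r1 <- permanova(dist(pts), md, n_permutations = 199, seed = 7)
  r2 <- permanova(dist(pts), md, n_permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$details$f_permuted, r2$details$f_permuted)
  # perfect separation: only label-preserving permutations reach F_obs
  expect_equal(r1$p_value, (1 + sum(r1$details$f_permuted >= r1$statistic)) / 200)
  expect_lte(r1$p_value, 0.05)
  expect_error(permanova(dist(pts), dplyr::mutate(md, group = "a")), "two groups")
})

test_that("diversity indices are invariant to taxon ordering", {
  withr::local_seed(61)
  x <- rpois(15, 4) + 1
  perm <- sample(length(x))
  expect_equal(shannon_index(x), shannon_index(x[perm]))
  expect_equal(simpson_indices(x), simpson_indices(x[perm]))
  expect_equal(chao1_richness(x), chao1_richness(x[perm]))
  expect_equal(ace_richness(x), ace_richness(x[perm]))
})

test_that("tidy and glance summarise test and ordination objects", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       group = rep(c("A", "B"), each = 3))
  v <- tibble::tibble(sample = md$sample_id, value = c(1, 2, 3, 4, 5, 6))
  tt <- group_compare(v, md, method = "mann_whitney")
  td <- tidy(tt)
  expect_identical(names(td), c("statistic", "p.value", "method"))
  ord <- pcoa(dist(matrix(rnorm(12), 4)))
  expect_identical(tidy(ord), ord$coordinates)
  g <- glance(ord)
  expect_equal(g$n_samples, 4L)
})
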