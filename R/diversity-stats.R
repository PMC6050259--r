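#' Shannon diversity of a count vector
#'
#' `H = -sum p_i ln p_i` over taxa with positive counts, natural log.
#'
#' @param x Non-negative counts (or abundances) with positive total.
#' @return H, in `[0, ln S_obs]`.
#' @export
shannon_index <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) <= 0) abort("shannon_index: zero total count")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Simpson and inverse Simpson indices of a count vector
#'
#' `D = 1 - sum p_i^2` and `1 / sum p_i^2`.
#'
#' @param x Non-negative counts with positive total.
#' @return Named list `simpson` (in `[0, 1)`) and `inv_simpson` (>= 1).
#' @export
simpson_indices <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) <= 0) abort("simpson_indices: zero total count")
  p <- x[x > 0] / sum(x)
  s2 <- sum(p^2)
  list(simpson = 1 - s2, inv_simpson = 1 / s2)
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` when doubletons exist, and the
#' `S_obs + F1 (F1 - 1) / 2` fallback when `F2 = 0`. Always at least `S_obs`.
#'
#' @param x Non-negative integer counts.
#' @return The Chao1 estimate.
#' @export
chao1_richness <- function(x) {
  x <- check_integer_counts(x)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' ACE (abundance-based coverage estimator) richness
#'
#' Taxa with counts at or below `rare_cutoff` form the rare group. With
#' `N_rare` the individuals in rare taxa, sample coverage
#' `C = 1 - F1 / N_rare`, and the coefficient-of-variation term
#' `gamma^2 = max(S_rare / C * sum_{i<=cutoff} i (i-1) F_i /
#' (N_rare (N_rare - 1)) - 1, 0)`:
#' `ACE = S_abund + S_rare / C + F1 / C * gamma^2`. When every rare
#' individual is a singleton (`C = 0`) the estimate falls back to
#' [chao1_richness()] with a warning.
#'
#' @param x Non-negative integer counts.
#' @param rare_cutoff Rare-taxon count cutoff (default 10).
#' @return The ACE estimate (equals `S_obs` when no taxon is rare).
#' @export
ace_richness <- function(x, rare_cutoff = 10L) {
  x <- check_integer_counts(x)
  pos <- x[x > 0]
  rare <- pos[pos <= rare_cutoff]
  s_abund <- sum(pos > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warn("ACE coverage is zero (all rare individuals are singletons); falling back to Chao1")
    return(chao1_richness(x))
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), 0)
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

check_integer_counts <- function(x) {
  stopifnot(all(x >= 0))
  if (any(abs(x - round(x)) > 1e-8)) {
    abort("richness estimators require integer counts")
  }
  round(x)
}

#' Per-sample alpha-diversity indices
#'
#' Computes ACE, Chao1, Shannon, Simpson and inverse Simpson per sample from
#' integer read counts. Richness estimators are undefined on relative
#' abundances, so counts (post detection threshold, pre normalization) are
#' the expected input.
#'
#' @param tbl Long counts tibble (`taxon`, `sample`, `count`).
#' @param rare_cutoff ACE rare-taxon cutoff.
#' @return Tibble `sample`, `ace`, `chao1`, `shannon`, `simpson`,
#'   `inv_simpson`.
#' @export
alpha_diversity <- function(tbl, rare_cutoff = 10L) {
  m <- abundance_matrix(tbl, value = abundance_value_col(tbl))
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    si <- simpson_indices(x)
    tibble(sample = s,
           ace = ace_richness(x, rare_cutoff),
           chao1 = chao1_richness(x),
           shannon = shannon_index(x),
           simpson = si$simpson,
           inv_simpson = si$inv_simpson)
  })
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, symmetric with zero
#' diagonal, in `[0, 1]` for non-negative data. Pairs of all-zero samples are
#' undefined and returned as `NA` with a warning.
#'
#' @param tbl Long abundance tibble (`taxon`, `sample`, value column).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(tbl) {
  m <- abundance_matrix(tbl)
  stopifnot(all(m >= 0))
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  undefined <- FALSE
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      denom <- sum(m[, i] + m[, j])
      if (denom == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- TRUE
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
      }
    }
  }
  if (undefined) warn("Bray-Curtis undefined for pair(s) of all-zero samples (NA)")
  stats::as.dist(d)
}

#' Spearman rank dissimilarity between samples
#'
#' `d = (1 - rho) / 2` where `rho` is the Spearman rank correlation of the
#' two samples' taxon abundance vectors; `d` is 0 for identical rank order,
#' 1 for exactly reversed ranks, and about 0.5 for unrelated compositions.
#' Pairs involving a constant abundance vector are undefined (`NA`, warned).
#'
#' @param tbl Long abundance tibble with at least two taxa.
#' @return A `dist` object over samples.
#' @export
spearman_dissimilarity <- function(tbl) {
  m <- abundance_matrix(tbl)
  if (nrow(m) < 2L) abort("spearman_dissimilarity requires at least two taxa")
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  undefined <- FALSE
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- TRUE
      } else {
        rho <- cor(m[, i], m[, j], method = "spearman")
        d[i, j] <- d[j, i] <- (1 - rho) / 2
      }
    }
  }
  if (undefined) warn("Spearman dissimilarity undefined for constant sample(s) (NA)")
  stats::as.dist(d)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2` (Gower centering) and eigendecomposes it.
#' Axes with non-positive eigenvalues are excluded from the coordinates;
#' for a Euclidean distance matrix the retained coordinates reproduce the
#' input distances exactly.
#'
#' @param d A symmetric zero-diagonal dissimilarity (`dist` or matrix).
#' @return An object of class `phgs_ordination`: list with `coordinates`
#'   (tibble `sample`, `axis_1`, ...; columns centered), `eigenvalues`
#'   (non-increasing, all axes), and `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    abort("pcoa requires a symmetric dissimilarity matrix")
  }
  if (any(abs(diag(m)) > 1e-12)) {
    abort("pcoa requires a zero diagonal")
  }
  n <- nrow(m)
  samples <- rownames(m) %||% paste0("s", seq_len(n))
  a <- -0.5 * m^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-10
  coords <- if (any(pos)) {
    e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), nrow = sum(pos))
  } else {
    matrix(0, n, 1L)
  }
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(sample = samples),
                                   as_tibble(coords)),
    eigenvalues = e$values,
    proportion_explained = if (any(pos)) {
      e$values[pos] / sum(e$values[pos])
    } else {
      numeric()
    }
  ), class = "phgs_ordination")
}

#' @export
print.phgs_ordination <- function(x, ...) {
  cat(sprintf("<phgs_ordination> %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1L))
  if (length(x$proportion_explained)) {
    cat("proportion explained:",
        paste(sprintf("%.1f%%", 100 * head(x$proportion_explained, 4L)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

new_phgs_test <- function(statistic, p_value, method, n_permutations = NA_integer_,
                          seed = NA_integer_, details = list()) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_permutations = n_permutations, seed = seed,
                 details = details),
            class = "phgs_test")
}

#' @export
print.phgs_test <- function(x, ...) {
  cat(sprintf("<phgs_test> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Two-group or k-group comparison of a per-sample statistic
#'
#' `method = "mann_whitney"` computes the Mann-Whitney U statistic; the
#' two-sided p-value is exact (full enumeration of group assignments,
#' counting arrangements with `|U - mn/2|` at least as extreme) when the
#' combined sample size is at most `exact_max`, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#' `method = "anova"` is the one-way fixed-effects F test
#' (equal-variance [stats::oneway.test()]).
#'
#' @param values Tibble `sample`, `value` (one row per sample).
#' @param metadata Tibble `sample_id`, `group`.
#' @param method `"mann_whitney"` (two groups) or `"anova"` (two or more).
#' @param exact_max Largest combined n for the exact Mann-Whitney p.
#' @return A `phgs_test` object.
#' @export
group_compare <- function(values, metadata,
                          method = c("mann_whitney", "anova"),
                          exact_max = 12L) {
  method <- match.arg(method)
  check_metadata(metadata, values$sample)
  g <- metadata$group[match(values$sample, metadata$sample_id)]
  groups <- unique(g)
  if (any(table(g) == 0L) || length(groups) < 2L) {
    abort("group_compare requires at least two non-empty groups")
  }
  v <- values$value
  if (method == "mann_whitney") {
    if (length(groups) != 2L) {
      abort("mann_whitney requires exactly two groups")
    }
    mw <- mann_whitney_u(v[g == groups[1L]], v[g == groups[2L]], exact_max)
    new_phgs_test(mw$u, mw$p, if (mw$exact) "mann_whitney_exact"
                  else "mann_whitney_normal")
  } else {
    fit <- oneway.test(v ~ factor(g), var.equal = TRUE)
    new_phgs_test(unname(fit$statistic), unname(fit$p.value), "anova_oneway")
  }
}

mann_whitney_u <- function(a, b, exact_max = 12L) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= exact_max) {
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
    center <- m * n / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-12)
    list(u = u, p = p, exact = TRUE)
  } else {
    nt <- table(pooled)
    N <- m + n
    tie_term <- sum(nt^3 - nt) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    z <- (abs(u - m * n / 2) - 0.5) / sqrt(sigma2)
    list(u = u, p = min(1, 2 * pnorm(-max(z, 0))), exact = FALSE)
  }
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / n`) into within- and between-group parts
#' and forms the pseudo-F statistic
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. The p-value is the
#' add-one permutation estimate `(1 + #{F_perm >= F_obs}) / (1 + P)` over `P`
#' random label permutations drawn with the given seed, so p-values are
#' reproducible bit-for-bit.
#'
#' @param d A `dist` or symmetric zero-diagonal matrix over samples.
#' @param metadata Tibble `sample_id`, `group` (each group n >= 2).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `phgs_test` with the observed pseudo-F and permutation p-value.
#' @export
permanova <- function(d, metadata, n_permutations = 999L, seed = 1L) {
  m <- as.matrix(d)
  samples <- rownames(m) %||% metadata$sample_id
  check_metadata(metadata, samples)
  g <- factor(metadata$group[match(samples, metadata$sample_id)])
  if (nlevels(g) < 2L) abort("permanova requires at least two groups")
  if (any(table(g) < 2L)) abort("permanova requires n >= 2 per group")
  labels <- as.integer(g)
  d2 <- m^2
  f_obs <- cpp_permanova_f(d2, matrix(labels, ncol = 1L), nlevels(g))[1L]
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) sample(labels),
           integer(length(labels)))
  })
  f_perm <- cpp_permanova_f(d2, perms, nlevels(g))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
  new_phgs_test(f_obs, p, "permanova", n_permutations = n_permutations,
                seed = seed, details = list(f_permuted = f_perm))
}
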