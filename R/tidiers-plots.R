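#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname phgs_test_tidiers
#' @export
tidy.phgs_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}

#' Tidiers for phagoscope test objects
#'
#' `tidy()` returns the statistic and p-value; `glance()` adds the
#' permutation setup where applicable.
#'
#' @param x A `phgs_test` object.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @name phgs_test_tidiers
#' @export
glance.phgs_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @rdname phgs_ordination_tidiers
#' @export
tidy.phgs_ordination <- function(x, ...) {
  x$coordinates
}

#' Tidiers for ordination results
#'
#' `tidy()` returns the sample coordinates; `glance()` summarises the
#' eigenvalue spectrum.
#'
#' @param x A `phgs_ordination` from [pcoa()].
#' @param ... Ignored.
#' @return A tibble.
#' @name phgs_ordination_tidiers
#' @export
glance.phgs_ordination <- function(x, ...) {
  tibble(
    n_samples = nrow(x$coordinates),
    n_positive_axes = sum(x$eigenvalues > 1e-10),
    prop_axis_1 = x$proportion_explained[1] %||% NA_real_,
    prop_axis_2 = if (length(x$proportion_explained) >= 2) {
      x$proportion_explained[2]
    } else {
      NA_real_
    }
  )
}

#' PCoA ordination plot
#'
#' @param object A `phgs_ordination`.
#' @param metadata Optional `sample_id`/`group` tibble for coloring.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.phgs_ordination <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (!"axis_2" %in% names(df)) df$axis_2 <- 0
  if (!is.null(metadata)) {
    df <- df |> left_join(metadata, by = c(sample = "sample_id"))
  }
  pe <- object$proportion_explained
  lab <- function(i) {
    if (length(pe) >= i) {
      sprintf("PCo%d (%.1f%%)", i, 100 * pe[i])
    } else {
      sprintf("PCo%d", i)
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis_1, y = .data$axis_2)) +
    ggplot2::labs(x = lab(1L), y = lab(2L)) +
    ggplot2::theme_minimal()
  if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group,
                                         shape = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Alpha-diversity comparison plot
#'
#' Boxplots of each diversity index by group.
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Tibble `sample_id`, `group`.
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(alpha, metadata) {
  long <- alpha |>
    tidyr::pivot_longer(-"sample", names_to = "index", values_to = "value") |>
    left_join(metadata, by = c(sample = "sample_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Phage/bacteria ratio plot
#'
#' Group-level log10 phage/bacteria ratios per host genus, with the
#' integrated-prophage band at log10 R = 0.
#'
#' @param object A `phgs_ratio` from [phage_bacteria_ratio()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.phgs_ratio <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$level == "group", .data$status == "defined")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$host_genus,
                                   y = .data$log10_ratio,
                                   fill = .data$unit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "log10 phage/bacteria ratio",
                  fill = "group") +
    ggplot2::theme_minimal()
}

#' Per-phage case/control log-ratio plot
#'
#' Diverging bars of log10 case/control abundance ratios (positive up in
#' cases, negative down).
#'
#' @param log_ratios Output of [lifestyle_log_ratio()].
#' @return A ggplot.
#' @export
plot_lifestyle_log_ratio <- function(log_ratios) {
  ggplot2::ggplot(log_ratios,
                  ggplot2::aes(x = stats::reorder(.data$taxon,
                                                  .data$log10_ratio),
                               y = .data$log10_ratio,
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(down = "#c0392b", up = "#27ae60",
                                          equal = "grey60")) +
    ggplot2::labs(x = NULL, y = "log10 case/control abundance ratio") +
    ggplot2::theme_minimal()
}

#' Family-level composition plot
#'
#' Stacked relative abundance of phage families per sample.
#'
#' @param family_tbl Output of [aggregate_by_family()].
#' @param metadata Optional `sample_id`/`group` tibble for faceting.
#' @return A ggplot.
#' @export
plot_family_composition <- function(family_tbl, metadata = NULL) {
  df <- family_tbl
  if (!is.null(metadata)) {
    df <- df |> left_join(metadata, by = c(sample = "sample_id"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample,
                                        y = .data$abundance,
                                        fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(metadata)) {
    p <- p + ggplot2::facet_grid(~group, scales = "free_x", space = "free_x")
  }
  p
}
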