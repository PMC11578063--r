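# ggplot2 views of the main result types.

#' Heatmap of summary ANI values
#'
#' @param ani An `ani_tbl` (from [ani_matrix()]) or an [ani_summary()]
#'   tibble.
#' @param threshold Species threshold drawn into the fill scale midpoint.
#' @return A ggplot.
#' @export
plot_ani_matrix <- function(ani, threshold = 95) {
  s <- if (inherits(ani, "ani_tbl")) ani_summary(ani) else ani
  ids <- sort(unique(c(s$genome_a, s$genome_b)))
  full <- dplyr::bind_rows(
    s,
    dplyr::rename(s, genome_a = "genome_b", genome_b = "genome_a"),
    tibble::tibble(genome_a = ids, genome_b = ids, ani = 100)
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$genome_a, y = .data$genome_b,
                                     fill = .data$ani)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$ani)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "white", mid = "lightyellow", high = "firebrick",
                                  midpoint = threshold, name = "ANI (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot ani_tbl
#' @export
autoplot.ani_tbl <- function(object, ...) plot_ani_matrix(object, ...)

#' GC skew profile plot
#'
#' @param skew A [gc_skew()] tibble.
#' @return A ggplot with per-window skew and the cumulative curve.
#' @export
plot_gc_skew <- function(skew) {
  long <- tidyr::pivot_longer(skew, c("skew", "cumulative"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~ .data$series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' RDase cluster synteny plot
#'
#' Draws each cluster as a row of member boxes (5'->3') and the cross-row
#' links as segments: solid for same-OG (>90% identity), dashed for
#' umbrella-tier (75-90%).
#'
#' @param clusters A [find_rdh_clusters()] table (two or more rows).
#' @param links Tibble of [link_clusters()] outputs with added columns
#'   `cluster_a`, `cluster_b` naming the cluster ids.
#' @param partition Optional `og_partition` used to colour members.
#' @return A ggplot.
#' @export
plot_synteny <- function(clusters, links, partition = NULL) {
  rows <- tibble::as_tibble(clusters) |>
    dplyr::mutate(row = dplyr::row_number())
  members <- rows |>
    dplyr::mutate(member = .data$members) |>
    tidyr::unnest_longer(.data$member, values_to = "feature_id") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup()
  if (!is.null(partition)) {
    members <- dplyr::left_join(members, dplyr::rename(tidy(partition),
                                                       feature_id = "id",
                                                       og = "label"),
                                by = "feature_id")
  } else {
    members$og <- NA_character_
  }
  row_of <- stats::setNames(rows$row, rows$cluster_id)
  idx_of <- stats::setNames(members$idx, members$feature_id)
  seg <- links |>
    dplyr::mutate(
      x = unname(idx_of[.data$from]), xend = unname(idx_of[.data$to]),
      y = unname(row_of[.data$cluster_a]), yend = unname(row_of[.data$cluster_b])
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y - 0.15, yend = .data$yend + 0.15,
                   linetype = .data$tier),
      colour = "grey40"
    ) +
    ggplot2::geom_tile(
      data = members,
      ggplot2::aes(x = .data$idx, y = row_of[.data$cluster_id], fill = .data$og),
      width = 0.9, height = 0.3, colour = "black"
    ) +
    ggplot2::scale_linetype_manual(values = c(solid = "solid", umbrella = "dashed")) +
    ggplot2::scale_y_continuous(breaks = rows$row, labels = rows$cluster_id) +
    ggplot2::labs(x = "cluster position (5'→3')", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
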