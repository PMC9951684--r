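#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_hline
#'   geom_tile labs scale_y_log10 facet_wrap theme_minimal
NULL

#' Plot an LD-decay curve
#'
#' Mean r^2 against bin midpoint distance.
#'
#' @param object An `ld_curve` from [decay_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_curve <- function(object, ...) {
  unit <- attr(object, "scheme")$unit %||% "kb"
  df <- object[object$n_pairs > 0, ]
  ggplot(df, aes(x = .data$bin_mid, y = .data$mean_r2)) +
    geom_line(colour = "steelblue") + geom_point(size = 1) +
    labs(x = sprintf("distance (%s)", unit), y = expression(mean ~ r^2),
         title = "LD decay") +
    theme_minimal()
}

#' Plot an effective-population-size trajectory
#'
#' Ne against generations in the past (both axes log-scaled).
#'
#' @param object An `ne_estimate` from [ne_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ne_estimate <- function(object, ...) {
  df <- object[!object$skipped, ]
  ggplot(df, aes(x = .data$generation, y = .data$ne)) +
    geom_line(colour = "firebrick") + geom_point(size = 1) +
    scale_y_log10() +
    labs(x = "generations in the past", y = "Ne",
         title = "Effective population size trajectory") +
    theme_minimal()
}

#' Plot per-breed ROH burden
#'
#' Per-breed total ROH length (SROH, Mb).
#'
#' @param object A `roh_summary` from [summarize_roh()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roh_summary <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$breed, -.data$SROH_mb),
                     y = .data$SROH_mb)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "SROH (Mb)", title = "Total ROH length per breed") +
    theme_minimal()
}

#' Plot leave-one-out diversity contributions
#'
#' Percentage loss (+) or gain (-) of total gene and allelic diversity on
#' removal of each breed.
#'
#' @param object A `contribution_tbl` from [leave_one_out()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contribution_tbl <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("breed", "dHT_pct", "dAT_pct")],
                            c("dHT_pct", "dAT_pct"),
                            names_to = "metric", values_to = "pct")
  ggplot(df, aes(x = .data$breed, y = .data$pct)) +
    geom_col(fill = "grey40") + geom_hline(yintercept = 0) +
    facet_wrap(~metric) +
    labs(x = NULL, y = "contribution (%)",
         title = "Leave-one-out contribution to diversity") +
    theme_minimal()
}

#' Plot a Nei-distance heatmap
#'
#' @param object A `nei_dist` from [nei_minimum_distance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nei_dist <- function(object, ...) {
  D <- unclass(object)
  df <- tidyr::expand_grid(breed_i = rownames(D), breed_j = colnames(D)) |>
    dplyr::mutate(nei_d = as.vector(t(D)))
  ggplot(df, aes(x = .data$breed_i, y = .data$breed_j, fill = .data$nei_d)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = "Nei D",
         title = "Nei minimum distance between breeds") +
    theme_minimal()
}

#' Plot per-SNP ROH incidence with island threshold
#'
#' Manhattan-style incidence along the genome; the island threshold is drawn
#' as a horizontal line.
#'
#' @param incidence A [snp_incidence()] result.
#' @param threshold Island threshold (default 0.30).
#' @return A ggplot.
#' @export
plot_incidence <- function(incidence, threshold = 0.30) {
  ggplot(incidence, aes(x = .data$pos_bp / 1e6, y = .data$incidence)) +
    geom_point(size = 0.3, alpha = 0.6) +
    geom_hline(yintercept = threshold, colour = "red", linetype = 2) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "fraction of individuals in ROH",
         title = "ROH incidence") +
    theme_minimal()
}
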