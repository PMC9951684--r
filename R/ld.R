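#' Pairwise genotype r-squared within a distance window
#'
#' Composite (Rogers-Huff style) LD: the squared Pearson correlation of the
#' two dosage vectors over pairwise-complete samples, for all marker pairs
#' on the same chromosome separated by at most `max_dist_bp`. Pairs where
#' either marker is monomorphic on the shared calls have undefined r^2 and
#' are excluded (their number is reported in the `n_undefined` attribute).
#'
#' @param ds A [gen_dataset()].
#' @param breed Optional breed label to restrict the samples to; `NULL`
#'   uses all samples. An unknown label is an error.
#' @param max_dist_bp Maximum pair distance in bp.
#' @return A tibble of class `ld_pairs`: `chrom`, `id1`, `id2`, `dist_bp`,
#'   `r2`.
#' @export
pairwise_r2 <- function(ds, breed = NULL, max_dist_bp = 2e6) {
  if (!is.null(breed)) {
    if (!breed %in% ds$samples$breed)
      abort(sprintf("breed '%s' is not in the dataset", breed))
    ds <- subset_gen(ds, breeds = breed)
  }
  out <- list(); n_undef <- 0L; n_considered <- 0L
  for (ch in unique(ds$markers$chrom)) {
    midx <- which(ds$markers$chrom == ch)
    if (length(midx) < 2) next
    pos <- ds$markers$pos_bp[midx]
    X <- ds$dosages[, midx, drop = FALSE]
    storage.mode(X) <- "double"
    cm <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- d <= max_dist_bp
    pr <- pr[keep, , drop = FALSE]; d <- d[keep]
    n_considered <- n_considered + nrow(pr)
    r2 <- cm[pr]^2
    undef <- is.na(r2)
    n_undef <- n_undef + sum(undef)
    out[[length(out) + 1]] <- tibble(
      chrom = ch, id1 = ds$markers$marker_id[midx][pr[!undef, 1]],
      id2 = ds$markers$marker_id[midx][pr[!undef, 2]],
      dist_bp = d[!undef], r2 = r2[!undef])
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(chrom = character(), id1 = character(), id2 = character(),
           dist_bp = numeric(), r2 = numeric())
  if (n_considered == 0)
    abort("no marker pair within max_dist_bp on any chromosome")
  attr(res, "n_undefined") <- n_undef
  class(res) <- c("ld_pairs", class(res))
  res
}

#' Binned LD-decay curve
#'
#' Bins pair distances with a two-resolution scheme: width `width_near`
#' below `breakpoint` and `width_far` above it (all in `unit`). Bins are
#' contiguous and non-overlapping; empty bins are reported with count 0 and
#' `NA` mean.
#'
#' @param pairs A [pairwise_r2()] result (non-empty).
#' @param width_near,width_far Bin widths below/above the breakpoint.
#' @param breakpoint Distance at which the bin width switches.
#' @param unit `"kb"` (default) or `"bp"`; the unit of the three scheme
#'   parameters and of the output bin columns.
#' @return A tibble of class `ld_curve`: `bin_start`, `bin_end`, `bin_mid`
#'   (in `unit`), `mean_r2`, `n_pairs`, with the scheme in attributes.
#' @export
decay_curve <- function(pairs, width_near = 500, width_far = 1100,
                        breakpoint = 2000, unit = c("kb", "bp")) {
  unit <- match.arg(unit)
  if (nrow(pairs) == 0) abort("no pairs to bin")
  mult <- if (unit == "kb") 1000 else 1
  d <- pairs$dist_bp / mult
  near_edges <- seq(0, breakpoint, by = width_near)
  if (near_edges[length(near_edges)] < breakpoint)
    near_edges <- c(near_edges, breakpoint)
  top <- max(d, breakpoint)
  far_edges <- if (top > breakpoint)
    seq(breakpoint, breakpoint + width_far * ceiling((top - breakpoint) / width_far),
        by = width_far) else numeric(0)
  edges <- unique(c(near_edges, far_edges))
  bin <- cut(d, breaks = edges, include.lowest = TRUE, right = FALSE)
  ## right = FALSE: [a, b) bins; include the exact top edge in the last bin
  bin[d == edges[length(edges)]] <- levels(bin)[length(levels(bin))]
  agg <- tibble(bin = bin, r2 = pairs$r2) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop")
  out <- tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
                bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                mean_r2 = ifelse(agg$n_pairs > 0, agg$mean_r2, NA_real_),
                n_pairs = agg$n_pairs)
  attr(out, "scheme") <- list(width_near = width_near, width_far = width_far,
                              breakpoint = breakpoint, unit = unit)
  class(out) <- c("ld_curve", class(out))
  out
}

#' Effective population size trajectory from LD decay
#'
#' Inverts Sved's relation `E[r^2] = 1 / (1 + 4 Ne c)` per distance bin.
#' The bin midpoint distance is converted to a recombination fraction
#' `c = distance_Mb * cm_per_mb / 100` Morgans, the mean r^2 is corrected
#' for sample size as `r2_adj = mean_r2 - 1/n_samples`, and each bin yields
#' `Ne = (1 / r2_adj - 1) / (4c)` attributed to generation `t = 1 / (2c)`
#' in the past. Bins with `r2_adj <= epsilon` (or no pairs) are skipped
#' with a reason.
#'
#' @param curve An [decay_curve()] result with at least one occupied bin.
#' @param n_samples Number of individuals behind the r^2 estimates (>= 2);
#'   `Inf` disables the correction.
#' @param cm_per_mb Genetic-map scaling (default 3 cM/Mb).
#' @param epsilon Lower guard on `r2_adj`.
#' @return A tibble of class `ne_estimate`: `bin_mid`, `c_morgan`,
#'   `generation`, `r2_adj`, `ne`, `skipped`, `reason`, ordered by
#'   increasing `c` (decreasing generation).
#' @export
ne_trajectory <- function(curve, n_samples, cm_per_mb = 3, epsilon = 1e-6) {
  if (!any(curve$n_pairs > 0)) abort("LD curve has no occupied bin")
  if (n_samples < 2) abort("n_samples must be >= 2")
  unit <- attr(curve, "scheme")$unit %||% "kb"
  to_mb <- if (unit == "kb") 1e-3 else 1e-6
  c_morgan <- curve$bin_mid * to_mb * cm_per_mb / 100
  r2_adj <- curve$mean_r2 - 1 / n_samples
  skipped <- curve$n_pairs == 0 | is.na(r2_adj) | r2_adj <= epsilon
  reason <- dplyr::case_when(
    curve$n_pairs == 0 ~ "empty bin",
    is.na(r2_adj) ~ "undefined r2",
    r2_adj <= epsilon ~ "r2_adj at or below epsilon",
    TRUE ~ NA_character_)
  ne <- ifelse(skipped, NA_real_, (1 / r2_adj - 1) / (4 * c_morgan))
  out <- tibble(bin_mid = curve$bin_mid, c_morgan = c_morgan,
                generation = 1 / (2 * c_morgan), r2_adj = r2_adj,
                ne = ne, skipped = skipped, reason = reason) |>
    dplyr::arrange(.data$c_morgan)
  class(out) <- c("ne_estimate", class(out))
  out
}
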