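#' ROH detection parameters
#'
#' Defaults follow the standard high-density-array configuration for
#' livestock: minimum run length 1 Mb, at least 100 consecutive SNPs, at
#' most 1 heterozygous and 2 missing calls per run, SNP density at least
#' 0.01 SNP/kb (1 SNP per 100 kb), and a maximum gap of 1 Mb between
#' consecutive homozygous SNPs.
#'
#' @param min_length_bp Minimum run length in bp.
#' @param min_snps Minimum number of SNPs in a run.
#' @param max_het Maximum heterozygous calls allowed inside a run.
#' @param max_missing Maximum missing calls allowed inside a run.
#' @param min_density_snp_per_kb Minimum SNP density (SNPs per kb).
#' @param max_gap_bp Maximum gap between consecutive SNPs inside a run.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 100L, max_het = 1L,
                       max_missing = 2L, min_density_snp_per_kb = 0.01,
                       max_gap_bp = 1e6) {
  stopifnot(min_length_bp > 0, min_snps > 0, max_het >= 0, max_missing >= 0,
            min_density_snp_per_kb > 0, max_gap_bp > 0)
  structure(list(min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 min_density_snp_per_kb = min_density_snp_per_kb,
                 max_gap_bp = max_gap_bp), class = "roh_params")
}

## Candidate intervals (maximal under the het/missing allowances) for one
## piece of a chromosome, via two pointers. het/mis: logical vectors.
## Returns a matrix with columns start_idx, end_idx.
maximal_intervals <- function(het, mis, max_het, max_missing) {
  n <- length(het)
  l <- 1L
  nh <- 0L; nm <- 0L
  left <- integer(n)
  for (r in seq_len(n)) {
    nh <- nh + het[r]; nm <- nm + mis[r]
    while (nh > max_het || nm > max_missing) {
      nh <- nh - het[l]; nm <- nm - mis[l]
      l <- l + 1L
    }
    left[r] <- l
  }
  keep <- c(left[-1] > left[-n], TRUE)  # window maximal iff left strictly grows
  keep <- keep & left <= seq_len(n)     # drop empty windows (left passed r)
  cbind(start_idx = unname(left[keep]), end_idx = which(keep))
}

## Greedy selection of non-overlapping intervals: longest (bp) first, ties
## towards the leftmost start, then fewest SNPs (stable).
greedy_select <- function(cand, pos) {
  if (nrow(cand) == 0) return(cand)
  len <- pos[cand[, 2]] - pos[cand[, 1]] + 1
  ord <- order(-len, pos[cand[, 1]], cand[, 1])
  chosen <- logical(nrow(cand))
  taken_s <- numeric(0); taken_e <- numeric(0)
  for (k in ord) {
    s <- pos[cand[k, 1]]; e <- pos[cand[k, 2]]
    if (!any(s <= taken_e & e >= taken_s)) {
      chosen[k] <- TRUE
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
    }
  }
  cand[chosen, , drop = FALSE]
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: (a) the marker sequence is split wherever
#' the gap between consecutive SNPs exceeds `max_gap_bp`; (b) within each
#' piece, all maximal intervals containing at most `max_het` heterozygous
#' and `max_missing` missing calls are enumerated with a two-pointer scan;
#' (c) non-overlapping intervals are selected greedily, longest first with
#' ties to the leftmost; (d) survivors are filtered by `min_snps`,
#' `min_length_bp` and `min_density_snp_per_kb`
#' (`n_snps / (length_bp / 1000)`). Coordinates are 1-based inclusive at SNP
#' positions; `length_bp = end_bp - start_bp + 1`. Deterministic.
#'
#' @param ds A [gen_dataset()] (map must be sorted; enforced by the
#'   container).
#' @param params A [roh_params()].
#' @return A tibble of class `roh_segments`: `sample_id`, `breed`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp`.
#' @export
detect_roh <- function(ds, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  chr_split <- split(seq_len(nrow(ds$markers)),
                     factor(ds$markers$chrom, levels = unique(ds$markers$chrom)))
  out <- list()
  for (ci in seq_along(chr_split)) {
    idx <- chr_split[[ci]]
    pos <- ds$markers$pos_bp[idx]
    gaps <- diff(pos)
    piece_id <- cumsum(c(1L, as.integer(gaps > params$max_gap_bp)))
    pieces <- split(seq_along(idx), piece_id)
    chrom <- names(chr_split)[ci]
    for (i in seq_len(nrow(ds$dosages))) {
      x <- ds$dosages[i, idx]
      for (pc in pieces) {
        if (length(pc) < params$min_snps) next
        het <- !is.na(x[pc]) & x[pc] == 1L
        mis <- is.na(x[pc])
        cand <- maximal_intervals(het, mis, params$max_het, params$max_missing)
        sel <- greedy_select(cand, pos[pc])
        if (nrow(sel) == 0) next
        s <- unname(pos[pc][sel[, 1]]); e <- unname(pos[pc][sel[, 2]])
        n_snps <- unname(sel[, 2] - sel[, 1] + 1L)
        len <- e - s + 1
        ok <- n_snps >= params$min_snps & len >= params$min_length_bp &
          n_snps / (len / 1000) >= params$min_density_snp_per_kb
        if (!any(ok)) next
        ch <- cumsum(het); cm <- cumsum(mis)
        at <- function(v, k) ifelse(k >= 1, v[pmax(k, 1)], 0)
        out[[length(out) + 1]] <- tibble(
          sample_id = ds$samples$sample_id[i], breed = ds$samples$breed[i],
          chrom = chrom, start_bp = s[ok], end_bp = e[ok],
          n_snps = n_snps[ok],
          n_het = as.integer(ch[sel[ok, 2]] - at(ch, sel[ok, 1] - 1L)),
          n_missing = as.integer(cm[sel[ok, 2]] - at(cm, sel[ok, 1] - 1L)),
          length_bp = len[ok])
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(sample_id = character(), breed = character(), chrom = character(),
           start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
           n_het = integer(), n_missing = integer(), length_bp = numeric())
  res <- dplyr::arrange(res, .data$sample_id,
                        match(.data$chrom, unique(ds$markers$chrom)),
                        .data$start_bp)
  class(res) <- c("roh_segments", class(res))
  res
}

#' Summarize ROH per breed
#'
#' Per breed: `SROH` the total length of all individual ROH (Mb), `NROH`
#' the number of ROH over all individuals, `MNROH` the mean individual ROH
#' length (Mb) with its standard deviation (sample SD, `n - 1`). Grand
#' totals, the longest single segment, and the across-breed averages are
#' attached via [aggregate_breed_summary()].
#'
#' @param segments A [detect_roh()] result.
#' @param samples Sample table (provides breeds with zero segments).
#' @return A tibble of class `roh_summary` with one row per breed and an
#'   attribute `totals` (see [aggregate_breed_summary()]).
#' @export
summarize_roh <- function(segments, samples) {
  breeds <- unique(samples$breed)
  per <- lapply(breeds, function(b) {
    seg <- segments[segments$breed == b, , drop = FALSE]
    lens <- seg$length_bp / 1e6
    tibble(breed = b,
           n_samples = sum(samples$breed == b),
           SROH_mb = sum(lens), NROH = nrow(seg),
           MNROH_mb = if (nrow(seg)) mean(lens) else NA_real_,
           MNROH_sd = if (nrow(seg) > 1) sd(lens) else NA_real_)
  })
  out <- dplyr::bind_rows(per)
  attr(out, "totals") <- aggregate_breed_summary(out)
  attr(out, "longest_mb") <- if (nrow(segments)) max(segments$length_bp) / 1e6 else 0
  class(out) <- c("roh_summary", class(out))
  out
}

#' Aggregate a per-breed ROH summary table
#'
#' Takes a table with per-breed `SROH_mb`, `NROH` (and optionally
#' `MNROH_mb`) columns — either produced by [summarize_roh()] or supplied
#' externally, e.g. a published per-breed summary — and computes the
#' population-level aggregates: total and per-breed-mean SROH, total, mean,
#' maximum and minimum NROH, and the mean ROH length under both
#' conventions (the mean of the per-breed `MNROH` values, and the pooled
#' total length divided by the total count).
#'
#' @param tbl Per-breed summary tibble.
#' @return One-row tibble with columns `nroh_total`, `nroh_mean`,
#'   `nroh_max`, `nroh_min`, `sroh_total_mb`, `sroh_mean_mb`,
#'   `mnroh_breed_mean_mb` (NA when `MNROH_mb` is absent) and
#'   `mnroh_pooled_mb`.
#' @export
aggregate_breed_summary <- function(tbl) {
  stopifnot(all(c("SROH_mb", "NROH") %in% names(tbl)))
  tibble(
    nroh_total = sum(tbl$NROH),
    nroh_mean = mean(tbl$NROH),
    nroh_max = max(tbl$NROH),
    nroh_min = min(tbl$NROH),
    sroh_total_mb = sum(tbl$SROH_mb),
    sroh_mean_mb = mean(tbl$SROH_mb),
    mnroh_breed_mean_mb = if ("MNROH_mb" %in% names(tbl))
      mean(tbl$MNROH_mb, na.rm = TRUE) else NA_real_,
    mnroh_pooled_mb = sum(tbl$SROH_mb) / sum(tbl$NROH))
}

#' Per-SNP ROH incidence
#'
#' Fraction of all individuals in the dataset whose ROH cover each SNP
#' position (coverage by bp-interval inclusion).
#'
#' @param segments A [detect_roh()] result.
#' @param ds The [gen_dataset()] the segments came from.
#' @return Tibble with `chrom`, `pos_bp`, `marker_id`, `n_covered`,
#'   `incidence`.
#' @export
snp_incidence <- function(segments, ds) {
  n_ind <- nrow(ds$samples)
  counts <- integer(nrow(ds$markers))
  for (ch in unique(ds$markers$chrom)) {
    midx <- which(ds$markers$chrom == ch)
    pos <- ds$markers$pos_bp[midx]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    ## difference trick: +1 at first covered SNP, -1 after last covered SNP
    first <- findInterval(seg$start_bp - 1, pos) + 1L
    last <- findInterval(seg$end_bp, pos)
    okseg <- first <= last
    d <- integer(length(pos) + 1L)
    for (k in which(okseg)) {
      d[first[k]] <- d[first[k]] + 1L
      d[last[k] + 1L] <- d[last[k] + 1L] - 1L
    }
    counts[midx] <- cumsum(d[-length(d)])
  }
  tibble(chrom = ds$markers$chrom, pos_bp = ds$markers$pos_bp,
         marker_id = ds$markers$marker_id, n_covered = counts,
         incidence = counts / n_ind)
}

#' Call population ROH islands
#'
#' Maximal runs of consecutive SNPs (within one chromosome, no gap merging)
#' whose ROH incidence is strictly greater than `threshold`; runs with fewer
#' than `min_island_snps` SNPs are discarded (their count is reported in the
#' `n_discarded_runs` attribute).
#'
#' @param incidence A [snp_incidence()] result.
#' @param threshold Incidence threshold (strict `>`; default 0.30).
#' @param min_island_snps Minimum SNPs per island (default 50).
#' @return A tibble of class `roh_islands`: `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `mean_incidence`, `max_incidence`.
#' @export
call_islands <- function(incidence, threshold = 0.30, min_island_snps = 50L) {
  out <- list(); discarded <- 0L
  for (ch in unique(incidence$chrom)) {
    sub <- incidence[incidence$chrom == ch, , drop = FALSE]
    above <- sub$incidence > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      n <- r$lengths[k]
      if (n < min_island_snps) { discarded <- discarded + 1L; next }
      sl <- starts[k]:ends[k]
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start_bp = sub$pos_bp[starts[k]], end_bp = sub$pos_bp[ends[k]],
        n_snps = n, mean_incidence = mean(sub$incidence[sl]),
        max_incidence = max(sub$incidence[sl]))
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(chrom = character(), start_bp = numeric(), end_bp = numeric(),
           n_snps = integer(), mean_incidence = numeric(),
           max_incidence = numeric())
  attr(res, "n_discarded_runs") <- discarded
  attr(res, "threshold") <- threshold
  class(res) <- c("roh_islands", class(res))
  res
}
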