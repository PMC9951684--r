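#' Quality-control filter for a genotype dataset
#'
#' Applies the standard SNP-array filters in a fixed, documented order:
#' (1) duplicated markers (same id or same chromosome + position; first
#' occurrence kept), (2) non-autosomal markers (chromosome codes not
#' coercible to an integer in `1..max_autosome`), (3) individuals below the
#' call-rate threshold, (4) markers below the call-rate threshold. Call rates
#' are computed on the axis surviving the previous stages and thresholds are
#' inclusive (`>=`).
#'
#' @param ds A [gen_dataset()].
#' @param min_ind_call Minimum individual call rate (default 0.95).
#' @param min_snp_call Minimum marker call rate (default 0.99).
#' @param autosomes_only Drop non-autosomal markers (default `TRUE`).
#' @param drop_duplicates Drop duplicated markers (default `TRUE`).
#' @param max_autosome Largest autosome code (default 28, chicken).
#' @return A list with elements `dataset` (the filtered [gen_dataset()]) and
#'   `report` (a tibble with one row per stage: axis, removed, retained).
#' @export
qc_filter <- function(ds, min_ind_call = 0.95, min_snp_call = 0.99,
                      autosomes_only = TRUE, drop_duplicates = TRUE,
                      max_autosome = 28L) {
  stopifnot(min_ind_call >= 0, min_ind_call <= 1,
            min_snp_call >= 0, min_snp_call <= 1)
  report <- list()
  note <- function(stage, axis, removed, retained)
    tibble(stage = stage, axis = axis, removed = removed, retained = retained)

  keep_m <- rep(TRUE, nrow(ds$markers))
  dup <- duplicated(ds$markers$marker_id) |
    duplicated(paste(ds$markers$chrom, ds$markers$pos_bp))
  if (drop_duplicates) keep_m <- keep_m & !dup
  report$dup <- note("duplicate_markers", "marker",
                     sum(drop_duplicates & dup), sum(keep_m))

  chr_num <- suppressWarnings(as.integer(ds$markers$chrom))
  non_auto <- is.na(chr_num) | chr_num < 1 | chr_num > max_autosome
  if (autosomes_only) keep_m <- keep_m & !non_auto
  report$auto <- note("non_autosomal_markers", "marker",
                      sum(autosomes_only & non_auto & !(drop_duplicates & dup)),
                      sum(keep_m))

  X <- ds$dosages[, keep_m, drop = FALSE]
  ind_cr <- rowMeans(!is.na(X))
  keep_s <- ind_cr >= min_ind_call
  report$ind <- note("individual_call_rate", "sample", sum(!keep_s), sum(keep_s))
  if (!any(keep_s)) abort("QC removed every sample (individual call rate)")

  snp_cr <- colMeans(!is.na(X[keep_s, , drop = FALSE]))
  keep_m2 <- snp_cr >= min_snp_call
  report$snp <- note("marker_call_rate", "marker", sum(!keep_m2), sum(keep_m2))
  if (!any(keep_m2)) abort("QC removed every marker (marker call rate)")

  keep_m[keep_m] <- keep_m2
  out <- gen_dataset(ds$dosages[keep_s, keep_m, drop = FALSE],
                     ds$markers[keep_m, , drop = FALSE],
                     ds$samples[keep_s, , drop = FALSE])
  list(dataset = out, report = dplyr::bind_rows(report))
}

## Pairwise r^2 between two dosage vectors over pairwise-complete samples;
## 0 when either vector is constant on the shared calls (monomorphic pairs
## are never pruned for LD).
safe_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Sliding-window pruning in the style of PLINK's `--indep-pairwise`: within
#' each window of `window_snps` consecutive markers on one chromosome, while
#' any retained pair has genotype-correlation `r^2` greater than the
#' threshold, the member of the currently worst pair with the lower minor
#' allele frequency is removed (ties broken towards the later map position);
#' the window then advances by `step_snps`. Deterministic.
#'
#' @param ds A [gen_dataset()].
#' @param window_snps Window size in markers (>= 2).
#' @param step_snps Step size in markers (>= 1).
#' @param r2_threshold Pruning threshold on `r^2`.
#' @return Character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(ds, window_snps = 50L, step_snps = 5L, r2_threshold = 0.2) {
  stopifnot(window_snps >= 2, step_snps >= 1,
            r2_threshold >= 0, r2_threshold <= 1)
  X <- ds$dosages
  maf <- pmin(colMeans(X, na.rm = TRUE) / 2, 1 - colMeans(X, na.rm = TRUE) / 2)
  maf[is.nan(maf)] <- 0
  keep <- rep(TRUE, ncol(X))
  for (idx in split(seq_len(ncol(X)),
                    factor(ds$markers$chrom, levels = unique(ds$markers$chrom)))) {
    n <- length(idx)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window_snps - 1L, n)]
      active <- win[keep[win]]
      if (length(active) >= 2) {
        r2 <- outer(seq_along(active), seq_along(active), Vectorize(function(i, j)
          if (i < j) safe_r2(X[, active[i]], X[, active[j]]) else 0))
        repeat {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[worst[1], worst[2]] <= r2_threshold) break
          pair <- active[c(worst[1], worst[2])]
          victim_local <- if (maf[pair[1]] < maf[pair[2]]) worst[1]
            else if (maf[pair[2]] < maf[pair[1]]) worst[2]
            else worst[2]  # equal MAF: later map position loses
          keep[active[victim_local]] <- FALSE
          r2[victim_local, ] <- 0; r2[, victim_local] <- 0
        }
      }
      if (start + window_snps - 1L >= n) break
      start <- start + step_snps
    }
  }
  ds$markers$marker_id[keep]
}
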