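#' Genotype dataset container
#'
#' Bundles a samples-by-markers dosage matrix with its physical marker map
#' and per-sample breed labels. Dosages count copies of the alternate allele
#' (0, 1, 2) with `NA` for missing calls.
#'
#' @param dosages Integer matrix, samples in rows, markers in columns. Values
#'   must be 0, 1, 2 or `NA`.
#' @param markers Data frame with columns `chrom`, `marker_id`, `pos_bp`
#'   (1-based physical coordinate), sorted by chromosome then position,
#'   strictly increasing within chromosome, ids unique.
#' @param samples Data frame with columns `sample_id` (unique) and `breed`.
#'
#' @return An object of class `gen_dataset`: a list with elements `dosages`,
#'   `markers` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' ds <- gen_dataset(
#'   dosages = rbind(a1 = c(0L, 1L), a2 = c(2L, NA)),
#'   markers = data.frame(chrom = "1", marker_id = c("m1", "m2"),
#'                        pos_bp = c(100L, 200L)),
#'   samples = data.frame(sample_id = c("a1", "a2"), breed = "B1")
#' )
#' glance(ds)
gen_dataset <- function(dosages, markers, samples) {
  markers <- as_tibble(markers)
  samples <- as_tibble(samples)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- markers$marker_id
  ds <- structure(list(dosages = dosages, markers = markers, samples = samples),
                  class = "gen_dataset")
  validate_gen_dataset(ds)
  ds
}

validate_gen_dataset <- function(ds) {
  m <- ds$markers; s <- ds$samples; x <- ds$dosages
  stopifnot(is.matrix(x))
  if (nrow(x) != nrow(s)) abort("dosage rows must match the sample table")
  if (ncol(x) != nrow(m)) abort("dosage columns must match the marker map")
  if (!all(c("chrom", "marker_id", "pos_bp") %in% names(m)))
    abort("marker map needs columns chrom, marker_id, pos_bp")
  if (!all(c("sample_id", "breed") %in% names(s)))
    abort("sample table needs columns sample_id, breed")
  if (anyDuplicated(m$marker_id)) abort("marker ids must be unique")
  if (anyDuplicated(s$sample_id)) abort("sample ids must be unique")
  if (any(is.na(s$breed))) abort("every sample needs a breed label")
  if (any(m$pos_bp < 1)) abort("positions must be >= 1")
  bad <- !(is.na(x) | x %in% 0:2)
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  ## sorted positions within chromosome; ties are admitted so that raw data
  ## with duplicated markers can be loaded and cleaned by qc_filter()
  cf <- factor(m$chrom, levels = unique(m$chrom))
  if (any(unlist(tapply(m$pos_bp, cf, function(p) diff(p) < 0))))
    abort("marker map must be sorted by position within each chromosome")
  invisible(ds)
}

#' @export
print.gen_dataset <- function(x, ...) {
  cat(sprintf(
    "<gen_dataset> %d samples x %d markers | %d chromosome(s), %d breed(s), %.2f%% missing\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$markers$chrom)),
    length(unique(x$samples$breed)), 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @describeIn gen_dataset One-row summary: sample/marker/chromosome/breed
#'   counts and overall missing-call rate.
#' @param x A `gen_dataset`.
#' @param ... Unused.
#' @export
glance.gen_dataset <- function(x, ...) {
  tibble(n_samples = nrow(x$dosages), n_markers = ncol(x$dosages),
         n_chrom = length(unique(x$markers$chrom)),
         n_breeds = length(unique(x$samples$breed)),
         missing_rate = mean(is.na(x$dosages)))
}

#' @describeIn gen_dataset Per-marker tibble with call rate and alternate
#'   allele frequency.
#' @export
tidy.gen_dataset <- function(x, ...) {
  d <- x$dosages
  x$markers |>
    dplyr::mutate(call_rate = colMeans(!is.na(d)),
                  alt_freq = colMeans(d, na.rm = TRUE) / 2)
}

#' Subset a genotype dataset
#'
#' @param ds A [gen_dataset()].
#' @param samples Optional character vector of sample ids (or logical/integer
#'   index into the sample table) to keep.
#' @param markers Optional character vector of marker ids (or index) to keep;
#'   map order is preserved.
#' @param breeds Optional character vector of breed labels to keep.
#' @return A `gen_dataset` restricted to the requested rows/columns.
#' @export
subset_gen <- function(ds, samples = NULL, markers = NULL, breeds = NULL) {
  keep_s <- rep(TRUE, nrow(ds$samples))
  if (!is.null(breeds)) keep_s <- keep_s & ds$samples$breed %in% breeds
  if (!is.null(samples)) {
    if (is.character(samples)) keep_s <- keep_s & ds$samples$sample_id %in% samples
    else { tmp <- rep(FALSE, nrow(ds$samples)); tmp[samples] <- TRUE; keep_s <- keep_s & tmp }
  }
  keep_m <- rep(TRUE, nrow(ds$markers))
  if (!is.null(markers)) {
    if (is.character(markers)) keep_m <- ds$markers$marker_id %in% markers
    else { tmp <- rep(FALSE, nrow(ds$markers)); tmp[markers] <- TRUE; keep_m <- tmp }
  }
  if (!any(keep_s)) abort("subset removes every sample")
  if (!any(keep_m)) abort("subset removes every marker")
  gen_dataset(ds$dosages[keep_s, keep_m, drop = FALSE],
              ds$markers[keep_m, , drop = FALSE],
              ds$samples[keep_s, , drop = FALSE])
}

#' Per-breed allele frequencies and called-allele counts
#'
#' @param ds A [gen_dataset()].
#' @return List with `p` (breeds x markers matrix of alternate-allele
#'   frequencies, `NaN` where a breed has no calls) and `n` (matrix of called
#'   allele counts, twice the called genotypes).
#' @export
breed_freqs <- function(ds) {
  breeds <- unique(ds$samples$breed)
  L <- ncol(ds$dosages)
  p <- matrix(NA_real_, length(breeds), L, dimnames = list(breeds, colnames(ds$dosages)))
  n <- matrix(0, length(breeds), L, dimnames = dimnames(p))
  for (b in breeds) {
    xb <- ds$dosages[ds$samples$breed == b, , drop = FALSE]
    called <- colSums(!is.na(xb))
    n[b, ] <- 2 * called
    tot <- colSums(xb, na.rm = TRUE)
    p[b, ] <- ifelse(called > 0, tot / (2 * called), NaN)
  }
  list(p = p, n = n, breeds = breeds)
}
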