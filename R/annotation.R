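#' Overlap ROH islands with a gene/QTL annotation table
#'
#' Islands arrive with 1-based inclusive SNP-position coordinates; the
#' annotation table is 0-based half-open. Both are converted to 1-based
#' closed intervals internally (annotation `[start, end)` becomes
#' `[start + 1, end]`) and intersected with
#' [GenomicRanges::findOverlaps()]. A record overlaps an island iff the
#' intersection length is at least `min_overlap_bp`; each record is counted
#' once per island. Records on chromosomes outside `chrom_levels` are
#' listed, excluded and warned about.
#'
#' @param islands A [call_islands()] result (or any tibble with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param annotation Annotation tibble (`chrom`, `start`, `end`, `name`,
#'   `kind`, optionally `trait_class`), 0-based half-open.
#' @param min_overlap_bp Minimum intersection length in bp (default 1).
#' @param chrom_levels Chromosome vocabulary of the genotype map; defaults
#'   to the chromosomes present in `islands`' map... i.e. the union of
#'   island chromosomes. Pass the map's chromosome set explicitly to get
#'   unknown-chromosome warnings for records off the map.
#' @return An object of class `overlap_report`: a per-island tibble with
#'   `n_genes`, `n_qtl` and a list-column `record_ids`; the full pair table
#'   is in the `pairs` attribute and excluded chromosomes in
#'   `unknown_chroms`.
#' @export
overlap_islands <- function(islands, annotation, min_overlap_bp = 1,
                            chrom_levels = NULL) {
  stopifnot(min_overlap_bp >= 1)
  chrom_levels <- chrom_levels %||% unique(c(islands$chrom, annotation$chrom))
  unknown <- setdiff(unique(annotation$chrom), chrom_levels)
  if (length(unknown)) {
    warn(paste("annotation chromosomes not in the genotype map, excluded:",
               paste(unknown, collapse = ", ")))
    annotation <- annotation[annotation$chrom %in% chrom_levels, , drop = FALSE]
  }
  if (!"trait_class" %in% names(annotation)) annotation$trait_class <- NA_character_
  n_isl <- nrow(islands)
  pairs <- tibble(island = integer(), record = character(), kind = character(),
                  trait_class = character(), overlap_bp = numeric())
  if (n_isl > 0 && nrow(annotation) > 0) {
    gr_isl <- GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(islands$start_bp, islands$end_bp))
    gr_ann <- GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(annotation$start + 1, annotation$end))
    hits <- GenomicRanges::findOverlaps(gr_isl, gr_ann,
                                        minoverlap = min_overlap_bp)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(islands$end_bp[qi], annotation$end[si]) -
      pmax(islands$start_bp[qi], annotation$start[si] + 1) + 1
    pairs <- tibble(island = qi, record = annotation$name[si],
                    kind = annotation$kind[si],
                    trait_class = annotation$trait_class[si], overlap_bp = ov)
  }
  per <- lapply(seq_len(n_isl), function(k) {
    pk <- pairs[pairs$island == k, , drop = FALSE]
    tibble(island = k, chrom = islands$chrom[k],
           start_bp = islands$start_bp[k], end_bp = islands$end_bp[k],
           n_genes = sum(pk$kind == "gene"), n_qtl = sum(pk$kind == "qtl"),
           record_ids = list(pk$record))
  })
  out <- if (n_isl) dplyr::bind_rows(per) else
    tibble(island = integer(), chrom = character(), start_bp = numeric(),
           end_bp = numeric(), n_genes = integer(), n_qtl = integer(),
           record_ids = list())
  attr(out, "pairs") <- pairs
  attr(out, "unknown_chroms") <- unknown
  class(out) <- c("overlap_report", class(out))
  out
}

#' Classify the traits of overlapping QTLs
#'
#' Maps the trait labels of the QTL records in an overlap report onto coarse
#' classes (e.g. meat, egg, fat, immunity, other) and tabulates class
#' percentages over all classified QTLs. Each distinct QTL record is counted
#' once, even when it overlaps several islands. Unmapped labels are routed
#' to `"other"` with a warning; percentages are rounded to 2 decimals.
#'
#' @param report An [overlap_islands()] result.
#' @param class_map Data frame with columns `trait` and `class` (e.g. read
#'   from a two-column TSV), or `NULL` to use each record's `trait_class`
#'   as-is.
#' @return Tibble with columns `class`, `n`, `percentage` (empty when no
#'   QTL overlaps).
#' @export
classify_traits <- function(report, class_map = NULL) {
  pairs <- attr(report, "pairs")
  q <- pairs[pairs$kind == "qtl", , drop = FALSE]
  q <- q[!duplicated(q$record), , drop = FALSE]
  if (nrow(q) == 0)
    return(tibble(class = character(), n = integer(), percentage = numeric()))
  lab <- q$trait_class
  if (!is.null(class_map)) {
    stopifnot(all(c("trait", "class") %in% names(class_map)))
    cls <- class_map$class[match(lab, class_map$trait)]
    if (anyNA(cls)) {
      warn(paste("unmapped trait labels routed to 'other':",
                 paste(unique(lab[is.na(cls)]), collapse = ", ")))
      cls[is.na(cls)] <- "other"
    }
    lab <- cls
  }
  lab[is.na(lab)] <- "other"
  dplyr::count(tibble(class = lab), .data$class, name = "n") |>
    dplyr::mutate(percentage = round(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
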