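#' Simulation configuration for multi-breed SNP genotypes
#'
#' Describes a Balding-Nichols multi-breed panel with per-individual
#' autozygous-tract mosaics. The defaults emulate a high-density chicken
#' SNP-array panel: eight breeds of about twenty birds each, 28 autosomes,
#' breed divergence giving pairwise Nei minimum distances of roughly
#' 0.03-0.10, and per-breed autozygosity levels differing more than
#' ten-fold so that megabase-scale runs of homozygosity appear at very
#' different rates per breed.
#'
#' @param n_breeds Number of breeds.
#' @param breed_sizes Integer vector of individuals per breed (each >= 2).
#' @param fst_per_breed Balding-Nichols divergence parameter per breed, each
#'   in `[0, 1)`. `0` means the breed's frequencies equal the ancestral ones.
#' @param froh_per_breed Target autozygous genome fraction per breed, each in
#'   `[0, 1)`.
#' @param chrom_lengths_bp Autosome lengths in bp (each >= 2 Mb).
#' @param n_snps Total marker count across chromosomes (>= number of
#'   chromosomes).
#' @param cm_per_mb Genetic-map scaling in cM per Mb; default 3, the standard
#'   chicken genome-wide average.
#' @param g_generations Generations back to the common ancestor of an
#'   autozygous tract; mean tract length is `100 / (2 * g_generations)` cM.
#' @param missing_rate Per-call missing probability.
#' @param maf_range Interval from which ancestral allele frequencies are
#'   drawn uniformly.
#' @param breed_labels Breed names; defaults to `B1..Bn`.
#' @param seed RNG seed; identical config + seed gives byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 8,
                       breed_sizes = c(18L, 19L, rep(20L, 6)),
                       fst_per_breed = c(0.13, 0.30, 0.26, 0.24, 0.20, 0.09, 0.16, 0.11),
                       froh_per_breed = c(0.11, 0.15, 0.12, 0.14, 0.03, 0.01, 0.14, 0.09),
                       chrom_lengths_bp = chicken_autosome_lengths(),
                       n_snps = 450000L,
                       cm_per_mb = 3,
                       g_generations = 8,
                       missing_rate = 0.002,
                       maf_range = c(0.05, 0.95),
                       breed_labels = paste0("B", seq_len(n_breeds)),
                       seed = 1L) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              breed_sizes = as.integer(breed_sizes),
              fst_per_breed = fst_per_breed,
              froh_per_breed = froh_per_breed,
              chrom_lengths_bp = as.numeric(chrom_lengths_bp),
              n_snps = as.integer(n_snps),
              cm_per_mb = cm_per_mb,
              g_generations = g_generations,
              missing_rate = missing_rate,
              maf_range = maf_range,
              breed_labels = breed_labels,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_breeds < 1) abort("need at least one breed")
    if (length(breed_sizes) != n_breeds || any(breed_sizes < 2))
      abort("breed_sizes must have one entry >= 2 per breed")
    if (length(fst_per_breed) != n_breeds || any(fst_per_breed < 0) ||
        any(fst_per_breed >= 1))
      abort("fst_per_breed must lie in [0, 1) (F >= 1 is rejected)")
    if (length(froh_per_breed) != n_breeds || any(froh_per_breed < 0) ||
        any(froh_per_breed >= 1))
      abort("froh_per_breed must lie in [0, 1)")
    if (any(chrom_lengths_bp < 2e6)) abort("chromosome lengths must be >= 2 Mb")
    if (n_snps < length(chrom_lengths_bp))
      abort("n_snps must be at least the number of chromosomes")
    if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must be in [0, 1]")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
        maf_range[1] > maf_range[2])
      abort("maf_range must be an interval inside (0, 1)")
    if (length(breed_labels) != n_breeds || anyDuplicated(breed_labels))
      abort("breed_labels must be unique, one per breed")
  })
  invisible(cfg)
}

#' Approximate chicken autosome lengths
#'
#' Rounded physical lengths (bp) of the 28 chicken autosomes used as the
#' default simulated genome (~1 Gb total, macro- to micro-chromosomes).
#'
#' @return Numeric vector of 28 lengths in bp.
#' @export
chicken_autosome_lengths <- function() {
  1e6 * c(196, 149, 111, 91, 60, 35, 36, 29, 24, 21,
          20, 20, 18, 15, 13, 3, 11, 11, 10, 14,
          7, 4, 6, 6, 3, 5, 5, 5)
}

## Partition n_snps across chromosomes proportionally to length
## (largest-remainder), at least one marker each.
allocate_snps <- function(n_snps, lengths) {
  raw <- n_snps * lengths / sum(lengths)
  n <- pmax(1L, floor(raw))
  rem <- n_snps - sum(n)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep(ord, length.out = rem)
    for (i in idx) n[i] <- n[i] + 1L
  } else if (rem < 0) {
    ord <- order(n, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      if (n[ord[i]] > 1) { n[ord[i]] <- n[ord[i]] - 1L; rem <- rem + 1 }
      i <- i %% length(ord) + 1
    }
  }
  as.integer(n)
}

## Autozygous/outbred mosaic along one chromosome's genetic map (cM).
## Two-state continuous Markov chain: rate out of the autozygous state
## a = 2g/100 per cM (mean tract 100/(2g) cM), rate in chosen so the
## stationary autozygous probability equals froh. Returns a logical vector
## (TRUE = autozygous) at the marker cM positions.
sim_mosaic <- function(cm_pos, froh, g) {
  L <- length(cm_pos)
  if (froh <= 0) return(rep(FALSE, L))
  a <- 2 * g / 100
  b <- a * froh / (1 - froh)
  total <- max(cm_pos)
  state <- runif(1) < froh
  bounds <- numeric(0)
  at <- 0
  s <- state
  while (at < total) {
    at <- at + rexp(1, rate = if (s) a else b)
    bounds <- c(bounds, at)
    s <- !s
  }
  seg <- findInterval(cm_pos, bounds, left.open = TRUE)
  if (state) seg %% 2 == 0 else seg %% 2 == 1
}

#' Simulate a multi-breed genotype dataset with known ground truth
#'
#' Draws ancestral allele frequencies uniformly on `maf_range`, per-breed
#' frequencies from the Balding-Nichols model
#' `p_b ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` (exactly `p` when `F = 0`), and each
#' individual's genome as a two-state autozygous/outbred Markov mosaic along
#' the genetic map with stationary autozygous probability `froh` and mean
#' autozygous tract length `100/(2g)` cM. Genotypes are Hardy-Weinberg draws
#' outside autozygous tracts and forced homozygous (one allele drawn per
#' tract locus) inside them; calls are then masked missing i.i.d.
#'
#' @param cfg A [sim_config()].
#' @return A [gen_dataset()] with attributes `auto_mask` (samples x markers
#'   logical matrix of simulated autozygosity, the ground truth for ROH
#'   recovery) and `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_breeds = 2, breed_sizes = c(5L, 5L),
#'                   fst_per_breed = c(0.1, 0.1), froh_per_breed = c(0, 0),
#'                   chrom_lengths_bp = 10e6, n_snps = 200,
#'                   missing_rate = 0, seed = 7)
#' ds <- simulate_dataset(cfg)
#' glance(ds)
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n_chr <- length(cfg$chrom_lengths_bp)
    per_chr <- allocate_snps(cfg$n_snps, cfg$chrom_lengths_bp)
    chrom <- rep(as.character(seq_len(n_chr)), per_chr)
    pos <- unlist(lapply(seq_len(n_chr), function(k) {
      sort(sample.int(cfg$chrom_lengths_bp[k], per_chr[k]))
    }))
    L <- length(pos)
    markers <- tibble(chrom = chrom,
                      marker_id = sprintf("snp_%s_%d", chrom, pos),
                      pos_bp = as.integer(pos))

    p_anc <- runif(L, cfg$maf_range[1], cfg$maf_range[2])
    pb <- matrix(NA_real_, cfg$n_breeds, L)
    for (b in seq_len(cfg$n_breeds)) {
      Fb <- cfg$fst_per_breed[b]
      pb[b, ] <- if (Fb == 0) p_anc else
        rbeta(L, p_anc * (1 - Fb) / Fb, (1 - p_anc) * (1 - Fb) / Fb)
    }

    cm <- pos / 1e6 * cfg$cm_per_mb
    chr_index <- split(seq_len(L), factor(chrom, levels = unique(chrom)))

    n_ind <- sum(cfg$breed_sizes)
    X <- matrix(NA_integer_, n_ind, L)
    auto_mask <- matrix(FALSE, n_ind, L)
    sample_id <- character(n_ind)
    breed <- character(n_ind)
    row <- 0
    for (b in seq_len(cfg$n_breeds)) {
      p <- pb[b, ]
      for (i in seq_len(cfg$breed_sizes[b])) {
        row <- row + 1
        sample_id[row] <- sprintf("%s_%02d", cfg$breed_labels[b], i)
        breed[row] <- cfg$breed_labels[b]
        auto <- logical(L)
        for (idx in chr_index) {
          cmk <- cm[idx]
          auto[idx] <- sim_mosaic(cmk - cmk[1], cfg$froh_per_breed[b],
                                  cfg$g_generations)
        }
        g <- integer(L)
        if (any(auto)) g[auto] <- 2L * rbinom(sum(auto), 1L, p[auto])
        if (any(!auto)) g[!auto] <- rbinom(sum(!auto), 2L, p[!auto])
        if (cfg$missing_rate > 0)
          g[runif(L) < cfg$missing_rate] <- NA_integer_
        X[row, ] <- g
        auto_mask[row, ] <- auto
      }
    }
    ds <- gen_dataset(X, markers, tibble(sample_id = sample_id, breed = breed))
    dimnames(auto_mask) <- dimnames(ds$dosages)
    attr(ds, "auto_mask") <- auto_mask
    attr(ds, "sim_config") <- cfg
    attr(ds, "breed_freq_truth") <- `dimnames<-`(pb, list(cfg$breed_labels,
                                                          markers$marker_id))
    ds
  })
}

#' Simulate a gene/QTL annotation table
#'
#' Places non-degenerate random intervals inside the configured chromosome
#' bounds: `n_genes` records of kind "gene" (10-100 kb) and `n_qtl` of kind
#' "qtl" (0.2-4 Mb, capped at the chromosome), each QTL tagged with one of
#' `trait_classes` drawn uniformly. Coordinates are 0-based half-open.
#'
#' @param cfg A [sim_config()] supplying chromosome lengths and the base seed.
#' @param n_genes,n_qtl Record counts (>= 0).
#' @param trait_classes Labels assigned to QTL records.
#' @param seed RNG seed; defaults to a seed derived from `cfg$seed`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `kind`,
#'   `trait_class` (`NA` for genes).
#' @export
simulate_annotation <- function(cfg, n_genes = 100, n_qtl = 100,
                                trait_classes = c("meat", "egg", "fat",
                                                  "immunity", "other"),
                                seed = derive_seed(cfg$seed, 91L)) {
  stopifnot(n_genes >= 0, n_qtl >= 0)
  lens <- cfg$chrom_lengths_bp
  with_seed(seed, {
    draw <- function(n, kind, wmin, wmax) {
      if (n == 0)
        return(tibble(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), kind = character(),
                      trait_class = character()))
      ci <- sample.int(length(lens), n, replace = TRUE, prob = lens)
      width <- pmin(round(runif(n, wmin, wmax)), lens[ci] - 1)
      start <- floor(runif(n, 0, lens[ci] - width))
      tibble(chrom = as.character(ci), start = start, end = start + width,
             name = sprintf("%s_%04d", kind, seq_len(n)), kind = kind,
             trait_class = NA_character_)
    }
    genes <- draw(n_genes, "gene", 1e4, 1e5)
    qtl <- draw(n_qtl, "qtl", 2e5, 4e6)
    if (n_qtl > 0)
      qtl$trait_class <- sample(trait_classes, n_qtl, replace = TRUE)
    out <- dplyr::bind_rows(genes, qtl)
    stopifnot(all(out$start < out$end), all(out$end <= lens[as.integer(out$chrom)]))
    out
  })
}

#' Write the sample-to-breed table as TSV
#'
#' @param ds A [gen_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breeds_tsv <- function(ds, path) {
  readr::write_tsv(ds$samples, path)
  invisible(path)
}

#' Write an annotation table as BED-like TSV (0-based half-open)
#'
#' @param annotation Tibble as returned by [simulate_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' Read a BED-like annotation TSV
#'
#' Expects columns `chrom`, `start`, `end`, `name`, `kind`, `trait_class`
#' (header required); coordinates 0-based half-open.
#'
#' @param path Input path.
#' @return An annotation tibble.
#' @export
read_annotation_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           trait_class = readr::col_character(),
                           .default = readr::col_guess()))
  need <- c("chrom", "start", "end", "name", "kind")
  if (!all(need %in% names(out)))
    abort(paste("annotation file needs columns", paste(need, collapse = ", ")))
  if (any(out$start >= out$end)) abort("annotation intervals must satisfy start < end")
  out
}
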