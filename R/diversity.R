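#' Molecular coancestry matrix
#'
#' Identity-by-state molecular coancestry between all pairs of individuals:
#' per locus `f_ij = (x_i x_j + (2 - x_i)(2 - x_j)) / 4` for dosages
#' `x` in `{0, 1, 2}`, averaged over the loci at which both individuals are
#' called. The diagonal holds the self-coancestry
#' `s_i = (1 + homozygosity_i) / 2`, the same formula evaluated at `i = j`.
#'
#' @param ds A [gen_dataset()].
#' @return An object of class `coancestry`: list with `f` (n x n symmetric
#'   matrix), `n_loci` (loci used per pair) and the sample table.
#' @export
#' @examples
#' ds <- gen_dataset(rbind(a = c(2L, 1L), b = c(0L, 1L)),
#'                   data.frame(chrom = "1", marker_id = c("m1", "m2"),
#'                              pos_bp = 1:2),
#'                   data.frame(sample_id = c("a", "b"), breed = "X"))
#' coancestry(ds)$f
coancestry <- function(ds) {
  X <- ds$dosages
  M <- !is.na(X)
  A <- X; A[!M] <- 0L
  B <- 2L - X; B[!M] <- 0L
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  Mm <- matrix(as.double(M), nrow(M))
  n_loci <- tcrossprod(Mm)
  if (any(n_loci == 0)) {
    bad <- which(n_loci == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("samples %s and %s share no called locus",
                  ds$samples$sample_id[bad[1]], ds$samples$sample_id[bad[2]]))
  }
  f <- (tcrossprod(A) + tcrossprod(B)) / (4 * n_loci)
  dimnames(f) <- list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(f = f, n_loci = n_loci, samples = ds$samples),
            class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat(sprintf("<coancestry> %d individuals | mean f = %.4f, mean self s = %.4f\n",
              nrow(x$f), mean(x$f[lower.tri(x$f)]), mean(diag(x$f))))
  invisible(x)
}

#' @describeIn coancestry Long tibble of pairwise coancestries (`i < j` pairs
#'   plus the diagonal).
#' @param x A `coancestry` object.
#' @param ... Unused.
#' @export
tidy.coancestry <- function(x, ...) {
  ut <- which(upper.tri(x$f, diag = TRUE), arr.ind = TRUE)
  tibble(sample_i = rownames(x$f)[ut[, 1]], sample_j = colnames(x$f)[ut[, 2]],
         f = x$f[ut], n_loci = x$n_loci[ut])
}

#' @describeIn coancestry One-row summary (mean off-diagonal coancestry,
#'   mean self-coancestry).
#' @export
glance.coancestry <- function(x, ...) {
  tibble(n = nrow(x$f), mean_f = mean(x$f[lower.tri(x$f)]),
         mean_self = mean(diag(x$f)))
}

## Breed-block means of a coancestry matrix; within-breed blocks include the
## diagonal (so the HT = HS + DG identity is exact).
breed_block_means <- function(coan, breeds = coan$samples$breed) {
  labs <- unique(breeds)
  G <- vapply(labs, function(b) as.numeric(breeds == b), numeric(length(breeds)))
  cnt <- colSums(G)
  M <- t(G) %*% coan$f %*% G / outer(cnt, cnt)
  dimnames(M) <- list(labs, labs)
  M
}

#' Nei minimum genetic distance between breeds
#'
#' For a biallelic locus the Nei minimum distance between breeds `b`, `b'`
#' is `(p_b - p_b')^2` (equivalently `(J_x + J_y)/2 - J_xy`), averaged over
#' the loci at which both breeds have at least one called allele.
#'
#' @param x A [gen_dataset()] or the list returned by [breed_freqs()].
#' @return An object of class `nei_dist`: a symmetric breeds-by-breeds
#'   matrix with zero diagonal.
#' @export
nei_minimum_distance <- function(x) {
  fr <- if (inherits(x, "gen_dataset")) breed_freqs(x) else x
  B <- nrow(fr$p)
  if (B < 2) abort("Nei distance needs at least two breeds")
  D <- matrix(0, B, B, dimnames = list(rownames(fr$p), rownames(fr$p)))
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    ok <- fr$n[i, ] > 0 & fr$n[j, ] > 0
    D[i, j] <- D[j, i] <- mean((fr$p[i, ok] - fr$p[j, ok])^2)
  }
  structure(D, class = c("nei_dist", "matrix"))
}

#' @describeIn nei_minimum_distance Long tibble of breed pairs and distances.
#' @param ... Unused.
#' @export
tidy.nei_dist <- function(x, ...) {
  ut <- which(upper.tri(x), arr.ind = TRUE)
  D <- unclass(x)
  tibble(breed_i = rownames(D)[ut[, 1]], breed_j = colnames(D)[ut[, 2]],
         nei_d = D[ut])
}

#' Gene-diversity partition HT = HS + DG
#'
#' With `fbar_bb'` the mean coancestry between breeds `b` and `b'`
#' (within-breed means taken over the full block including the diagonal),
#' the partition is `HS = 1 - sum_b w_b fbar_bb` (mean within-breed gene
#' diversity), `DG = sum_bb' w_b w_b' D_bb'` with
#' `D_bb' = (fbar_bb + fbar_b'b')/2 - fbar_bb'` (mean between-breed Nei
#' distance component), and `HT = 1 - sum_bb' w_b w_b' fbar_bb'` (total gene
#' diversity). `HT = HS + DG` holds algebraically and is asserted.
#'
#' @param coan A [coancestry()] object.
#' @param breeds Breed labels per sample; defaults to the labels stored in
#'   `coan`.
#' @param breed_weights Optional breed weights (normalised to sum 1);
#'   default equal weights `1/B`.
#' @return An object of class `div_partition`: list with `HS`, `DG`, `HT`,
#'   a per-breed tibble of within-breed gene diversity, the block-mean
#'   matrix and the coancestry-based distance matrix.
#' @export
gene_diversity_partition <- function(coan, breeds = coan$samples$breed,
                                     breed_weights = NULL) {
  M <- breed_block_means(coan, breeds)
  B <- nrow(M)
  if (B < 2) abort("gene-diversity partition needs at least two breeds")
  w <- breed_weights %||% rep(1 / B, B)
  w <- w / sum(w)
  D <- (outer(diag(M), diag(M), `+`)) / 2 - M
  HS <- 1 - sum(w * diag(M))
  DG <- as.numeric(t(w) %*% D %*% w)
  HT <- 1 - as.numeric(t(w) %*% M %*% w)
  stopifnot(abs(HT - (HS + DG)) < 1e-12)
  structure(list(
    HS = HS, DG = DG, HT = HT,
    per_breed = tibble(breed = rownames(M), within_gene_diversity = 1 - diag(M)),
    block_means = M, D_breed = D, weights = setNames(w, rownames(M))),
    class = "div_partition")
}

#' @export
print.div_partition <- function(x, ...) {
  cat(sprintf("<div_partition> HT = %.4f = HS %.4f + DG %.4f (%d breeds)\n",
              x$HT, x$HS, x$DG, nrow(x$per_breed)))
  invisible(x)
}

#' @describeIn gene_diversity_partition Per-breed within-breed gene
#'   diversity as a tibble.
#' @param x A `div_partition`.
#' @param ... Unused.
#' @export
tidy.div_partition <- function(x, ...) x$per_breed

#' @describeIn gene_diversity_partition One-row `HS`/`DG`/`HT` summary.
#' @export
glance.div_partition <- function(x, ...) tibble(HS = x$HS, DG = x$DG, HT = x$HT)

## Expected rarefied allele count per locus for one breed.
## counts: matrix with rows = alleles (ref, alt), cols = loci; n = called
## allele count per locus; g = rarefaction size per locus.
rarefied_richness <- function(ref_n, alt_n, n, g) {
  term <- function(na) {
    miss <- exp(lchoose(n - na, g) - lchoose(n, g))
    miss[n - na < g] <- 0
    1 - miss
  }
  term(ref_n) + term(alt_n)
}

#' Allelic-diversity partition AT = AS + DA
#'
#' Rarefied allelic richness per breed and locus is
#' `sum_a (1 - C(n - N_a, g) / C(n, g))` with `n` the breed's called allele
#' count, `N_a` the count of allele `a` and `g` the rarefaction size
#' (El Mousadik-Petit). `AS` is the mean over breeds and loci of
#' richness - 1. `DA` averages, over ordered breed pairs, the per-locus
#' number of alleles present in the first breed and absent from the second,
#' where rarefied presence means an expected rarefied count above 0.5.
#' `AT = AS + DA` by construction.
#'
#' @param ds A [gen_dataset()].
#' @param rarefaction_size `NULL` (auto: per locus, the smallest per-breed
#'   called allele count, floored at 2) or a fixed number of alleles.
#' @return An object of class `allelic_partition`: list with `AS`, `DA`,
#'   `AT`, per-breed mean richness, the pooled rarefied richness - 1
#'   diagnostic, and the number of loci dropped as uncallable.
#' @export
allelic_diversity_partition <- function(ds, rarefaction_size = NULL) {
  fr <- breed_freqs(ds)
  B <- nrow(fr$p)
  if (B < 2) abort("allelic partition needs at least two breeds")
  n <- fr$n                       # B x L called allele counts
  alt <- round(fr$p * n); alt[n == 0] <- 0
  ref <- n - alt
  g <- if (is.null(rarefaction_size)) pmax(2, apply(n, 2, min))
       else rep(rarefaction_size, ncol(n))
  callable <- colSums(n < rep(g, each = B) * 1) == 0  # every breed has n >= g
  n_dropped <- sum(!callable)
  if (!any(callable)) abort("no locus callable in every breed at the rarefaction size")
  keep <- which(callable)
  gk <- g[keep]
  rich <- matrix(NA_real_, B, length(keep))
  pres <- array(FALSE, c(B, length(keep), 2))
  for (b in seq_len(B)) {
    rich[b, ] <- rarefied_richness(ref[b, keep], alt[b, keep], n[b, keep], gk)
    pres[b, , 1] <- gk * ref[b, keep] / n[b, keep] > 0.5
    pres[b, , 2] <- gk * alt[b, keep] / n[b, keep] > 0.5
  }
  AS <- mean(rich - 1)
  a_mat <- matrix(0, B, B)
  for (i in seq_len(B)) for (j in seq_len(B)) if (i != j)
    a_mat[i, j] <- mean((pres[i, , 1] & !pres[j, , 1]) +
                        (pres[i, , 2] & !pres[j, , 2]))
  DA <- sum(a_mat) / (B * (B - 1))
  pooled_n <- colSums(n[, keep, drop = FALSE])
  pooled_alt <- colSums(alt[, keep, drop = FALSE])
  pooled <- mean(rarefied_richness(pooled_n - pooled_alt, pooled_alt,
                                   pooled_n, gk)) - 1
  structure(list(
    AS = AS, DA = DA, AT = AS + DA,
    per_breed = tibble(breed = rownames(fr$p), mean_richness = rowMeans(rich)),
    pooled_richness_minus_1 = pooled,
    n_loci_used = length(keep), n_loci_dropped = n_dropped),
    class = "allelic_partition")
}

#' @export
print.allelic_partition <- function(x, ...) {
  cat(sprintf("<allelic_partition> AT = %.4f = AS %.4f + DA %.4f (%d loci, %d dropped)\n",
              x$AT, x$AS, x$DA, x$n_loci_used, x$n_loci_dropped))
  invisible(x)
}

#' @describeIn allelic_diversity_partition Per-breed mean rarefied richness.
#' @param x An `allelic_partition`.
#' @param ... Unused.
#' @export
tidy.allelic_partition <- function(x, ...) x$per_breed

#' @describeIn allelic_diversity_partition One-row `AS`/`DA`/`AT` summary.
#' @export
glance.allelic_partition <- function(x, ...)
  tibble(AS = x$AS, DA = x$DA, AT = x$AT,
         pooled_richness_minus_1 = x$pooled_richness_minus_1)

#' Mean private alleles per locus and breed
#'
#' An allele is private to breed `b` at a locus when it is observed (at
#' least one called copy) in `b` and in no other breed. Reported as the mean
#' count per locus over all loci.
#'
#' @param ds A [gen_dataset()] with at least two breeds.
#' @return Tibble with columns `breed`, `private_per_locus`.
#' @export
private_alleles <- function(ds) {
  fr <- breed_freqs(ds)
  B <- nrow(fr$p)
  if (B < 2) abort("private alleles are undefined for a single breed")
  alt <- round(fr$p * fr$n); alt[fr$n == 0] <- 0
  ref <- fr$n - alt
  ref_obs <- ref > 0; alt_obs <- alt > 0
  priv <- vapply(seq_len(B), function(b) {
    others_ref <- colSums(ref_obs[-b, , drop = FALSE]) > 0
    others_alt <- colSums(alt_obs[-b, , drop = FALSE]) > 0
    mean((ref_obs[b, ] & !others_ref) + (alt_obs[b, ] & !others_alt))
  }, numeric(1))
  tibble(breed = rownames(fr$p), private_per_locus = priv)
}

#' Within-breed diversity indices
#'
#' Per breed: `fii` the mean coancestry over ordered pairs of distinct
#' individuals, `si` the mean self-coancestry, `dii` the mean inter-individual
#' Nei distance `d_ij = (s_i + s_j)/2 - f_ij`, and
#' `Gi = dii / (dii + (1 - si))`, the between-individual share of the
#' within-breed diversity. `Gi` is `NA` when its denominator is zero.
#'
#' @param coan A [coancestry()] object.
#' @param breeds Breed labels per sample (default: stored labels). Every
#'   breed needs at least two individuals.
#' @return Tibble with columns `breed`, `fii`, `si`, `dii`, `Gi`.
#' @export
breed_indices <- function(coan, breeds = coan$samples$breed) {
  labs <- unique(breeds)
  rows <- lapply(labs, function(b) {
    idx <- which(breeds == b)
    if (length(idx) < 2)
      abort(sprintf("breed %s has fewer than two individuals (dii undefined)", b))
    fb <- coan$f[idx, idx, drop = FALSE]
    s <- diag(fb)
    off <- !diag(length(idx))
    fii <- mean(fb[off])
    dmat <- (outer(s, s, `+`)) / 2 - fb
    dii <- mean(dmat[off])
    si <- mean(s)
    den <- dii + (1 - si)
    tibble(breed = b, fii = fii, si = si, dii = dii,
           Gi = if (den > 0) dii / den else NA_real_)
  })
  dplyr::bind_rows(rows)
}
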