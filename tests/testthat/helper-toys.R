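# Small construction helpers and independent brute-force oracles shared
# across the test files. Oracles deliberately use naive per-locus /
# per-subinterval enumeration, independent of the package's vectorized code.

toy_ds <- function(dosages, breeds = rep("B1", nrow(dosages)),
                   chrom = NULL, pos = NULL) {
  d <- as.matrix(dosages)
  L <- ncol(d)
  chrom <- chrom %||% rep("1", L)
  pos <- pos %||% unlist(lapply(split(seq_len(L), factor(chrom, unique(chrom))),
                                seq_along))
  gen_dataset(d,
              data.frame(chrom = chrom, marker_id = paste0("m", seq_len(L)),
                         pos_bp = as.integer(pos)),
              data.frame(sample_id = paste0("s", seq_len(nrow(d))),
                         breed = breeds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-individual dataset on a single chromosome, dosages at given positions.
roh_ds <- function(dosages, pos, chrom = "1") {
  toy_ds(matrix(as.integer(dosages), nrow = 1), chrom = rep(chrom, length(pos)),
         pos = pos)
}

# Per-locus brute-force molecular coancestry between two dosage vectors.
brute_coancestry_pair <- function(x, y) {
  vals <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    (a * b + (2 - a) * (2 - b)) / 4
  }, x, y)
  mean(vals, na.rm = TRUE)
}

# Brute-force ROH enumeration for one individual on one chromosome,
# following the same rule set as detect_roh but via O(n^2) subinterval
# enumeration: split at gaps, qualify subintervals by het/missing counts,
# keep only maximal ones, greedy-select longest-first (leftmost tie),
# then filter by min_snps / min_length / density.
brute_roh <- function(dosage, pos, params) {
  n <- length(pos)
  piece_id <- cumsum(c(1L, as.integer(diff(pos) > params$max_gap_bp)))
  het <- !is.na(dosage) & dosage == 1L
  mis <- is.na(dosage)
  cand <- list()
  for (pc in split(seq_len(n), piece_id)) {
    m <- length(pc)
    ## enumerate every subinterval via prefix sums: qual[i, j] marks those
    ## within the het/missing allowances
    H0 <- c(0, cumsum(het[pc])); M0 <- c(0, cumsum(mis[pc]))
    hc <- outer(seq_len(m), seq_len(m), function(i, j) H0[j + 1] - H0[i])
    mc <- outer(seq_len(m), seq_len(m), function(i, j) M0[j + 1] - M0[i])
    qual <- hc <= params$max_het & mc <= params$max_missing &
      outer(seq_len(m), seq_len(m), `<=`)
    left_ext <- rbind(FALSE, qual[-m, , drop = FALSE])
    right_ext <- cbind(qual[, -1, drop = FALSE], FALSE)
    maximal <- which(qual & !left_ext & !right_ext, arr.ind = TRUE)
    for (k in seq_len(nrow(maximal)))
      cand[[length(cand) + 1]] <- c(start = pc[maximal[k, 1]],
                                    end = pc[maximal[k, 2]])
  }
  if (!length(cand)) return(data.frame())
  cand <- do.call(rbind, cand)
  len <- pos[cand[, "end"]] - pos[cand[, "start"]] + 1
  ord <- order(-len, pos[cand[, "start"]])
  sel <- matrix(numeric(0), 0, 2)
  for (k in ord) {
    s <- pos[cand[k, "start"]]; e <- pos[cand[k, "end"]]
    if (nrow(sel) == 0 || !any(s <= sel[, 2] & e >= sel[, 1]))
      sel <- rbind(sel, c(s, e))
  }
  out <- data.frame(start_bp = sel[, 1], end_bp = sel[, 2])
  out$n_snps <- mapply(function(s, e) sum(pos >= s & pos <= e),
                       out$start_bp, out$end_bp)
  out$length_bp <- out$end_bp - out$start_bp + 1
  keep <- out$n_snps >= params$min_snps &
    out$length_bp >= params$min_length_bp &
    out$n_snps / (out$length_bp / 1000) >= params$min_density_snp_per_kb
  out <- out[keep, , drop = FALSE]
  out[order(out$start_bp), , drop = FALSE]
}

# Random single-individual ROH instance generator for oracle comparison.
random_roh_instance <- function(seed) {
  set.seed(seed)
  n <- sample(20:200, 1)
  pos <- sort(sample.int(5e6, n))
  dosage <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                   prob = c(0.45, 0.08, 0.43, 0.04))
  params <- roh_params(
    min_length_bp = sample(c(1e4, 1e5, 5e5), 1),
    min_snps = sample(3:15, 1),
    max_het = sample(0:2, 1),
    max_missing = sample(0:3, 1),
    min_density_snp_per_kb = sample(c(0.001, 0.01, 0.05), 1),
    max_gap_bp = sample(c(2e5, 5e5, 1e6), 1))
  list(dosage = dosage, pos = pos, params = params)
}

# Balding-Nichols two-breed fixture for divergence-recovery checks; returns
# the generator's realized (true) breed frequencies alongside the dataset.
bn_two_breeds <- function(F, n_snps, seed, breed_sizes = c(20L, 20L)) {
  cfg <- sim_config(n_breeds = 2, breed_sizes = breed_sizes,
                    fst_per_breed = c(F, F), froh_per_breed = c(0, 0),
                    chrom_lengths_bp = c(100e6, 100e6), n_snps = n_snps,
                    missing_rate = 0, seed = seed)
  simulate_dataset(cfg)
}

# Maximal candidate intervals (bp) for one individual under the het/missing
# allowances, before selection and filtering; used for the candidate-level
# monotonicity checks.
candidate_intervals <- function(dosage, pos, params) {
  piece_id <- cumsum(c(1L, as.integer(diff(pos) > params$max_gap_bp)))
  het <- !is.na(dosage) & dosage == 1L
  mis <- is.na(dosage)
  out <- list()
  for (pc in split(seq_along(pos), piece_id)) {
    cand <- rohdiv:::maximal_intervals(het[pc], mis[pc], params$max_het,
                                       params$max_missing)
    if (nrow(cand))
      out[[length(out) + 1]] <- cbind(start = pos[pc][cand[, 1]],
                                      end = pos[pc][cand[, 2]])
  }
  if (length(out)) do.call(rbind, out) else cbind(start = numeric(0), end = numeric(0))
}

contained_in <- function(tight, base) {
  if (nrow(tight) == 0) return(TRUE)
  all(vapply(seq_len(nrow(tight)), function(k)
    any(base[, "start"] <= tight[k, "start"] & tight[k, "end"] <= base[, "end"]),
    logical(1)))
}

# Direct pool-objective evaluation, shared by the optimizer oracles.
eval_pool_for_test <- function(ds, counts, objective) {
  fr <- breed_freqs(ds)
  N <- sum(counts)
  p <- as.numeric((counts / N) %*% fr$p)
  if (objective == "H") mean(2 * p * (1 - p)) * N / (N - 1)
  else mean((1 - (1 - p)^(2 * N)) + (1 - p^(2 * N)))
}

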