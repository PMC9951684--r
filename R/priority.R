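#' Leave-one-out breed contributions to diversity
#'
#' Recomputes the gene-diversity partition (HT = HS + DG) and the allelic
#' partition (AT = AS + DA) after removing each breed in turn, and reports
#' the percentage change `100 * (X_full - X_without_breed) / X_full` for
#' every component. Positive values mean diversity is lost when the breed is
#' removed (the breed contributes diversity); negative values mean removal
#' increases diversity.
#'
#' @param ds A [gen_dataset()] with at least three breeds (each removal must
#'   leave at least two).
#' @param rarefaction_size Passed to [allelic_diversity_partition()].
#' @return A tibble of class `contribution_tbl` with per-breed columns
#'   `dHT_pct`, `dHS_pct`, `dDG_pct`, `dAT_pct`, `dAS_pct`, `dDA_pct` and
#'   rank columns for `dHT_pct` and `dAT_pct`. The full-set partitions are
#'   attached as attributes `gene_full` and `allelic_full`.
#' @export
leave_one_out <- function(ds, rarefaction_size = NULL) {
  breeds <- unique(ds$samples$breed)
  if (length(breeds) < 3)
    abort("leave-one-out needs at least three breeds (removal must leave two)")
  coan <- coancestry(ds)
  gene_full <- gene_diversity_partition(coan)
  allelic_full <- allelic_diversity_partition(ds, rarefaction_size)
  if (gene_full$HT == 0 || allelic_full$AT == 0)
    abort("full-set HT or AT is zero; contributions are undefined")
  pct <- function(full, red) 100 * (full - red) / full
  rows <- lapply(breeds, function(b) {
    keep <- ds$samples$breed != b
    sub_breeds <- ds$samples$breed[keep]
    coan_sub <- structure(list(f = coan$f[keep, keep, drop = FALSE],
                               n_loci = coan$n_loci[keep, keep, drop = FALSE],
                               samples = ds$samples[keep, , drop = FALSE]),
                          class = "coancestry")
    g <- gene_diversity_partition(coan_sub, sub_breeds)
    a <- allelic_diversity_partition(subset_gen(ds, samples = which(keep)),
                                     rarefaction_size)
    tibble(breed = b,
           dHT_pct = pct(gene_full$HT, g$HT),
           dHS_pct = pct(gene_full$HS, g$HS),
           dDG_pct = pct(gene_full$DG, g$DG),
           dAT_pct = pct(allelic_full$AT, a$AT),
           dAS_pct = pct(allelic_full$AS, a$AS),
           dDA_pct = pct(allelic_full$DA, a$DA))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(rank_gene = rank(-.data$dHT_pct, ties.method = "min"),
                  rank_allelic = rank(-.data$dAT_pct, ties.method = "min"))
  attr(out, "gene_full") <- gene_full
  attr(out, "allelic_full") <- allelic_full
  class(out) <- c("contribution_tbl", class(out))
  out
}

## Pool objectives. p: B x L breed alternate-allele frequencies.
## H: expected heterozygosity of the pooled frequencies with the finite-pool
## correction N/(N-1). K: expected number of distinct alleles per locus seen
## in a pool sample of 2N allele draws.
pool_objective_H <- function(p_pool, N) mean(2 * p_pool * (1 - p_pool)) * N / (N - 1)
pool_objective_K <- function(p_pool, N)
  mean((1 - (1 - p_pool)^(2 * N)) + (1 - p_pool^(2 * N)))

eval_pool <- function(counts, p, N, objective) {
  w <- counts / N
  p_pool <- as.numeric(w %*% p)
  if (objective == "H") pool_objective_H(p_pool, N) else pool_objective_K(p_pool, N)
}

#' Optimize the breed composition of a synthetic conservation pool
#'
#' Finds the integer breed composition `c` (counts of individuals summing to
#' `N`) that maximizes either the expected heterozygosity of the pool
#' (`objective = "H"`: mean over loci of `2 p (1 - p)` at the pooled
#' frequencies `p = sum_b (c_b / N) p_b`, times the finite-pool factor
#' `N / (N - 1)`) or its allelic diversity (`objective = "K"`: expected
#' number of distinct alleles per locus in a sample of `2N` allele draws
#' from the pooled frequencies). The search is simulated annealing over
#' integer compositions (single-individual transfers, geometric cooling,
#' best of `restarts` random starts) followed by a deterministic
#' steepest-ascent polish; every pure-breed composition and the uniform
#' composition are also evaluated, so the returned objective can never fall
#' below them. Both objectives are concave in the proportions, so the polish
#' makes two-breed instances exact.
#'
#' @param ds A [gen_dataset()].
#' @param N Pool size in individuals (default 1000; must be >= the number
#'   of breeds and >= 2).
#' @param objective `"H"` (gene diversity) or `"K"` (allelic diversity).
#' @param seed RNG seed (deterministic search).
#' @param restarts Number of annealing restarts.
#' @param iters Annealing iterations per restart.
#' @param t0,cooling Initial temperature and geometric cooling factor.
#' @return An object of class `pool_solution`: list with the composition
#'   counts, proportions, objective kind and value, per-restart optima, a
#'   `flat` flag (landscape flat: uniform composition returned) and the seed.
#' @export
optimize_pool <- function(ds, N = 1000L, objective = c("H", "K"), seed = 1L,
                          restarts = 10L, iters = 1000L, t0 = 0.01,
                          cooling = 0.995) {
  objective <- match.arg(objective)
  fr <- breed_freqs(ds)
  p <- fr$p
  p[is.nan(p)] <- 0.5  # breed with no calls at a locus: uninformative
  B <- nrow(p)
  if (N < max(B, 2)) abort("pool size N must be at least the number of breeds (and >= 2)")
  with_seed(seed, {
    obj <- function(counts) eval_pool(counts, p, N, objective)
    ## reference compositions: pure breeds and (near-)uniform
    pure <- lapply(seq_len(B), function(b) { c0 <- rep(0, B); c0[b] <- N; c0 })
    uni <- rep(floor(N / B), B)
    uni[seq_len(N - sum(uni))] <- uni[seq_len(max(0, N - sum(uni)))] + 1
    cand <- c(pure, list(uni))
    cand_vals <- vapply(cand, obj, numeric(1))
    flat <- diff(range(cand_vals)) < 1e-14
    best <- cand[[which.max(cand_vals)]]
    best_val <- max(cand_vals)
    restart_vals <- numeric(0)
    if (!flat && B > 1) {
      for (r in seq_len(restarts)) {
        cur <- if (r == 1) uni else as.numeric(stats::rmultinom(1, N, runif(B) + 0.05))
        cur_val <- obj(cur)
        temp <- t0
        loc_best <- cur; loc_val <- cur_val
        for (it in seq_len(iters)) {
          donors <- which(cur > 0)
          from <- donors[sample.int(length(donors), 1)]
          others <- setdiff(seq_len(B), from)
          to <- others[sample.int(length(others), 1)]
          prop <- cur; prop[from] <- prop[from] - 1; prop[to] <- prop[to] + 1
          pv <- obj(prop)
          if (pv >= cur_val || runif(1) < exp((pv - cur_val) / temp)) {
            cur <- prop; cur_val <- pv
            if (cur_val > loc_val) { loc_best <- cur; loc_val <- cur_val }
          }
          temp <- temp * cooling
        }
        ## deterministic steepest-ascent polish on single transfers
        repeat {
          improved <- FALSE
          best_move <- NULL; best_gain <- 0
          for (from in which(loc_best > 0)) for (to in seq_len(B)) {
            if (to == from) next
            prop <- loc_best; prop[from] <- prop[from] - 1; prop[to] <- prop[to] + 1
            gain <- obj(prop) - loc_val
            if (gain > best_gain + 1e-15) { best_gain <- gain; best_move <- prop }
          }
          if (!is.null(best_move)) {
            loc_best <- best_move; loc_val <- loc_val + best_gain; improved <- TRUE
          }
          if (!improved) break
        }
        restart_vals <- c(restart_vals, loc_val)
        if (loc_val > best_val) { best <- loc_best; best_val <- loc_val }
      }
    }
    if (flat) { best <- uni; best_val <- cand_vals[[length(cand_vals)]] }
    structure(list(
      N = N, counts = setNames(as.integer(best), rownames(p)),
      proportions = setNames(best / N, rownames(p)),
      objective = objective, value = best_val,
      restart_values = restart_vals, flat = flat, seed = seed),
      class = "pool_solution")
  })
}

#' @export
print.pool_solution <- function(x, ...) {
  cat(sprintf("<pool_solution> objective %s = %.5f at N = %d%s\n",
              x$objective, x$value, x$N,
              if (x$flat) " (flat landscape: uniform composition)" else ""))
  print(round(x$proportions, 3))
  invisible(x)
}

#' @describeIn optimize_pool Per-breed pool counts and proportions.
#' @param x A `pool_solution`.
#' @param ... Unused.
#' @export
tidy.pool_solution <- function(x, ...)
  tibble(breed = names(x$counts), count = as.integer(x$counts),
         proportion = as.numeric(x$proportions))

#' @describeIn optimize_pool One-row summary of the optimum.
#' @export
glance.pool_solution <- function(x, ...)
  tibble(objective = x$objective, value = x$value, N = x$N, flat = x$flat,
         n_restarts = length(x$restart_values))
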