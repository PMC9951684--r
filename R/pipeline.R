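#' Pipeline run configuration
#'
#' Assembles the full run configuration with every stage parameter at its
#' standard value: call-rate thresholds 0.95 (individual) and 0.99 (marker),
#' pruning window 50/5 with r^2 threshold 0.2, the [roh_params()] defaults,
#' island incidence threshold 0.30, pool size 1000, LD bins 500/1100 with
#' breakpoint 2000 kb, and 3 cM/Mb. Unknown keys in `...` are rejected.
#'
#' @param ... Named overrides for any default entry (nested lists are
#'   merged key-by-key, unknown keys rejected).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, prune = FALSE, diversity = TRUE,
                  priority = TRUE, roh = TRUE, islands = TRUE,
                  annotate = FALSE, ld = TRUE, ne = TRUE),
    inputs = list(ped = NULL, map = NULL, bed = NULL, bim = NULL, fam = NULL,
                  annotation = NULL, class_map = NULL),
    sim = list(n_breeds = 8L, breed_sizes = NULL, fst_per_breed = NULL,
               froh_per_breed = NULL, chrom_lengths_bp = NULL,
               n_snps = 450000L, cm_per_mb = 3, g_generations = 8,
               missing_rate = 0.002, maf_range = c(0.05, 0.95)),
    qc = list(min_ind_call = 0.95, min_snp_call = 0.99, autosomes_only = TRUE,
              drop_duplicates = TRUE, max_autosome = 28L),
    prune = list(window_snps = 50L, step_snps = 5L, r2_threshold = 0.2),
    priority = list(pool_size = 1000L, restarts = 10L, iters = 1000L),
    roh = list(min_length_bp = 1e6, min_snps = 100L, max_het = 1L,
               max_missing = 2L, min_density_snp_per_kb = 0.01,
               max_gap_bp = 1e6),
    islands = list(threshold = 0.30, min_island_snps = 50L),
    annotate = list(min_overlap_bp = 1),
    ld = list(breed = NULL, max_dist_bp = 2e6, width_near = 500,
              width_far = 1100, breakpoint = 2000, unit = "kb"),
    ne = list(cm_per_mb = 3, epsilon = 1e-6))
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    abort(sprintf("config entries under '%s' must be named", path))
  unknown <- setdiff(nm, names(base))
  if (length(unknown))
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" under '", path, "'") else "",
                  paste(unknown, collapse = ", ")))
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, if (nzchar(path)) "$" else "", k))
    else base[k] <- override[k]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys must match [pipeline_config()] entries
#'   (unknown keys are rejected).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

## Non-cryptographic 32-bit FNV-1a hash of the serialized config, for output
## provenance headers.
config_hash <- function(cfg) {
  s <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 2166136261
  for (ch in s) h <- (bitwXor(as.integer(h %% 2^31), ch) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

write_stage_tsv <- function(x, path, cfg) {
  hdr <- sprintf("# rohdiv %s | config %s | seed %d",
                 as.character(utils::packageVersion("rohdiv")),
                 config_hash(cfg), cfg$seed)
  writeLines(hdr, path)
  vroom_ok <- readr::format_tsv(as_tibble(x))
  cat(vroom_ok, file = path, append = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — simulate (or load), qc, prune,
#' diversity, priority, roh, islands, annotate, ld, ne — writing one TSV
#' per stage into `out_dir`, each with a provenance header (package
#' version, config hash, global seed), plus the serialized configuration
#' and a plain-text summary of the headline tables. Per-stage seeds are
#' derived deterministically from the global seed, so two runs with the
#' same config are identical. A failing stage stops the run with the stage
#' named; TSVs already written are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `pipeline_run`: list of stage results and
#'   output paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  res <- list(config = config, paths = character())
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, code) {
    if (!isTRUE(config$stages[[name]])) { logf("stage %s: skipped", name); return(NULL) }
    logf("stage %s: start", name)
    tryCatch(code, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }
  emit <- function(x, name) {
    p <- write_stage_tsv(x, file.path(out_dir, paste0(name, ".tsv")), config)
    res$paths <<- c(res$paths, p)
  }

  ds <- stage("simulate", {
    sim_args <- config$sim[!vapply(config$sim, is.null, logical(1))]
    cfg <- do.call(sim_config, c(sim_args, list(seed = derive_seed(config$seed, 1L))))
    simulate_dataset(cfg)
  })
  if (is.null(ds)) {
    inp <- config$inputs
    ds <- if (!is.null(inp$bed)) read_plink_binary(inp$bed, inp$bim, inp$fam)
      else if (!is.null(inp$ped)) read_plink_text(inp$ped, inp$map)
      else abort("simulate stage disabled and no genotype input configured")
  }

  qc <- stage("qc", do.call(qc_filter, c(list(ds), config$qc)))
  if (!is.null(qc)) { ds <- qc$dataset; emit(qc$report, "qc_report") }

  pruned <- stage("prune", do.call(ld_prune, c(list(ds), config$prune)))
  if (!is.null(pruned)) {
    emit(tibble(marker_id = pruned), "pruned_markers")
    res$pruned_markers <- pruned
  }

  div <- stage("diversity", {
    coan <- coancestry(ds)
    list(coancestry = coan,
         nei = nei_minimum_distance(ds),
         gene = gene_diversity_partition(coan),
         allelic = allelic_diversity_partition(ds),
         indices = breed_indices(coan),
         private = private_alleles(ds))
  })
  if (!is.null(div)) {
    emit(tidy(div$nei), "nei_distance")
    emit(div$indices, "breed_indices")
    emit(dplyr::bind_cols(glance(div$gene), glance(div$allelic)), "partitions")
    emit(div$private, "private_alleles")
    res$diversity <- div
  }

  prio <- stage("priority", {
    contrib <- leave_one_out(ds)
    pool_h <- optimize_pool(ds, N = config$priority$pool_size, objective = "H",
                            seed = derive_seed(config$seed, 5L),
                            restarts = config$priority$restarts,
                            iters = config$priority$iters)
    pool_k <- optimize_pool(ds, N = config$priority$pool_size, objective = "K",
                            seed = derive_seed(config$seed, 6L),
                            restarts = config$priority$restarts,
                            iters = config$priority$iters)
    list(contrib = contrib, pool_h = pool_h, pool_k = pool_k)
  })
  if (!is.null(prio)) {
    emit(prio$contrib, "contributions")
    emit(dplyr::full_join(
      dplyr::rename(tidy(prio$pool_h), count_H = "count", prop_H = "proportion"),
      dplyr::rename(tidy(prio$pool_k), count_K = "count", prop_K = "proportion"),
      by = "breed"), "pool_composition")
    res$priority <- prio
  }

  segs <- stage("roh", detect_roh(ds, do.call(roh_params, config$roh)))
  summ <- NULL
  if (!is.null(segs)) {
    emit(dplyr::mutate(segs, length_kb = .data$length_bp / 1000), "roh_segments")
    summ <- summarize_roh(segs, ds$samples)
    emit(summ, "roh_summary")
    res$roh <- list(segments = segs, summary = summ)
  }

  if (is.null(segs) && isTRUE(config$stages$islands)) {
    logf("stage islands: skipped (roh stage did not run)")
    config$stages$islands <- FALSE
  }
  isl <- stage("islands", {
    inc <- snp_incidence(segs, ds)
    list(incidence = inc,
         islands = call_islands(inc, config$islands$threshold,
                                config$islands$min_island_snps))
  })
  if (!is.null(isl)) {
    emit(isl$islands, "roh_islands")
    ## BED mirror, 0-based half-open
    readr::write_tsv(tibble(chrom = isl$islands$chrom,
                            start = isl$islands$start_bp - 1,
                            end = isl$islands$end_bp),
                     file.path(out_dir, "roh_islands.bed"), col_names = FALSE)
    res$islands <- isl
  }

  if (is.null(isl) && isTRUE(config$stages$annotate)) {
    logf("stage annotate: skipped (islands stage did not run)")
    config$stages$annotate <- FALSE
  }
  ann <- stage("annotate", {
    tab <- read_annotation_tsv(config$inputs$annotation)
    rep <- overlap_islands(isl$islands, tab,
                           min_overlap_bp = config$annotate$min_overlap_bp,
                           chrom_levels = unique(ds$markers$chrom))
    cmap <- if (!is.null(config$inputs$class_map))
      readr::read_tsv(config$inputs$class_map, show_col_types = FALSE) else NULL
    list(report = rep, classes = classify_traits(rep, cmap))
  })
  if (!is.null(ann)) {
    emit(dplyr::select(ann$report, -"record_ids"), "island_annotation")
    emit(ann$classes, "trait_classes")
    res$annotation <- ann
  }

  ld <- stage("ld", {
    pairs <- pairwise_r2(ds, breed = config$ld$breed,
                         max_dist_bp = config$ld$max_dist_bp)
    decay_curve(pairs, config$ld$width_near, config$ld$width_far,
                config$ld$breakpoint, config$ld$unit)
  })
  if (!is.null(ld)) { emit(ld, "ld_curve"); res$ld_curve <- ld }

  if (is.null(ld) && isTRUE(config$stages$ne)) {
    logf("stage ne: skipped (ld stage did not run)")
    config$stages$ne <- FALSE
  }
  ne <- stage("ne", {
    n_s <- if (is.null(config$ld$breed)) nrow(ds$samples)
      else sum(ds$samples$breed == config$ld$breed)
    ne_trajectory(ld, n_samples = n_s, cm_per_mb = config$ne$cm_per_mb,
                  epsilon = config$ne$epsilon)
  })
  if (!is.null(ne)) { emit(ne, "ne_trajectory"); res$ne <- ne }

  res$dataset <- ds
  writeLines(pipeline_summary_text(res), file.path(out_dir, "summary.txt"))
  res$paths <- c(res$paths, file.path(out_dir, "summary.txt"))
  logf("pipeline complete: %d output tables", length(res$paths))
  class(res) <- "pipeline_run"
  invisible(res)
}

pipeline_summary_text <- function(res) {
  out <- c("rohdiv pipeline summary", strrep("=", 40))
  fmt_tbl <- function(x) utils::capture.output(print(as.data.frame(x), digits = 4))
  if (!is.null(res$roh)) {
    out <- c(out, "", "Per-breed ROH summary (SROH Mb / NROH / MNROH Mb):",
             fmt_tbl(res$roh$summary), "",
             "Aggregates:", fmt_tbl(attr(res$roh$summary, "totals")))
  }
  if (!is.null(res$priority))
    out <- c(out, "", "Leave-one-out contributions (%):", fmt_tbl(res$priority$contrib))
  if (!is.null(res$islands))
    out <- c(out, "", "ROH islands:", fmt_tbl(res$islands$islands))
  if (!is.null(res$annotation))
    out <- c(out, "", "Trait classes of overlapping QTLs:",
             fmt_tbl(res$annotation$classes))
  if (is.null(res$roh)) out <- c(out, "", "(roh stage skipped)")
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d output files, seed %d\n",
              length(x$paths), x$config$seed))
  invisible(x)
}
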