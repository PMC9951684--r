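#' Read PLINK text genotypes (PED/MAP)
#'
#' The alternate allele of each marker is the lexicographically larger allele
#' observed at that marker (deterministic, since PED files carry no
#' reference-allele metadata); dosages count copies of it. A marker at which
#' only one allele is observed therefore decodes as dosage 2 for every called
#' sample. `0 0` decodes as missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [gen_dataset()]. Breed labels are taken from the PED family id
#'   column.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- read_map_file(map_path)
  L <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) > 1)
    abort("ragged PED file: lines have differing field counts")
  if (nf[1] != 2L * L + 6L)
    abort(sprintf("PED has %d fields per line; expected %d for %d markers",
                  nf[1], 2L * L + 6L, L))
  ped <- do.call(rbind, fields)
  samples <- tibble(sample_id = ped[, 2], breed = ped[, 1])
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample id in PED")
  a1 <- ped[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(L), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  if (any(xor(is.na(a1), is.na(a2))))
    abort("half-missing genotype (one allele '0') in PED")
  X <- matrix(NA_integer_, nrow(ped), L)
  for (l in seq_len(L)) {
    obs <- sort(unique(c(a1[, l], a2[, l])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2)
      abort(sprintf("marker %s has more than two alleles", map$marker_id[l]))
    alt <- if (length(obs)) obs[length(obs)] else NA_character_
    X[, l] <- (a1[, l] == alt) + (a2[, l] == alt)
  }
  gen_dataset(X, map, samples)
}

read_map_file <- function(map_path) {
  m <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(m) < 4) abort("MAP file needs 4 columns: chrom, id, cM, bp")
  tibble(chrom = m[[1]], marker_id = m[[2]], pos_bp = as.integer(m[[4]]))
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Alleles are written as `A` (reference) and `B` (alternate) so that the
#' lexicographic alternate-allele convention of [read_plink_text()] inverts
#' the encoding; missing calls are written `0 0`. A marker whose called
#' dosages are all 0 is indistinguishable in PED text from one fixed for the
#' alternate allele and reads back as dosage 2 (the binary format, which
#' stores both allele names, round-trips exactly).
#'
#' @param ds A [gen_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(ds, prefix) {
  write_map_file(ds, paste0(prefix, ".map"))
  X <- ds$dosages
  code <- c("A A", "A B", "B B")
  lines <- vapply(seq_len(nrow(X)), function(i) {
    g <- ifelse(is.na(X[i, ]), "0 0", code[X[i, ] + 1L])
    paste(ds$samples$breed[i], ds$samples$sample_id[i], "0 0 0 -9",
          paste(g, collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

write_map_file <- function(ds, path) {
  writeLines(sprintf("%s\t%s\t0\t%d", ds$markers$chrom, ds$markers$marker_id,
                     ds$markers$pos_bp), path)
}

## 2-bit PLINK codes, SNP-major: within a byte, samples occupy bit pairs from
## the least-significant end; 00 = hom alternate (A1) -> dosage 2,
## 10 = het -> 1, 11 = hom reference (A2) -> 0, 01 = missing -> NA.
plink_bits_to_dosage <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

decode_table <- function() {
  sapply(0:255, function(byte) {
    pairs <- bitwAnd(bitwShiftR(byte, c(0L, 2L, 4L, 6L)), 3L)
    unname(plink_bits_to_dosage[as.character(pairs)])
  })  # 4 x 256
}

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Decodes the SNP-major 2-bit PLINK 1 format exactly. Dosages count copies
#' of the BIM A1 allele (the alternate allele as written by
#' [write_plink_binary()]).
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.
#' @return A [gen_dataset()]; breed labels come from the FAM family id.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  markers <- tibble(chrom = bim[[1]], marker_id = bim[[2]],
                    pos_bp = as.integer(bim[[4]]))
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  samples <- tibble(sample_id = fam[[2]], breed = fam[[1]])
  n <- nrow(samples); L <- nrow(markers)
  bpm <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = 3 + bpm * L + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    abort("not a PLINK 1 BED file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    abort("only SNP-major BED files (mode byte 0x01) are supported")
  body <- raw[-(1:3)]
  if (length(body) < bpm * L)
    abort(sprintf("truncated BED file: need %d data bytes, found %d",
                  bpm * L, length(body)))
  tab <- decode_table()
  codes <- tab[, as.integer(body[seq_len(bpm * L)]) + 1L]  # 4 x (bpm*L)
  X <- matrix(as.integer(codes), nrow = 4 * bpm)[seq_len(n), , drop = FALSE]
  dim(X) <- c(n, L)
  gen_dataset(X, markers, samples)
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Writes the SNP-major 2-bit coding bit-exactly, with A1 = `B` (alternate)
#' and A2 = `A` (reference) in the BIM, so [read_plink_binary()] recovers the
#' dosage matrix exactly.
#'
#' @param ds A [gen_dataset()].
#' @param prefix Output path prefix; writes `.bed`, `.bim` and `.fam`.
#' @return The prefix, invisibly.
#' @export
write_plink_binary <- function(ds, prefix) {
  writeLines(sprintf("%s\t%s\t0\t%d\tB\tA", ds$markers$chrom,
                     ds$markers$marker_id, ds$markers$pos_bp),
             paste0(prefix, ".bim"))
  writeLines(sprintf("%s %s 0 0 0 -9", ds$samples$breed, ds$samples$sample_id),
             paste0(prefix, ".fam"))
  X <- ds$dosages
  n <- nrow(X); L <- ncol(X); bpm <- ceiling(n / 4)
  ## dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, 4 * bpm, L)
  codes_by_dosage <- c(3L, 2L, 0L)
  blk <- matrix(NA_integer_, 4 * bpm, L)
  blk[seq_len(n), ] <- X
  known <- !is.na(blk)
  code[known] <- codes_by_dosage[blk[known] + 1L]
  code[seq_len(4 * bpm) > n, ] <- 3L  # pad bits: hom reference (ignored)
  shift <- rep(c(0L, 2L, 4L, 6L), bpm)
  bytes <- matrix(bitwShiftL(code, shift), nrow = 4)
  bytes <- colSums(matrix(bytes, nrow = 4))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
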