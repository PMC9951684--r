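sim_fixture <- function(seed = 21) {
  cfg <- sim_config(n_breeds = 2, breed_sizes = c(10L, 10L),
                    fst_per_breed = c(0.05, 0.1), froh_per_breed = c(0.05, 0),
                    chrom_lengths_bp = c(20e6, 10e6), n_snps = 300,
                    missing_rate = 0.02, maf_range = c(0.2, 0.8), seed = seed)
  ds <- simulate_dataset(cfg)
  ## keep markers at which the alternate allele is observed, so the PED
  ## text dialect (which carries no allele metadata) can represent them
  keep <- colSums(ds$dosages, na.rm = TRUE) > 0
  subset_gen(ds, markers = which(keep))
}

test_that("PED text decoding follows the lexicographic alternate convention", {
  dir <- withr::local_tempdir()
  writeLines("1\tm1\t0\t100\n1\tm2\t0\t200\n1\tm3\t0\t300",
             file.path(dir, "t.map"))
  writeLines("F1 s1 0 0 0 -9 A A A G 0 0", file.path(dir, "t.ped"))
  ds <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  ## marker 2 shows {A, G}: alternate = G, "A G" = 1; marker 1 shows only A,
  ## so the single observed allele is the alternate and "A A" decodes as 2
  ## (the documented monomorphic convention); marker 3 is all missing
  expect_identical(as.integer(ds$dosages[1, ]), c(2L, 1L, NA))
  expect_identical(ds$samples$breed, "F1")
})

test_that("malformed PED input is rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), file.path(dir, "t.map"))
  # 2L + 5 fields instead of 2L + 6
  writeLines("F1 s1 0 0 -9 A A A G", file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map")),
               "expected")
  writeLines(c("F1 s1 0 0 0 -9 A A A G", "F1 s2 0 0 0 -9 A A"),
             file.path(dir, "t2.ped"))
  expect_error(read_plink_text(file.path(dir, "t2.ped"), file.path(dir, "t.map")),
               "ragged")
  writeLines(c("F1 s1 0 0 0 -9 A A A G", "F1 s1 0 0 0 -9 A A G G"),
             file.path(dir, "t3.ped"))
  expect_error(read_plink_text(file.path(dir, "t3.ped"), file.path(dir, "t.map")),
               "duplicated sample")
})

test_that("text and binary round trips recover the dosage matrix", {
  ds <- sim_fixture()
  dir <- withr::local_tempdir()
  write_plink_text(ds, file.path(dir, "x"))
  back <- read_plink_text(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  expect_identical(back$dosages, ds$dosages)
  expect_identical(back$markers, ds$markers)

  write_plink_binary(ds, file.path(dir, "y"))
  bin <- read_plink_binary(file.path(dir, "y.bed"), file.path(dir, "y.bim"),
                           file.path(dir, "y.fam"))
  expect_identical(bin$dosages, ds$dosages)
  ## text and binary exports of the same dataset decode identically
  expect_identical(bin$dosages, back$dosages)
})

test_that("BED 2-bit codes decode per the PLINK 1 specification", {
  dir <- withr::local_tempdir()
  writeLines("1\tm1\t0\t100\tB\tA", file.path(dir, "z.bim"))
  writeLines(sprintf("F1 s%d 0 0 0 -9", 1:4), file.path(dir, "z.fam"))
  con <- file(file.path(dir, "z.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE1)), con)  # 0b11_10_00_01
  close(con)
  ds <- read_plink_binary(file.path(dir, "z.bed"), file.path(dir, "z.bim"),
                          file.path(dir, "z.fam"))
  ## sample1 = 01 missing, sample2 = 00 hom alt, sample3 = 10 het,
  ## sample4 = 11 hom ref
  expect_identical(as.integer(ds$dosages[, 1]), c(NA, 2L, 1L, 0L))
})

test_that("corrupt BED files are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100\tB\tA", "1\tm2\t0\t200\tB\tA"),
             file.path(dir, "z.bim"))
  writeLines(sprintf("F1 s%d 0 0 0 -9", 1:5), file.path(dir, "z.fam"))
  con <- file(file.path(dir, "z.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00, 0x00)), con)  # needs 2x2 bytes
  close(con)
  expect_error(read_plink_binary(file.path(dir, "z.bed"), file.path(dir, "z.bim"),
                                 file.path(dir, "z.fam")), "truncated")
  con <- file(file.path(dir, "bad.bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), con)
  close(con)
  expect_error(read_plink_binary(file.path(dir, "bad.bed"), file.path(dir, "z.bim"),
                                 file.path(dir, "z.fam")), "magic")
})

test_that("call-rate thresholds are inclusive and order is pinned", {
  ## 100 markers; sample 2 has 5 missing (rate 0.95, kept at >= 0.95),
  ## sample 3 has 6 missing (0.94, removed)
  X <- matrix(0L, 3, 100)
  X[2, 1:5] <- NA
  X[3, 1:6] <- NA
  ds <- toy_ds(X)
  res <- qc_filter(ds, min_ind_call = 0.95, min_snp_call = 0)
  expect_setequal(res$dataset$samples$sample_id, c("s1", "s2"))
  rep <- res$report
  expect_identical(rep$removed[rep$stage == "individual_call_rate"], 1L)
})

test_that("marker call rate is computed on surviving samples", {
  ## toy 4 x 10: one marker with one missing call (rate 0.75) removed at 0.99
  X <- matrix(1L, 4, 10)
  X[1, 3] <- NA
  ds <- toy_ds(X)
  res <- qc_filter(ds, min_ind_call = 0, min_snp_call = 0.99)
  expect_identical(ncol(res$dataset$dosages), 9L)
  rep <- res$report
  expect_identical(rep$removed[rep$stage == "marker_call_rate"], 1L)
  expect_false("m3" %in% res$dataset$markers$marker_id)
})

test_that("qc with all thresholds zero and flags off is the identity", {
  ds <- sim_fixture(5)
  res <- qc_filter(ds, min_ind_call = 0, min_snp_call = 0,
                   autosomes_only = FALSE, drop_duplicates = FALSE)
  expect_identical(res$dataset$dosages, ds$dosages)
  expect_true(all(res$report$removed == 0))
})

test_that("qc drops duplicates and non-autosomes and is idempotent", {
  X <- matrix(0L, 3, 5)
  ds <- gen_dataset(X,
                    data.frame(chrom = c("1", "1", "1", "Z", "30"),
                               marker_id = paste0("m", 1:5),
                               pos_bp = c(10L, 10L, 20L, 5L, 5L)),
                    data.frame(sample_id = paste0("s", 1:3), breed = "B"))
  res <- qc_filter(ds, min_ind_call = 0, min_snp_call = 0, max_autosome = 28)
  expect_identical(res$dataset$markers$marker_id, c("m1", "m3"))
  again <- qc_filter(res$dataset, min_ind_call = 0, min_snp_call = 0)
  expect_identical(again$dataset$dosages, res$dataset$dosages)
  expect_true(all(again$report$removed == 0))
})

test_that("ld pruning removes one of a duplicated marker pair", {
  set.seed(1)
  x <- sample(0:2, 50, replace = TRUE)
  y <- sample(0:2, 50, replace = TRUE)
  ds <- toy_ds(cbind(x, x, y), pos = c(100, 200, 300))
  kept <- ld_prune(ds, window_snps = 3, step_snps = 1, r2_threshold = 0.2)
  expect_identical(sum(c("m1", "m2") %in% kept), 1L)
  ## equal MAF tie: the later map position is the victim
  expect_true("m1" %in% kept)
  expect_true("m3" %in% kept)
})

test_that("vacuous threshold retains everything; output preserves map order", {
  ds <- sim_fixture(9)
  kept <- ld_prune(ds, r2_threshold = 1.0)
  expect_identical(kept, ds$markers$marker_id)
  kept2 <- ld_prune(ds, window_snps = 10, step_snps = 2, r2_threshold = 0.05)
  expect_true(all(kept2 %in% ds$markers$marker_id))
  expect_identical(kept2, ds$markers$marker_id[ds$markers$marker_id %in% kept2])
})

test_that("independent markers are almost never pruned at threshold 0.2", {
  set.seed(42)
  retained <- vapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rbinom(100 * 200, 2, 0.4), nrow = 100)
    ds <- toy_ds(X, pos = seq_len(200) * 1000)
    length(ld_prune(ds)) / 200
  }, numeric(1))
  expect_true(all(retained >= 0.99))
})

test_that("monomorphic markers never cause pruning failures", {
  X <- cbind(rep(2L, 20), rep(2L, 20), rbinom(20, 2, 0.5))
  ds <- toy_ds(X, pos = c(10, 20, 30))
  kept <- ld_prune(ds, window_snps = 3, step_snps = 1, r2_threshold = 0.2)
  expect_identical(kept, c("m1", "m2", "m3"))
})
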