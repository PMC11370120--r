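vcf_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # 5 sites: clean SNP, low-QD SNP, InDel with FS between the SNP and
  # InDel thresholds, multiallelic, SNP with a missing genotype
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t100\tv1\tA\tG\t50\tPASS\tQD=20;MQ=60;FS=1.0\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tA\tC\t50\tPASS\tQD=1.5;MQ=60;FS=1.0\tGT\t0/0\t0/0\t0/1",
    "1\t300\tv3\tA\tATT\t50\tPASS\tQD=20;FS=150.0\tGT\t0/1\t0/1\t1/1",
    "2\t400\tv4\tC\tA,T\t50\tPASS\tQD=20\tGT\t0/1\t0/2\t0/0",
    "2\t500\tv5\tG\tT\t50\tPASS\tQD=20\tGT\t./.\t0/1\t1/1")
  path <- file.path(dir, "toy.vcf")
  writeLines(lines, path)
  path
}

test_that("VCF reading captures sites, annotations, dosages and missingness", {
  rec <- read_vcf(vcf_fixture())
  expect_s3_class(rec, "variant_records")
  expect_identical(nrow(rec$sites), 5L)
  expect_identical(rec$individual_ids, c("s1", "s2", "s3"))
  expect_identical(rec$sites$multiallelic, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(as.vector(rec$dosages[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(rec$dosages[5, 1]))      # ./. is missing
  expect_true(is.na(rec$dosages[4, 2]))      # allele index 2 not dosable
  expect_equal(rec$sites$QD, c(20, 1.5, 20, 20, 20))
  expect_true(is.na(rec$sites$MQ[3]))
})

test_that("hard filters apply per-ruleset thresholds and pass absent annotations", {
  rec <- read_vcf(vcf_fixture())
  snp <- hard_filter(rec, "SNP")
  expect_false("v2" %in% snp$sites$id)   # QD 1.5 < 2.0 removed
  expect_true("v1" %in% snp$sites$id)
  expect_true("v5" %in% snp$sites$id)    # absent FS/MQ pass

  ind <- hard_filter(rec, "InDel")
  expect_true("v3" %in% ind$sites$id)    # FS 150 < InDel threshold 200
  # same site under the SNP ruleset would fail (FS > 60)
  expect_false("v3" %in% hard_filter(rec, "SNP")$sites$id)
  expect_error(hard_filter(rec, "CNV"))
})

test_that("marker QC enforces the four rules and yields a complete matrix", {
  rec <- read_vcf(vcf_fixture())
  gm <- qc_filter(rec)
  # v4 multiallelic out, v5 missing genotype out; v1-v3 retained
  expect_setequal(gm$map$id, c("v1", "v2", "v3"))
  expect_false(anyNA(gm$dosages))
  expect_identical(gm$map$type, c("SNP", "SNP", "InDel"))

  # non-autosomal and long-InDel removal on a matrix input
  map <- toy_map(3)
  map$chrom <- c("1", "X", "1")
  map$ref[3] <- paste(rep("A", 61), collapse = "")   # 60-bp deletion
  map$alt[3] <- "A"
  gm2 <- genotype_matrix(matrix(1L, 4, 3), map)
  out <- qc_filter(gm2)
  expect_identical(out$map$id, map$id[1])

  # idempotence
  expect_identical(qc_filter(gm)$map$id, gm$map$id)
  expect_error(qc_filter(subset_genotypes(gm2, markers = 2)), "every marker")
})

test_that("empty VCF yields empty records with a warning", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t")), path)
  expect_warning(rec <- read_vcf(path), "no variant")
  expect_identical(nrow(rec$sites), 0L)
})

test_that("marker classification splits alleles into SNPs and InDels", {
  expect_identical(classify_marker("A", "G"), "SNP")
  expect_identical(classify_marker("A", "ATT"), "InDel")
  expect_identical(classify_marker("ACGT", "A"), "InDel")
  expect_identical(classify_marker(c("A", "AC"), c("T", "A")),
                   c("SNP", "InDel"))
  expect_error(classify_marker("", "A"), "empty")
})

test_that("dosage r2 matches direct Pearson computation", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1.0)  # perfect negative
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  a <- c(0, 1, 2, 1, 0, 2); b <- c(1, 1, 2, 0, 0, 2)
  expect_equal(ld_r2(a, b), stats::cor(a, b)^2)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero-variance")
  expect_identical(r, 0)
})

test_that("LD pruning removes within-window linked markers only", {
  g <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  col <- g[, 1]
  # three identical columns within one window: exactly one survives
  gm <- toy_gm(cbind(col, col, col), step = 10000L)
  expect_identical(ncol(ld_prune(gm)$dosages), 1L)

  # identical columns 600 kb apart: both retained
  gm2 <- toy_gm(cbind(col, col), step = 600000L)
  expect_identical(ncol(ld_prune(gm2)$dosages), 2L)

  # unsorted map rejected
  gm3 <- gm
  gm3$map$pos <- rev(gm3$map$pos)
  expect_error(ld_prune(gm3), "sorted")
})

test_that("pruning post-condition holds under exhaustive all-pairs verification", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- 50
    g <- matrix(sample(0:2, 30 * m, replace = TRUE, prob = c(.3, .4, .3)),
                30, m)
    # plant correlated duplicates to give the pruner real work
    for (j in seq(2, m, by = 7)) g[, j] <- g[, j - 1]
    gm <- toy_gm(g, chrom = rep(c("1", "2"), each = m / 2), step = 120000L)
    pruned <- ld_prune(gm)
    d <- pruned$dosages; map <- pruned$map
    for (a in seq_len(ncol(d))) for (b in seq_len(ncol(d))) {
      if (a < b && map$chrom[a] == map$chrom[b] &&
          abs(map$pos[b] - map$pos[a]) <= 500000L) {
        expect_lt(suppressWarnings(ld_r2(d[, a], d[, b])), 0.2)
      }
    }
  }
})

test_that("SI merge concatenates, sorts and re-prunes", {
  set.seed(3)
  base <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  snp <- toy_gm(base, step = 50000L)
  ind_map <- toy_map(2, start = 1500L, step = 50000L, ref = "A", alt = "AT")
  ind_map$id <- c("i1", "i2")
  ind <- genotype_matrix(cbind(sample(0:2, 20, TRUE), base[, 1]), ind_map)
  rownames(ind$dosages) <- rownames(snp$dosages)

  merged <- merge_si(snp, ind)
  # the InDel duplicating SNP column 1 within 1 kb is pruned away
  expect_lte(ncol(merged$dosages), 4L)
  expect_true(all(diff(order(breedkit:::chrom_key(merged$map$chrom),
                             merged$map$pos)) == 1))
  # disjoint unlinked sets (every pair beyond the window): union retained
  snp_far <- toy_gm(base, step = 600000L)
  ind_far <- ind
  ind_far$map$pos <- ind_far$map$pos + 10000000L
  rownames(ind_far$dosages) <- rownames(snp_far$dosages)
  m2 <- merge_si(snp_far, ind_far)
  expect_identical(ncol(m2$dosages), 5L)

  bad <- ind
  rownames(bad$dosages) <- paste0("x", seq_len(20))
  expect_error(merge_si(snp, bad), "same individuals")
})

test_that("VCF and dosage-matrix writers round-trip through the readers", {
  ds <- simulate_dataset(sim_config(n_breeds = 3, n_per_breed = 4,
                                    n_markers = 30, admixed_fraction = 0,
                                    seed = 13))
  gm <- ds$genotypes
  dir <- withr::local_tempdir()

  vcf <- file.path(dir, "sim.vcf")
  write_vcf(gm, vcf)
  back <- qc_filter(read_vcf(vcf))
  expect_identical(unname(back$dosages[rownames(gm$dosages),
                                       gm$map$id]),
                   unname(gm$dosages))
  expect_identical(sort(back$map$type), sort(gm$map$type))

  stem <- file.path(dir, "sim")
  write_dosage_matrix(gm, stem)
  back2 <- read_dosage_matrix(stem)
  expect_identical(unname(back2$dosages), unname(gm$dosages))
  expect_identical(back2$labels, gm$labels)
})
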