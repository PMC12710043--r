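phi_table <- function() {
  data.frame(plant_id = rep("p1", 4), genotype_id = rep("g1", 4),
             timepoint = rep(1, 4), angle_index = 1:4,
             Phi = c(10, 20, 30, 40))
}

test_that("summary metrics reduce deviation tables as stated", {
  tb <- phi_table()
  out <- summary_metrics(tb, metrics = c("median_all", "mean_all", "max_all"))
  expect_equal(out$median_all, 25)
  expect_equal(out$mean_all, 25)
  expect_equal(out$max_all, 40)
  zero <- tb; zero$Phi <- 0
  z <- summary_metrics(zero)
  expect_true(all(unlist(z[, -(1:2)]) == 0))
  one <- tb[2, , drop = FALSE]
  s1 <- summary_metrics(one, metrics = "median_all")
  expect_equal(s1$median_all, 20)
  expect_error(summary_metrics(tb, metrics = character(0)), "metric")
  expect_error(summary_metrics(tb, metrics = "nope"), "unknown")
})

test_that("summary metrics restrict to the lower four angles", {
  tb <- rbind(phi_table(),
              data.frame(plant_id = "p1", genotype_id = "g1", timepoint = 1,
                         angle_index = 5, Phi = 170))
  out <- summary_metrics(tb, metrics = "max_all")
  expect_equal(out$max_all, 40)
})

test_that("IQR outlier flags follow the 1.5 x IQR fences", {
  v <- 1:100
  expect_false(iqr_outlier_flag(c(v, 50))[101])
  expect_true(iqr_outlier_flag(c(v, 10000))[101])
  const <- rep(5, 10)
  expect_false(any(iqr_outlier_flag(const)))
  expect_true(iqr_outlier_flag(c(const, 5.1))[11])
  expect_error(iqr_outlier_flag(1:3), "four")
})

test_that("broad-sense heritability follows the variance-component formula", {
  expect_equal(broad_sense_H(1, 1, n = 2), 1 / 1.5)
  expect_equal(broad_sense_H(0, 1), 0)
  expect_equal(broad_sense_H(1, 0), 1)
  # bounds and monotonicity in n
  set.seed(12)
  for (i in 1:50) {
    g <- runif(1, 0, 5); r <- runif(1, 0, 5)
    h2 <- broad_sense_H(g, r, 2); h4 <- broad_sense_H(g, r, 4)
    expect_gte(h2, 0); expect_lte(h2, 1)
    expect_gte(h4, h2)
  }
  expect_error(broad_sense_H(-1, 1), ">= 0")
})

test_that("heritability estimation recovers simulated truth", {
  ests <- vapply(1:20, function(s) {
    pop <- make_population(200, reps = 2, h2_target = h2_for_H(0.5), seed = s)
    heritability(pop$phenotypes$value, pop$phenotypes$genotype_id)$H
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.05)
  # pure-noise phenotype stays near zero; the panel must be large enough
  # that the sampling noise of the variance component stays below 0.1
  nulls <- vapply(1:20, function(s) {
    pop <- make_population(800, reps = 2, h2_target = 0, seed = s)
    heritability(pop$phenotypes$value, pop$phenotypes$genotype_id,
                 method = "mom")$H
  }, numeric(1))
  expect_lt(mean(nulls), 0.1)
  expect_gt(mean(nulls < 0.1), 0.9)
})

test_that("REML and method-of-moments agree on balanced data", {
  pop <- make_population(150, reps = 2, h2_target = h2_for_H(0.4), seed = 2)
  a <- heritability(pop$phenotypes$value, pop$phenotypes$genotype_id)
  b <- heritability(pop$phenotypes$value, pop$phenotypes$genotype_id,
                    method = "mom")
  expect_equal(a$H, b$H, tolerance = 0.02)
})

test_that("heritability guards unidentifiable designs and caps replicates", {
  expect_error(heritability(rnorm(5), letters[1:5]), "unreplicated")
  # one genotype with 8 replicates is capped at 2, seeded
  set.seed(1)
  vals <- c(rnorm(8, 5), rnorm(2, 0), rnorm(2, 1))
  gen <- c(rep("big", 8), rep("a", 2), rep("b", 2))
  f1 <- heritability(vals, gen, cap_replicates = 2, seed = 9)
  f2 <- heritability(vals, gen, cap_replicates = 2, seed = 9)
  expect_equal(f1$n_obs, 6)
  expect_identical(f1$H, f2$H)
})

test_that("marker QC applies the published filter battery", {
  dosage <- rbind(
    c(0, 2, 2, 0, 2, 0, 0, 2, 0, 2),          # fine: no hets, MAF 0.5
    c(0, 1, 1, 1, 0, 0, 0, 0, 0, 2),         # 3 het of 10 -> excluded
    c(2, rep(0, 9)),                          # MAF 0.10 -> kept
    c(NA, NA, NA, 0, 1, 2, 0, 1, 2, 0),      # 30% missing -> excluded
    rep(0, 10))                               # monomorphic, MAF 0 -> excluded
  info <- data.frame(id = paste0("m", 1:5),
                     is_biallelic = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                     is_indel = FALSE)
  qc <- marker_qc(list(dosage = dosage, info = info))
  expect_equal(unname(qc$keep), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(qc$exclusions["heterozygosity"]), 1L)
  expect_equal(unname(qc$exclusions["missing"]), 1L)
  expect_equal(unname(qc$exclusions["maf"]), 1L)
  # multiallelic and indel markers are excluded outright
  info2 <- info
  info2$is_biallelic[1] <- FALSE
  info2$is_indel[3] <- TRUE
  expect_warning(qc2 <- marker_qc(list(dosage = dosage, info = info2)),
                 "no markers")
  expect_false(qc2$keep[1])
  expect_false(qc2$keep[3])
  expect_equal(unname(qc2$exclusions["not_biallelic"]), 1L)
  expect_equal(unname(qc2$exclusions["indel"]), 1L)
})

test_that("QC filters are order-independent in the selected set", {
  set.seed(14)
  pop <- make_population(50, reps = 1, n_markers = 200, seed = 14)
  dosage <- pop$genotypes
  dosage[sample(length(dosage), 2000)] <- NA
  keep_joint <- marker_qc(dosage)$keep
  # applying single filters in any order intersects to the same set
  m1 <- marker_qc(dosage, max_missing = 0.30, max_het = 1.01, min_maf = 0)$keep
  m2 <- marker_qc(dosage, max_missing = 1.01, max_het = 0.10, min_maf = 0)$keep
  m3 <- marker_qc(dosage, max_missing = 1.01, max_het = 1.01,
                  min_maf = 0.05)$keep
  expect_equal(keep_joint, m1 & m2 & m3)
})

test_that("significance thresholds reproduce the worked arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(iteration_threshold(0.05, me = 1, m = 1), 0.05)
  expect_equal(iteration_threshold(0.05, me = 1, m = 2), 0.10)
  expect_error(bonferroni_threshold(0.05, 0), "> 0")
  expect_error(iteration_threshold(0.05, me = 3, m = 2), "me <= m")
})

test_that("the scan flags a perfect signal and controls type-I error", {
  pop <- make_population(100, reps = 1, n_markers = 100, seed = 6)
  y <- 2 * pop$genotypes[17, ]
  p <- suppressWarnings(scan_markers(pop$genotypes, y))
  expect_lt(p[17], 1e-60)
  # permutation null: rejection rate ~ alpha
  rates <- vapply(1:30, function(s) {
    pop <- make_population(120, reps = 1, n_markers = 400, seed = 100 + s)
    set.seed(s)
    y <- rnorm(120)
    p <- scan_markers(pop$genotypes, y)
    mean(p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
  # constant phenotype
  expect_warning(p0 <- scan_markers(pop$genotypes, rep(1, 100)), "constant")
  expect_true(all(p0 == 1))
})

test_that("scan handles missing dosages and covariates", {
  pop <- make_population(80, reps = 1, n_markers = 50, seed = 8)
  g <- pop$genotypes
  g[3, 1:10] <- NA
  set.seed(2)
  y <- as.numeric(g[5, ]) + rnorm(80, 0, 0.5)
  p <- scan_markers(g, y)
  expect_false(is.na(p[3]))
  expect_lt(p[5], 1e-10)
  pc <- scan_markers(g, y, n_pc = 3)
  expect_lt(pc[5], 1e-8)
})

test_that("RMIP counts iterations exactly and respects marker order", {
  pop <- make_population(60, reps = 2, n_markers = 20, seed = 4)
  always <- function(geno, y, ...) c(0, rep(1, nrow(geno) - 1))
  tb <- rmip(pop$genotypes, pop$phenotypes, n_iter = 25, engine = always)
  expect_equal(tb$rmip[1], 1)
  expect_true(all(tb$rmip[-1] == 0))
  expect_true(tb$called[1])
  never <- function(geno, y, ...) rep(1, nrow(geno))
  tb0 <- rmip(pop$genotypes, pop$phenotypes, n_iter = 25, engine = never)
  expect_true(all(tb0$rmip == 0))
  # RMIP values are multiples of 1/n_iter
  expect_true(all(abs(tb$rmip * 25 - round(tb$rmip * 25)) < 1e-12))
  # permuting markers permutes the table identically
  set.seed(3)
  perm <- sample(20)
  tbp <- rmip(pop$genotypes[perm, ], pop$phenotypes, n_iter = 10, seed = 2)
  tbo <- rmip(pop$genotypes, pop$phenotypes, n_iter = 10, seed = 2)
  expect_equal(tbp$rmip, tbo$rmip[perm])
})

test_that("RMIP masking is seeded and guards tiny panels", {
  pop <- make_population(30, reps = 1, n_markers = 10, seed = 4)
  a <- rmip(pop$genotypes, pop$phenotypes, n_iter = 5, seed = 7)
  b <- rmip(pop$genotypes, pop$phenotypes, n_iter = 5, seed = 7)
  expect_identical(a$hits, b$hits)
  tiny <- make_population(10, reps = 1, n_markers = 5, seed = 1)
  expect_error(rmip(tiny$genotypes, tiny$phenotypes, mask_frac = 0.5),
               "10 records")
})

test_that("LD r2 matches correlation identities", {
  g <- rbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2), c(2, 1, 0, 2, 1, 0))
  expect_equal(ld_r2(g, 1, 2), 1)
  expect_equal(ld_r2(g, 1, 3), 1) # complement coding leaves r2 unchanged
  gm <- rbind(g, rep(1, 6))
  expect_true(is.na(ld_r2(gm, 1, 4)))
  # independent markers have r2 near 1/N
  pop <- make_population(500, reps = 1, n_markers = 40, seed = 9)
  r2s <- vapply(2:40, function(j) ld_r2(pop$genotypes, 1, j), numeric(1))
  expect_lt(max(r2s), 0.05)
})

test_that("VCF round trip preserves dosages and flags", {
  pop <- make_population(12, reps = 1, n_markers = 8, seed = 2)
  g <- pop$genotypes
  g[2, 3] <- NA
  path <- tempfile(fileext = ".vcf")
  write_vcf_dosage(g, path)
  back <- read_vcf_dosage(path)
  expect_equal(unname(back$dosage), unname(g))
  expect_true(all(back$info$is_biallelic))
  expect_false(any(back$info$is_indel))
  # multiallelic and indel records are flagged for QC
  info <- data.frame(chrom = rep("1", 8), pos = 1:8 * 10,
                     id = paste0("v", 1:8),
                     ref = c("A", "AT", rep("A", 6)),
                     alt = c("T,G", "T", rep("C", 6)))
  write_vcf_dosage(g, path, info = info)
  back2 <- read_vcf_dosage(path)
  expect_false(back2$info$is_biallelic[1])
  expect_true(back2$info$is_indel[2])
  qc <- marker_qc(back2, min_maf = 0)
  expect_false(qc$keep[1])
  expect_false(qc$keep[2])
})
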