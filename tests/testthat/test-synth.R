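fam1 <- function(n) data.frame(mother = "F001", father = "F002", n_offspring = n,
                               stringsAsFactors = FALSE)

test_that("config validation rejects bad worlds", {
  expect_error(sim_config(0, NULL, 10), "founder")
  expect_error(sim_config(2, NULL, 0), "SNP")
  expect_error(sim_config(2, data.frame(mother = "F009", father = "F001",
                                        n_offspring = 2), 10), "parents")
  expect_error(sim_config(2, NULL, 10, founder_maf_range = c(0, 0.5)))
  expect_error(probe_effect("s", paralog_signal_fraction = 0.6))
})

test_that("recombination follows Haldane's map function", {
  fams <- data.frame(mother = sprintf("F%03d", seq(1, 39, 2)),
                     father = sprintf("F%03d", seq(2, 40, 2)),
                     n_offspring = 150, stringsAsFactors = FALSE)
  cfg <- sim_config(n_founders = 40, families = fams, n_snps = 2,
                    n_linkage_groups = 1, map_length_cM = 10,
                    founder_maf_range = c(0.5, 0.5), seed = 11)
  tr <- simulate_genotypes(cfg)
  d <- diff(tr$map$cM)
  r_exp <- (1 - exp(-2 * d / 100)) / 2
  # gamete provenance is identifiable from the truth haplotypes whenever
  # the parent is heterozygous at both SNPs
  n_rec <- 0L; n_inf <- 0L
  for (i in seq_len(nrow(fams))) {
    kids <- grep(sprintf("^X%02d_", i), colnames(tr$hap1), value = TRUE)
    for (side in 1:2) {
      parent <- if (side == 1) fams$mother[i] else fams$father[i]
      gam <- if (side == 1) tr$hap1[, kids] else tr$hap2[, kids]
      h1 <- tr$hap1[, parent]; h2 <- tr$hap2[, parent]
      if (h1[1] == h2[1] || h1[2] == h2[2]) next
      src <- gam == h1  # TRUE where the allele came from hap1
      rec <- xor(src[1, ], src[2, ])
      n_rec <- n_rec + sum(rec); n_inf <- n_inf + length(rec)
    }
  }
  expect_gt(n_inf, 1000)
  se <- sqrt(r_exp * (1 - r_exp) / n_inf)
  expect_lt(abs(n_rec / n_inf - r_exp), 3 * se)
})

test_that("zero map length means unrecombined parental haplotypes", {
  cfg <- sim_config(n_founders = 2, families = fam1(200), n_snps = 30,
                    n_linkage_groups = 1, map_length_cM = 0, seed = 4)
  tr <- simulate_genotypes(cfg)
  kids <- grep("^X", colnames(tr$hap1), value = TRUE)
  for (k in kids[1:20]) {
    g <- tr$hap1[, k]
    expect_true(identical(g, tr$hap1[, "F001"]) || identical(g, tr$hap2[, "F001"]))
  }
})

test_that("null fixation and Mendelian consistency by construction", {
  eff <- list(s = probe_effect("SNP00001", null_allele_frequency = 1))
  names(eff) <- "SNP00001"
  cfg <- sim_config(n_founders = 6, families = fam1(30), n_snps = 20,
                    effects = eff, seed = 5)
  tr <- simulate_genotypes(cfg)
  expect_true(all(tr$genotypes["SNP00001", ] == "NN*"))

  # every offspring x SNP is consistent with its true parents (oracle)
  g <- unclass(tr$genotypes)
  kids <- grep("^X", colnames(g), value = TRUE)
  bad <- 0L
  for (k in kids) for (i in seq_len(nrow(g)))
    if (oracle_trio_bad(g[i, "F001"], g[i, "F002"], g[i, k])) bad <- bad + 1L
  expect_identical(bad, 0L)
})

test_that("noise-free intensities hit the cluster centers exactly", {
  pf <- platform_model("infinium", theta_sd = 0, r_sd = 0)
  cfg <- sim_config(n_founders = 20, families = NULL, n_snps = 10, seed = 6)
  tr <- simulate_genotypes(cfg)
  ii <- simulate_intensities(tr, pf, effects = list(), seed = 7, noise = FALSE)
  g <- unclass(tr$genotypes)
  th <- stats::setNames(ii$theta, paste(ii$snp, ii$individual))
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    key <- paste(rownames(g)[i], colnames(g)[j])
    expected <- switch(g[i, j], AA = 0.05, AB = 0.5, BB = 0.95, NA)
    if (!is.na(expected)) expect_equal(unname(th[key]), expected, tolerance = 1e-12)
  }
})

test_that("double-null individuals collapse to near-zero R", {
  eff <- list(probe_effect("SNP00001", null_allele_frequency = 0.5))
  names(eff) <- "SNP00001"
  cfg <- sim_config(n_founders = 60, families = NULL, n_snps = 5,
                    effects = eff, seed = 8)
  tr <- simulate_genotypes(cfg)
  ii <- simulate_intensities(tr, cfg$platforms$infinium, eff, seed = 9, noise = FALSE)
  sel <- ii$snp == "SNP00001"
  r <- stats::setNames(ii$r[sel], ii$individual[sel])
  nn <- colnames(tr$hap1)[tr$genotypes["SNP00001", ] == "NN*"]
  expect_gt(length(nn), 3)
  # oracle = direct evaluation of the signal model: an NN individual emits
  # 2 * null_r_factor/2 per channel -> R = null_r_factor * r_mean
  expect_true(all(r[nn] < 0.1 * stats::median(r)))
  expect_equal(unname(r[nn]), rep(0.05, length(nn)), tolerance = 1e-12)
})

test_that("paralog signal pulls the BB cluster toward the emitting allele", {
  eff <- list(probe_effect("SNP00001", paralog_signal_fraction = 0.25,
                           paralog_allele = "A"))
  names(eff) <- "SNP00001"
  pf <- platform_model("axiom", paralog_sensitivity = 1)
  cfg <- sim_config(n_founders = 80, families = NULL, n_snps = 3,
                    founder_maf_range = c(0.5, 0.5), effects = eff, seed = 10)
  tr <- simulate_genotypes(cfg)
  ii <- simulate_intensities(tr, pf, eff, seed = 11, noise = FALSE)
  sel <- ii$snp == "SNP00001"
  th <- stats::setNames(ii$theta[sel], ii$individual[sel])
  bb <- colnames(tr$hap1)[tr$genotypes["SNP00001", ] == "BB"]
  expect_gt(length(bb), 5)
  expect_true(all(th[bb] < 0.95))
})

test_that("noise-free calling reproduces the truth exactly", {
  pf <- platform_model("infinium", theta_sd = 0, r_sd = 0)
  cfg <- sim_config(n_founders = 12, families = fam1(15), n_snps = 25,
                    call_error_rate = 0, seed = 12)
  tr <- simulate_genotypes(cfg)
  ii <- simulate_intensities(tr, pf, list(), seed = 13)
  cc <- call_genotypes(ii, pf)
  expect_identical(unclass(cc)[, ], unclass(tr$genotypes)[, ])
})

test_that("monomorphic SNP yields a single component, all calls equal", {
  pf <- platform_model("infinium")
  theta <- rep(0.05, 60) + rnorm(60, 0, 0.01)
  ii <- data.frame(snp = "s1", individual = sprintf("I%02d", 1:60),
                   theta = pmin(1, pmax(0, theta)), r = rep(1, 60))
  cc <- call_genotypes(ii, pf)
  expect_true(all(unclass(cc)[1, ] == "AA"))
})

test_that("a shifted het sub-cluster is miscalled into the homozygote class", {
  # the class-C phenotype: brute-force nearest-center assignment is the
  # oracle for where the displaced component must land
  pf <- platform_model("axiom")
  set.seed(14)
  theta <- c(rnorm(40, 0.05, 0.02), rnorm(40, 0.175, 0.02), rnorm(20, 0.95, 0.02))
  ii <- data.frame(snp = "s1",
                   individual = sprintf("I%03d", seq_along(theta)),
                   theta = pmin(1, pmax(0, theta)), r = 1)
  cc <- call_genotypes(ii, pf)
  shifted <- sprintf("I%03d", 41:80)
  # oracle: component mean 0.175 is nearer the AA center (0.05) than AB (0.5)
  expect_true(mean(unclass(cc)[1, shifted] == "AA", na.rm = TRUE) > 0.9)
})

test_that("same seed gives byte-identical outputs", {
  cfg <- sim_config(n_founders = 8, families = fam1(10), n_snps = 15, seed = 15)
  t1 <- simulate_genotypes(cfg); t2 <- simulate_genotypes(cfg)
  expect_identical(t1, t2)
  i1 <- simulate_intensities(t1, cfg$platforms$axiom, list(), seed = 16)
  i2 <- simulate_intensities(t2, cfg$platforms$axiom, list(), seed = 16)
  expect_identical(i1, i2)
  expect_identical(call_genotypes(i1, cfg$platforms$axiom),
                   call_genotypes(i2, cfg$platforms$axiom))
})

test_that("retention profile is monotone and saturates beyond the probe", {
  pf <- platform_model("axiom")
  d <- 1:40
  r <- retention(d, pf)
  expect_true(all(diff(r) >= 0))
  expect_identical(r[d > pf$probe_len], rep(1, sum(d > pf$probe_len)))
  # 35-mer chemistry is the more 3'-sensitive one
  expect_lt(retention(3, platform_model("axiom")),
            retention(3, platform_model("infinium")))
})
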