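codes_vis <- c("AA", "AB", "BB")
codes_all <- c("AA", "AB", "BB", "AN", "BN", "NN*")

test_that("duo and trio flags match the gamete-enumeration oracle", {
  for (p in c(codes_all, NA)) for (o in c(codes_all, NA)) {
    expect_identical(duo_inconsistent(p, o), oracle_duo_bad(p, o),
                     info = paste("duo", p, o))
  }
  for (m in c(codes_all, NA)) for (f in c(codes_all, NA)) for (o in c(codes_all, NA)) {
    expect_identical(trio_inconsistent(m, f, o), oracle_trio_bad(m, f, o),
                     info = paste("trio", m, f, o))
  }
})

test_that("specific trio cases behave as documented", {
  expect_true(trio_inconsistent("AA", "AA", "AB"))
  expect_false(duo_inconsistent("AA", "AB"))
  for (o in codes_vis) expect_false(trio_inconsistent("AB", "AB", o))
  expect_false(trio_inconsistent("AA", "BB", "AB"))
  expect_true(trio_inconsistent("AA", "BB", "AA"))
  expect_false(duo_inconsistent(NA, "BB"))
})

test_that("scan matches a brute-force recount after planted errors", {
  cfg <- sim_config(n_founders = 8,
                    families = data.frame(mother = c("F001", "F003"),
                                          father = c("F002", "F004"),
                                          n_offspring = 40),
                    n_snps = 60, call_error_rate = 0, seed = 21)
  tr <- simulate_genotypes(cfg)
  clean <- scan_mendelian_errors(tr$genotypes, tr$pedigree)
  expect_identical(nrow(clean$errors), 0L)

  noisy <- perturb_calls(tr$genotypes, 0.01, seed = 22)
  scan <- scan_mendelian_errors(noisy, tr$pedigree)
  # independent recount with the oracle, looping duos/trios explicitly
  g <- unclass(noisy)
  ped <- tr$pedigree
  expected <- stats::setNames(integer(nrow(g)), rownames(g))
  for (r in seq_len(nrow(ped))) {
    mo <- ped$mother[r]; fa <- ped$father[r]; kid <- ped$id[r]
    if (is.na(mo) && is.na(fa)) next
    for (i in seq_len(nrow(g)))
      if (oracle_trio_bad(if (is.na(mo)) NA else g[i, mo],
                          if (is.na(fa)) NA else g[i, fa], g[i, kid]))
        expected[i] <- expected[i] + 1L
  }
  expect_identical(scan$per_snp$n_inconsistent, unname(expected))
  expect_gt(sum(expected), 0L)
})

test_that("consistent-error detector flags singleton flips only", {
  # parent P heterozygous at every SNP, other parent Q homozygous AA:
  # offspring AB => P transmitted B, offspring AA => A. Five clean
  # offspring fix P's phase; the sixth carries the pattern under test.
  map <- data.frame(snp = sprintf("s%d", 1:7), lg = "LG1",
                    cM = seq(0, 6), bp = NA_integer_)
  mk <- function(states6) {
    kid_calls <- function(states) ifelse(states == 1, "AB", "AA")
    cm <- cbind(P = rep("AB", 7), Q = rep("AA", 7),
                K1 = kid_calls(rep(0, 7)), K2 = kid_calls(rep(0, 7)),
                K3 = kid_calls(rep(0, 7)), K4 = kid_calls(rep(0, 7)),
                K5 = kid_calls(rep(0, 7)), K6 = kid_calls(states6))
    rownames(cm) <- map$snp
    call_matrix(cm, "merged")
  }
  ped <- pedigree(data.frame(id = c("P", "Q", sprintf("K%d", 1:6)),
                             mother = c(NA, NA, rep("P", 6)),
                             father = c(NA, NA, rep("Q", 6))))
  hit <- detect_consistent_errors(mk(c(0, 0, 0, 1, 0, 0, 0)), ped, map, k_flank = 3)
  expect_identical(hit$snp, "s4")
  expect_identical(hit$parent, "P")
  expect_identical(hit$child, "K6")
  # a genuine single crossover is not a singleton
  none <- detect_consistent_errors(mk(c(0, 0, 0, 1, 1, 1, 1)), ped, map, k_flank = 3)
  expect_identical(nrow(none), 0L)
  # boundary safety: a flip without k_flank informative markers on both
  # sides is never flagged
  edge <- detect_consistent_errors(mk(c(1, 0, 0, 0, 0, 0, 0)), ped, map, k_flank = 3)
  expect_identical(nrow(edge), 0L)
  # window rule: flanks outside w_cM do not support a call
  wide_map <- transform(map, cM = c(0, 20, 40, 60, 80, 100, 120))
  wide <- detect_consistent_errors(mk(c(0, 0, 0, 1, 0, 0, 0)), ped, wide_map,
                                   k_flank = 3, w_cM = 10)
  expect_identical(nrow(wide), 0L)
  # too few offspring to phase: nothing is ever flagged
  solo_ped <- pedigree(data.frame(id = c("P", "Q", "K6"),
                                  mother = c(NA, NA, "P"),
                                  father = c(NA, NA, "Q")))
  solo <- detect_consistent_errors(mk(c(0, 0, 0, 1, 0, 0, 0))[, c("P", "Q", "K6")],
                                   solo_ped, map, k_flank = 3)
  expect_identical(nrow(solo), 0L)
})

test_that("planted miscall is flagged while true crossovers are not", {
  cfg <- sim_config(n_founders = 2,
                    families = data.frame(mother = "F001", father = "F002",
                                          n_offspring = 60),
                    n_snps = 120, n_linkage_groups = 1, map_length_cM = 60,
                    founder_maf_range = c(0.5, 0.5), call_error_rate = 0,
                    seed = 23)
  tr <- simulate_genotypes(cfg)
  base <- detect_consistent_errors(tr$genotypes, tr$pedigree, tr$map)
  # single crossovers are never flagged; the only background comes from
  # genuine close double-crossovers, which a no-interference (Haldane)
  # meiosis produces at a low rate and which are by definition what the
  # statistic reports - so the background must be small, not zero
  expect_lt(nrow(base), 0.002 * 120 * 60)
  m <- unclass(tr$genotypes)
  # flip one offspring call at an interior SNP with an unambiguous
  # transmitted-allele signature (mother heterozygous, offspring homozygous)
  kid <- grep("^X", colnames(m), value = TRUE)[1]
  cand <- which(m[, "F001"] == "AB" & m[, kid] %in% c("AA", "BB"))
  target <- rownames(m)[cand[cand > 40 & cand < 80][1]]
  m[target, kid] <- if (m[target, kid] == "AA") "BB" else "AA"
  flagged <- detect_consistent_errors(call_matrix(m, "merged"), tr$pedigree, tr$map)
  expect_true(target %in% flagged$snp)
})

test_that("null inference recodes the opposing-homozygote duo family", {
  # hand-built segregating null (AN x BN family): the carriers sit at
  # roughly half the R of their called cluster, the double null near zero
  ids <- c("P1", "P2", "K1", "K2", "K3",
           sprintf("A%d", 1:6), sprintf("B%d", 1:6), sprintf("H%d", 1:6))
  s1 <- c("AA", "BB", "BB", "AA", NA,            # AN, BN, BN, AN, NN*
          rep("AA", 6), rep("BB", 6), rep("AB", 6))
  s2 <- rep("AB", length(ids))                             # artifact-free
  mm <- rbind(snpN = s1, snpC = s2)
  colnames(mm) <- ids
  cm <- call_matrix(mm, "infinium")
  r1 <- c(0.55, 0.55, 0.55, 0.55, 0.04, rep(1, 18))
  intens <- rbind(
    data.frame(snp = "snpN", individual = ids, theta = 0.5, r = r1),
    data.frame(snp = "snpC", individual = ids, theta = 0.5, r = 1))
  ped <- pedigree(data.frame(id = ids,
                             mother = c(NA, NA, "P1", "P1", "P1", rep(NA, 18)),
                             father = c(NA, NA, "P2", "P2", "P2", rep(NA, 18))))
  res <- infer_null_alleles(cm, intens, ped)
  # artifact-free SNP untouched
  expect_true(all(res$null_calls$snp == "snpN"))
  m <- unclass(res$matrix)
  expect_identical(unname(m["snpN", c("P1", "P2", "K1", "K2", "K3")]),
                   c("AN", "BN", "BN", "AN", "NN*"))
  # recoding eliminates the duo errors entirely
  before <- nrow(scan_mendelian_errors(cm, ped)$errors)
  after <- nrow(scan_mendelian_errors(res$matrix, ped)$errors)
  expect_gt(before, 0L)
  expect_identical(after, 0L)
  # recoded calls stay consistent with the visible call
  vis_ok <- vapply(seq_len(nrow(res$null_calls)), function(k) {
    old <- unclass(cm)[res$null_calls$snp[k], res$null_calls$individual[k]]
    new <- res$null_calls$recoded[k]
    (new == "AN" && identical(old, "AA")) || (new == "BN" && identical(old, "BB")) ||
      (new == "NN*" && (is.na(old) || old %in% c("AA", "BB")))
  }, logical(1))
  expect_true(all(vis_ok))

  # no intensity: pedigree-only evidence, flagged low confidence
  res0 <- infer_null_alleles(cm, NULL, ped)
  expect_identical(attr(res0$null_calls, "confidence"), "low (pedigree-only evidence)")
})
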