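mk_profile <- function(n_classes = 3L, n_modes = 3L, cluster_space = 0.9,
                       separation = 0.3, width_max = 0.08,
                       between_fraction = 0, missing_fraction = 0.01,
                       low_r_fraction = 0) {
  data.frame(n = 100L, n_classes = n_classes, n_modes = n_modes,
             cluster_space = cluster_space, separation = separation,
             width_max = width_max, between_fraction = between_fraction,
             missing_fraction = missing_fraction,
             low_r_fraction = low_r_fraction, stringsAsFactors = FALSE)
}

inf_ev <- function(profile = mk_profile(), n_inconsistent = 0L,
                   null_carriers = 0L, call_shares = c(0.3, 0.5, 0.2))
  list(profile = profile, n_inconsistent = n_inconsistent,
       null_carriers = null_carriers, call_shares = call_shares)

test_that("first-platform ladder hits each exclusion category", {
  expect_identical(classify_infinium(inf_ev())$status, "included")
  expect_identical(classify_infinium(inf_ev(call_shares = c(0.995, 0.005)))$category,
                   "Monomorphic")
  expect_identical(classify_infinium(inf_ev(mk_profile(separation = 0.01)))$category,
                   "Poor clustering")
  expect_identical(classify_infinium(inf_ev(null_carriers = 10L))$category,
                   "Overlapping null and homozygous clusters")
  expect_identical(classify_infinium(inf_ev(mk_profile(n_modes = 4L),
                                            n_inconsistent = 2L))$category,
                   "Extra cluster(s) causing illogical segregation")
  expect_identical(classify_infinium(inf_ev(n_inconsistent = 3L))$category,
                   "Illogical segregation")
  # ladder order: monomorphic wins over everything downstream
  expect_identical(classify_infinium(inf_ev(mk_profile(separation = 0.01),
                                            call_shares = 1))$category,
                   "Monomorphic")
})

ax_ev <- function(profile = mk_profile(), in_axiom = TRUE, n_classes_first = 3L,
                  dup_discord = 0L, subcluster = NULL, between_individuals = NULL,
                  null_carriers = 0L, null_rare = FALSE,
                  null_resolved_by_axiom = FALSE, n_inconsistent = 0L,
                  n_consistent = 0L, n_consistent_unrelated = 0L,
                  discordant_ids = character(), ab_depleted = FALSE)
  list(profile = profile, in_axiom = in_axiom, n_classes_first = n_classes_first,
       dup_discord = dup_discord, subcluster = subcluster,
       between_individuals = between_individuals, null_carriers = null_carriers,
       null_rare = null_rare, null_resolved_by_axiom = null_resolved_by_axiom,
       n_inconsistent = n_inconsistent, n_consistent = n_consistent,
       n_consistent_unrelated = n_consistent_unrelated,
       discordant_ids = discordant_ids, ab_depleted = ab_depleted)

test_that("second-platform ladder assigns the documented classes", {
  expect_identical(classify_axiom(ax_ev())$class, "A")
  expect_identical(classify_axiom(ax_ev(in_axiom = FALSE))$class, "R")
  # C with its recode adjustments
  sub <- list(proposal = c("i1", "i2"), unsupported = NULL)
  resC <- classify_axiom(ax_ev(subcluster = sub, dup_discord = 30L))
  expect_identical(resC$class, "C")
  expect_identical(resC$adjustments$action, rep("recode", 2))
  # B with set-missing adjustments; B/G when rare nulls co-occur
  resB <- classify_axiom(ax_ev(mk_profile(between_fraction = 0.03),
                               between_individuals = c("i1", "i2", "i3")))
  expect_identical(resB$class, "B")
  expect_identical(nrow(resB$adjustments), 3L)
  expect_identical(classify_axiom(ax_ev(mk_profile(between_fraction = 0.03),
                                        null_carriers = 2L, null_rare = TRUE))$class,
                   "B/G")
  # exactly 1-2 discordant duplicate pairs, otherwise clean -> D
  resD <- classify_axiom(ax_ev(dup_discord = 2L, discordant_ids = c("i9", "i7")))
  expect_identical(resD$class, "D")
  expect_identical(resD$adjustments$action, rep("set_missing", 2))
  # J: compressed space with degraded intervals
  expect_identical(classify_axiom(ax_ev(mk_profile(cluster_space = 0.4,
                                                   width_max = 0.3)))$class, "J")
  # K: over-wide class interval
  expect_identical(classify_axiom(ax_ev(mk_profile(width_max = 0.15)))$class, "K")
  # O: missing cluster + elevated missingness
  expect_identical(classify_axiom(ax_ev(mk_profile(n_classes = 2L,
                                                   missing_fraction = 0.4)))$class, "O")
  # L: no differentiation at all
  expect_identical(classify_axiom(ax_ev(mk_profile(n_classes = 1L, n_modes = 1L,
                                                   separation = NA)))$class, "L")
  # N: extra unsupported mode with errors
  expect_identical(classify_axiom(ax_ev(mk_profile(n_modes = 4L),
                                        n_inconsistent = 1L))$class, "N")
  # P: error-count class on otherwise normal clustering
  expect_identical(classify_axiom(ax_ev(n_inconsistent = 3L))$class, "P")
  expect_identical(classify_axiom(ax_ev(n_consistent = 6L,
                                        n_consistent_unrelated = 6L))$class, "P")
  # Q: common null not callable
  expect_identical(classify_axiom(ax_ev(null_carriers = 10L))$class, "Q")
  # G and I: null-related resolvable
  expect_identical(classify_axiom(ax_ev(null_carriers = 2L, null_rare = TRUE))$class,
                   "G")
  expect_identical(classify_axiom(ax_ev(null_resolved_by_axiom = TRUE))$class, "I")
  # M: residual heavy discordance
  expect_identical(classify_axiom(ax_ev(dup_discord = 5L))$class, "M")
  # E: discordance confined to a designated founder lineage
  th <- default_thresholds(); th$founder_lineage <- "wild1"
  expect_identical(classify_axiom(ax_ev(dup_discord = 4L,
                                        discordant_ids = "wild1"), th)$class, "E")
})

test_that("every evidence combination yields exactly one class", {
  set.seed(71)
  for (k in 1:100) {
    ev <- ax_ev(mk_profile(n_classes = sample(1:3, 1), n_modes = sample(1:5, 1),
                           cluster_space = runif(1), separation = runif(1, -0.2, 0.5),
                           width_max = runif(1, 0, 0.5),
                           between_fraction = runif(1, 0, 0.1),
                           missing_fraction = runif(1)),
                dup_discord = sample(0:20, 1),
                n_inconsistent = sample(0:5, 1))
    res <- classify_axiom(ev)
    expect_true(is.character(res$class) && length(res$class) == 1L)
  }
})

test_that("adjustments apply idempotently and abort on unknown targets", {
  m <- call_matrix(matrix(c("AA", "AB", "BB", "AB"), 2,
                          dimnames = list(c("s1", "s2"), c("a", "b"))), "axiom")
  adj <- data.frame(snp = c("s1", "s2"), individual = c("a", "b"),
                    action = c("set_missing", "recode"),
                    new_call = c(NA, "AB"), reason = "test",
                    stringsAsFactors = FALSE)
  r1 <- apply_adjustments(m, adj)
  expect_true(is.na(unclass(r1$matrix)["s1", "a"]))
  # s2/b was already AB: only the real change is logged
  expect_identical(nrow(r1$log), 1L)
  r2 <- apply_adjustments(r1$matrix, adj)
  expect_identical(nrow(r2$log), 0L)
  expect_identical(unclass(r2$matrix)[, ], unclass(r1$matrix)[, ])
  expect_error(apply_adjustments(m, transform(adj, individual = c("zz", "b"))),
               "unknown individual")
  # no adjustments: unchanged
  expect_identical(unclass(apply_adjustments(m, NULL)$matrix)[, ], unclass(m)[, ])
})

test_that("integration collapses duplicates and computes MAF without them", {
  snps <- c("s1", "s2")
  a <- call_matrix(matrix(c("AA", "AB", "AA", "AB", "BB", "AA"), 2,
                          dimnames = list(snps, c("x", "y", "z"))), "infinium")
  b <- call_matrix(matrix(c("AA", "AB", "AA", "BB"), 2,
                          dimnames = list(snps, c("x", "w"))), "axiom")
  verd <- data.frame(snp = snps, compatible = c(TRUE, TRUE), class = "A",
                     stringsAsFactors = FALSE)
  out <- integrate_platforms(a, b, clone_groups = list(), verdicts = verd)
  # x collapses across platforms (concordant), w only on axiom
  expect_setequal(colnames(out$calls), c("x", "y", "z", "w"))
  expect_identical(unclass(out$calls)["s1", "x"], "AA")
  # duplicate pair discordant post-curation -> consensus missing + logged
  b2 <- call_matrix(matrix(c("BB", "AB", "AA", "BB"), 2,
                           dimnames = list(snps, c("x", "w"))), "axiom")
  out2 <- integrate_platforms(a, b2, list(), verd)
  expect_true(is.na(unclass(out2$calls)["s1", "x"]))
  expect_true(any(out2$conflicts$snp == "s1" & out2$conflicts$group == "x"))
  # MAF on collapsed columns: s1 calls AA, BB, AA, AA -> B freq 2/8
  expect_equal(unname(out$maf["s1"]), 0.25)
  # incompatible SNPs do not appear
  verd3 <- transform(verd, compatible = c(TRUE, FALSE))
  expect_identical(rownames(integrate_platforms(a, b, list(), verd3)$calls), "s1")
  # disjoint columns, no duplicates: column count adds up
  b3 <- call_matrix(matrix(c("AA", "AB"), 2, 1,
                           dimnames = list(snps, "solo")), "axiom")
  out3 <- integrate_platforms(a, b3, list(), verd)
  expect_identical(ncol(out3$calls), 4L)
})
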