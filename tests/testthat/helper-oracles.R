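# Independent oracles and fixture builders shared across the suite.

# Exhaustive gamete-enumeration oracle for Mendelian consistency, written
# as explicit loops over transmitted alleles - deliberately independent of
# the package's set-logic implementation.
.oracle_alleles <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"),
                        AN = c("A", "N"), BN = c("B", "N"), `NN*` = c("N", "N"))

oracle_trio_bad <- function(m, f, o) {
  if (is.na(o)) return(FALSE)
  if (is.na(m) && is.na(f)) return(FALSE)
  target <- sort(.oracle_alleles[[o]])
  ma <- if (is.na(m)) c("A", "B", "N") else .oracle_alleles[[m]]
  fa <- if (is.na(f)) c("A", "B", "N") else .oracle_alleles[[f]]
  for (x in ma) for (y in fa)
    if (identical(sort(c(x, y)), target)) return(FALSE)
  TRUE
}

oracle_duo_bad <- function(p, o) oracle_trio_bad(p, NA, o)

# tiny call-matrix builder
cm_build <- function(calls, snps = NULL, inds = NULL, platform = "merged") {
  m <- matrix(calls, nrow = length(snps %||% seq_len(length(calls))),
              dimnames = list(snps, inds))
  if (is.null(snps)) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(inds)) colnames(m) <- sprintf("I%d", seq_len(ncol(m)))
  call_matrix(m, platform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scenario with one secondary polymorphism per SNP at controlled
# 3'-distances (the distance-stratified experiment). Call error and other
# artifacts are off so the polymorphism mechanism is isolated.
distance_scenario <- function(seed, m_per_d = 40L, dgrid = c(1L, 2L, 3L, 5L, 8L)) {
  n <- m_per_d * length(dgrid)
  d_of <- rep(dgrid, each = m_per_d)
  snp_ids <- sprintf("SNP%05d", seq_len(n))
  effects <- list()
  for (i in seq_len(n))
    effects[[snp_ids[i]]] <- probe_effect(
      snp_ids[i],
      secondary = data.frame(d = d_of[i], carrier_frequency = NA_real_,
                             linked_allele = "B"))
  fams <- data.frame(mother = c("F001", "F003", "F005"),
                     father = c("F002", "F004", "F006"),
                     n_offspring = 25L, stringsAsFactors = FALSE)
  cfg <- sim_config(n_founders = 30L, families = fams, n_snps = n,
                    effects = effects, call_error_rate = 0, seed = seed)
  truth <- simulate_genotypes(cfg)
  int_inf <- simulate_intensities(truth, cfg$platforms$infinium, effects, seed + 1L)
  int_ax <- simulate_intensities(truth, cfg$platforms$axiom, effects, seed + 2L)
  ids <- colnames(truth$hap1)
  scn <- structure(list(
    truth = truth,
    inf = list(intens = int_inf, calls = call_genotypes(int_inf, cfg$platforms$infinium)),
    ax = list(intens = int_ax, calls = call_genotypes(int_ax, cfg$platforms$axiom)),
    pedigree = truth$pedigree,
    dup_pairs = data.frame(a = ids, b = ids, stringsAsFactors = FALSE)),
    class = "ab_scenario")
  reports <- data.frame(snp = snp_ids, probe_len = 35L, hits_1e12 = 1L,
                        hits_1e14 = 1L, hits_1e16 = 1L, best_e = 1e-20,
                        perfect_match = FALSE, n_secondary = 1L,
                        d_single = d_of, stringsAsFactors = FALSE)
  list(scn = scn, reports = reports, d_of = stats::setNames(d_of, snp_ids))
}
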