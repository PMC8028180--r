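# Duplicate identification, within-platform repeatability, and per-SNP
# discordance tallies.

# Visible-call projection: null-aware codes are compared at the level the
# arrays report them (AN looks AA, BN looks BB, the double null is not
# called), because duplicates are found before null curation.
visible_calls <- function(m) {
  m <- unclass(m)
  m[m == "AN"] <- "AA"
  m[m == "BN"] <- "BB"
  m[m == "NN*"] <- NA_character_
  m
}

#' Concordance between two call vectors
#'
#' Loci missing in either vector are excluded from the denominator.
#' Null-aware codes are compared on the underlying visible call.
#'
#' @param calls_a,calls_b named character call vectors (or single-column
#'   matrices) over the same SNPs.
#' @param snp_subset optional SNP ids restricting the comparison.
#' @return list: `n_compared`, `n_concordant`, `fraction` (NA, flagged via
#'   `valid = FALSE`, when nothing is comparable).
#' @export
pairwise_concordance <- function(calls_a, calls_b, snp_subset = NULL) {
  a <- visible_calls(as.matrix(calls_a)); b <- visible_calls(as.matrix(calls_b))
  a <- stats::setNames(a[, 1L], rownames(a)); b <- stats::setNames(b[, 1L], rownames(b))
  if (!is.null(snp_subset)) { a <- a[snp_subset]; b <- b[snp_subset] }
  else b <- b[names(a)]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  conc <- sum(a[ok] == b[ok])
  list(n_compared = n, n_concordant = conc,
       fraction = if (n > 0) conc / n else NA_real_, valid = n > 0)
}

# All-pairs concordance between the columns of two matrices via class
# indicator cross-products (avoids the O(pairs x snps) R loop).
concordance_counts <- function(ma, mb, snp_subset = NULL) {
  a <- visible_calls(ma); b <- visible_calls(mb)
  snps <- intersect(rownames(a), rownames(b))
  if (!is.null(snp_subset)) snps <- intersect(snps, snp_subset)
  a <- a[snps, , drop = FALSE]; b <- b[snps, , drop = FALSE]
  okA <- !is.na(a); okB <- !is.na(b)
  n_comp <- crossprod(okA, okB)
  n_conc <- matrix(0, ncol(a), ncol(b), dimnames = dimnames(n_comp))
  for (cl in c("AA", "AB", "BB")) {
    ia <- (!is.na(a) & a == cl); ib <- (!is.na(b) & b == cl)
    n_conc <- n_conc + crossprod(ia, ib)
  }
  list(n_compared = n_comp, n_concordant = n_conc, snps = snps)
}

#' Find genetic duplicates across two platforms
#'
#' All cross-platform column pairs with concordance strictly above
#' `threshold` (the duplicate rule is "more than", not "at least") over at
#' least `min_compared` jointly called loci are reported and merged into
#' clone groups by transitive closure. Pairs falling in
#' `[threshold - 0.02, threshold]` are reported as near-misses.
#'
#' @param matrix_a,matrix_b [call_matrix] objects (e.g. the two platforms).
#' @param snp_subset optional SNP ids (a pre-vetted robust subset).
#' @param threshold duplicate concordance threshold (default 0.97).
#' @param min_compared minimum jointly-called loci for a valid comparison.
#' @return list: `pairs` (data.frame a, b, n_compared, fraction),
#'   `clone_groups` (list of id vectors), `near_misses` (same shape as
#'   pairs).
#' @export
find_duplicates <- function(matrix_a, matrix_b, snp_subset = NULL,
                            threshold = 0.97, min_compared = 500L) {
  cc <- concordance_counts(matrix_a, matrix_b, snp_subset)
  frac <- cc$n_concordant / pmax(cc$n_compared, 1)
  valid <- cc$n_compared >= min_compared
  hit <- which(valid & frac > threshold, arr.ind = TRUE)
  pairs <- data.frame(a = rownames(frac)[hit[, 1L]], b = colnames(frac)[hit[, 2L]],
                      n_compared = cc$n_compared[hit],
                      fraction = frac[hit], stringsAsFactors = FALSE)
  near <- which(valid & frac <= threshold & frac >= threshold - 0.02, arr.ind = TRUE)
  near_misses <- data.frame(a = rownames(frac)[near[, 1L]],
                            b = colnames(frac)[near[, 2L]],
                            n_compared = cc$n_compared[near],
                            fraction = frac[near], stringsAsFactors = FALSE)
  groups <- uf_groups(pairs$a, pairs$b)
  list(pairs = pairs, clone_groups = groups, near_misses = near_misses)
}

#' Within-platform repeatability of replicate accessions
#'
#' For each clone group with >= 2 members present in the matrix, percent
#' discordant calls is computed for every replicate pair; an accession with
#' k replicates contributes the mean of its choose(k, 2) pair values as a
#' single number, and the grand mean is taken across accessions.
#'
#' @param matrix a [call_matrix].
#' @param clone_groups list of character vectors of replicate ids.
#' @param snp_subset optional SNP ids.
#' @return list: `per_accession` (data.frame accession, n_replicates,
#'   mean_pct_discordant), `grand_mean_pct`.
#' @export
repeatability <- function(matrix, clone_groups, snp_subset = NULL) {
  rows <- list()
  for (g in seq_along(clone_groups)) {
    mem <- intersect(clone_groups[[g]], colnames(matrix))
    if (length(mem) < 2L) next
    vals <- c()
    for (i in seq_len(length(mem) - 1L)) for (j in seq((i + 1L), length(mem))) {
      pc <- pairwise_concordance(matrix[, mem[i], drop = FALSE],
                                 matrix[, mem[j], drop = FALSE], snp_subset)
      if (pc$valid) vals <- c(vals, 100 * (1 - pc$fraction))
    }
    if (length(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = mem[1L], n_replicates = length(mem),
        mean_pct_discordant = mean(vals), stringsAsFactors = FALSE)
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), n_replicates = integer(),
               mean_pct_discordant = numeric(), stringsAsFactors = FALSE)
  list(per_accession = per,
       grand_mean_pct = if (nrow(per)) mean(per$mean_pct_discordant) else NA_real_)
}

#' Per-SNP duplicate discordance counts
#'
#' Counts, for each SNP, the duplicate pairs whose calls disagree (both
#' non-missing). Confirmed null calls can be exempted (`null_exempt`): a
#' curated Infinium null is not tallied as a cross-platform discordance.
#'
#' @param pairs data.frame with columns `a` (ids in `matrix_a`) and `b`
#'   (ids in `matrix_b`).
#' @param matrix_a,matrix_b [call_matrix] objects.
#' @param snp_subset optional SNP ids.
#' @param null_exempt optional data.frame (snp, individual) of confirmed
#'   null calls to skip.
#' @return data.frame: snp, n_informative, n_discordant.
#' @export
per_snp_discordance <- function(pairs, matrix_a, matrix_b, snp_subset = NULL,
                                null_exempt = NULL) {
  a <- visible_calls(matrix_a); b <- visible_calls(matrix_b)
  snps <- intersect(rownames(a), rownames(b))
  if (!is.null(snp_subset)) snps <- intersect(snps, snp_subset)
  n_inf <- stats::setNames(integer(length(snps)), snps)
  n_dis <- n_inf
  for (k in seq_len(nrow(pairs))) {
    va <- a[snps, pairs$a[k]]; vb <- b[snps, pairs$b[k]]
    if (!is.null(null_exempt) && nrow(null_exempt)) {
      ex <- null_exempt$snp[null_exempt$individual %in% c(pairs$a[k], pairs$b[k])]
      if (length(ex)) { va[snps %in% ex] <- NA; vb[snps %in% ex] <- NA }
    }
    ok <- !is.na(va) & !is.na(vb)
    n_inf <- n_inf + ok
    n_dis <- n_dis + (ok & va != vb)
  }
  data.frame(snp = snps, n_informative = as.integer(n_inf),
             n_discordant = as.integer(n_dis), stringsAsFactors = FALSE)
}
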