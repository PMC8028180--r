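# Mendelian error detection across a pedigree and null-allele inference.

# allele multiset for a call code (null-aware); NULL for missing
.call_alleles <- function(call) {
  switch(call,
         AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"),
         AN = c("A", "N"), BN = c("B", "N"), `NN*` = c("N", "N"),
         NULL)
}

#' Parent-offspring duo inconsistency (opposing homozygotes)
#'
#' A duo is Mendelian-inconsistent exactly when parent and offspring share
#' no allele; on visible biallelic codes that is the opposing-homozygote
#' signature \{AA, BB\}. Missing never flags. Null-aware codes are handled
#' with N as a transmissible allele (so AN vs BN is consistent).
#'
#' @param parent_call,offspring_call call codes (`NA` = missing).
#' @return logical flag.
#' @export
duo_inconsistent <- function(parent_call, offspring_call) {
  mapply(function(p, o) {
    if (is.na(p) || is.na(o)) return(FALSE)
    length(intersect(.call_alleles(p), .call_alleles(o))) == 0L
  }, parent_call, offspring_call, USE.NAMES = FALSE)
}

#' Trio inconsistency under biallelic Mendelian transmission
#'
#' Flags offspring genotypes impossible given both parents: the offspring's
#' two alleles must be assignable one to each parent. A missing parent
#' degrades to the duo check on the other.
#'
#' @param mother_call,father_call,offspring_call call codes (`NA` missing).
#' @return logical flag.
#' @export
trio_inconsistent <- function(mother_call, father_call, offspring_call) {
  mapply(function(m, f, o) {
    if (is.na(o)) return(FALSE)
    if (is.na(m) && is.na(f)) return(FALSE)
    if (is.na(m)) return(duo_inconsistent(f, o))
    if (is.na(f)) return(duo_inconsistent(m, o))
    oa <- .call_alleles(o); ma <- .call_alleles(m); fa <- .call_alleles(f)
    !((oa[1] %in% ma && oa[2] %in% fa) || (oa[2] %in% ma && oa[1] %in% fa))
  }, mother_call, father_call, offspring_call, USE.NAMES = FALSE)
}

# lookup tables over call codes (index 1 = missing) for vectorized scans
.mendel_luts <- function() {
  codes <- c(NA, .call_codes)
  n <- length(codes)
  duo <- matrix(FALSE, n, n)
  for (i in 2:n) for (j in 2:n)
    duo[i, j] <- duo_inconsistent(codes[i], codes[j])
  trio <- array(FALSE, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 2:n)
    trio[i, j, k] <- trio_inconsistent(codes[i], codes[j], codes[k])
  list(codes = codes, duo = duo, trio = trio)
}

.code_index <- function(m) {
  idx <- match(unclass(m), .call_codes) + 1L
  idx[is.na(idx)] <- 1L
  # the double null is uncallable on the array; scanning it as a literal
  # {N,N} genotype would manufacture errors against any called relative
  idx[unclass(m) %in% "NN*"] <- 1L
  matrix(idx, nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Scan a call matrix for Mendelian inconsistent errors
#'
#' Every parent-offspring duo (one genotyped parent) and complete trio
#' (both genotyped) in the pedigree is tested at every SNP. Individuals in
#' the pedigree but absent from the matrix are skipped.
#'
#' @param matrix a [call_matrix].
#' @param ped a [pedigree].
#' @return list: `errors` (data.frame snp, child, parent1, parent2, kind,
#'   code), `per_snp` (snp, n_inconsistent), `per_individual` (individual,
#'   n_inconsistent).
#' @export
scan_mendelian_errors <- function(matrix, ped) {
  stopifnot(inherits(ped, "pedigree"))
  luts <- .mendel_luts()
  idx <- .code_index(matrix)
  inds <- colnames(matrix)
  snps <- rownames(matrix)
  per_snp <- stats::setNames(integer(length(snps)), snps)
  per_ind <- stats::setNames(integer(length(inds)), inds)
  errs <- list()
  for (r in seq_len(nrow(ped))) {
    child <- ped$id[r]
    if (!(child %in% inds)) next
    mo <- ped$mother[r]; fa <- ped$father[r]
    mo_ok <- !is.na(mo) && mo %in% inds
    fa_ok <- !is.na(fa) && fa %in% inds
    if (!mo_ok && !fa_ok) next
    ci <- idx[, child]
    if (mo_ok && fa_ok) {
      bad <- luts$trio[cbind(idx[, mo], idx[, fa], ci)]
      code <- ifelse(luts$duo[cbind(idx[, mo], ci)] |
                     luts$duo[cbind(idx[, fa], ci)],
                     "opposing-homozygote-duo", "impossible-trio")
      p1 <- mo; p2 <- fa; kind <- "trio"
    } else {
      par <- if (mo_ok) mo else fa
      bad <- luts$duo[cbind(idx[, par], ci)]
      code <- rep("opposing-homozygote-duo", length(bad))
      p1 <- par; p2 <- NA_character_; kind <- "duo"
    }
    if (any(bad)) {
      per_snp[bad] <- per_snp[bad] + 1L
      per_ind[child] <- per_ind[child] + sum(bad)
      errs[[length(errs) + 1L]] <- data.frame(
        snp = snps[bad], child = child, parent1 = p1, parent2 = p2,
        kind = kind, code = code[bad], stringsAsFactors = FALSE)
    }
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(snp = character(), child = character(), parent1 = character(),
               parent2 = character(), kind = character(), code = character(),
               stringsAsFactors = FALSE)
  list(errors = errors,
       per_snp = data.frame(snp = snps, n_inconsistent = as.integer(per_snp),
                            stringsAsFactors = FALSE),
       per_individual = data.frame(individual = inds,
                                   n_inconsistent = as.integer(per_ind),
                                   stringsAsFactors = FALSE))
}

#' Detect Mendelian consistent errors (singleton double-recombinants)
#'
#' For each parent and linkage group, the transmitted-allele state of every
#' offspring is collected at SNPs where the parent is heterozygous and the
#' transmitted allele is unambiguous (offspring homozygous, or offspring
#' heterozygous with the other parent homozygous). Because the parent is
#' unphased, allele states are first converted to haplotype-origin states
#' with a minimum-recombinant phasing over the parent's offspring: adjacent
#' informative SNPs are declared in coupling or repulsion by majority vote
#' across offspring (parents with fewer than `min_offspring` informative
#' offspring are skipped - a single meiosis cannot distinguish phase from
#' recombination). A single-SNP origin flip flanked on both sides by at
#' least `k_flank` concordant informative SNPs within `w_cM` is a
#' consistent-error candidate: transmissible, but implying an implausible
#' double crossover.
#'
#' @param matrix a [call_matrix].
#' @param ped a [pedigree].
#' @param map genetic map data.frame (snp, lg, cM).
#' @param k_flank flanking concordant informative SNPs required per side.
#' @param w_cM window within which the flanks must lie.
#' @param min_offspring minimum informative offspring to phase a parent.
#' @return data.frame: snp, lg, parent, child.
#' @export
detect_consistent_errors <- function(matrix, ped, map, k_flank = 3L, w_cM = 10,
                                     min_offspring = 4L) {
  m <- visible_calls(matrix)
  unmapped <- setdiff(rownames(m), map$snp)
  if (length(unmapped))
    ab_warn("%d SNPs not in map skipped in consistent-error scan", length(unmapped))
  map <- map[map$snp %in% rownames(m), , drop = FALSE]
  out <- list()
  # offspring grouped by parent
  fam <- list()
  for (r in seq_len(nrow(ped))) {
    kid <- ped$id[r]
    if (!(kid %in% colnames(m))) next
    for (side in c("mother", "father")) {
      p <- ped[[side]][r]
      if (is.na(p) || !(p %in% colnames(m))) next
      other <- ped[[setdiff(c("mother", "father"), side)]][r]
      fam[[p]] <- rbind(fam[[p]],
                        data.frame(child = kid, other = other %||% NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  for (par in names(fam)) {
    kids <- fam[[par]]
    pc <- m[map$snp, par]
    het <- !is.na(pc) & pc == "AB"
    # transmitted-allele state per offspring (1 = A, 2 = B, NA = unknown)
    S <- matrix(NA_integer_, nrow(map), nrow(kids))
    for (k in seq_len(nrow(kids))) {
      cc <- m[map$snp, kids$child[k]]
      oc <- if (!is.na(kids$other[k]) && kids$other[k] %in% colnames(m))
        m[map$snp, kids$other[k]] else rep(NA_character_, nrow(map))
      st <- rep(NA_integer_, nrow(map))
      st[het & !is.na(cc) & cc == "AA"] <- 1L
      st[het & !is.na(cc) & cc == "BB"] <- 2L
      amb <- het & !is.na(cc) & cc == "AB"
      st[amb & !is.na(oc) & oc == "AA"] <- 2L
      st[amb & !is.na(oc) & oc == "BB"] <- 1L
      S[, k] <- st
    }
    if (sum(colSums(!is.na(S)) > 0) < min_offspring) next
    for (g in unique(map$lg)) {
      ix <- which(map$lg == g & het)
      ix <- ix[rowSums(!is.na(S[ix, , drop = FALSE])) > 0]
      if (length(ix) < 2L * k_flank + 1L) next
      # majority-vote phase between consecutive informative SNPs
      flip <- logical(length(ix))
      for (j in 2:length(ix)) {
        a <- S[ix[j - 1L], ]; b <- S[ix[j], ]
        ok <- !is.na(a) & !is.na(b)
        flip[j] <- sum(a[ok] != b[ok]) > sum(a[ok] == b[ok])
      }
      phase <- cumsum(flip) %% 2L
      for (k in seq_len(nrow(kids))) {
        s <- S[ix, k]
        origin <- ifelse(is.na(s), NA_integer_, (s - 1L + phase) %% 2L)
        jj <- which(!is.na(origin))
        if (length(jj) < 2L * k_flank + 1L) next
        o <- origin[jj]; cm <- map$cM[ix][jj]
        for (j in (k_flank + 1L):(length(jj) - k_flank)) {
          left <- o[(j - k_flank):(j - 1L)]
          right <- o[(j + 1L):(j + k_flank)]
          if (all(left != o[j]) && all(right != o[j]) &&
              cm[j] - cm[j - k_flank] <= w_cM && cm[j + k_flank] - cm[j] <= w_cM) {
            out[[length(out) + 1L]] <- data.frame(
              snp = map$snp[ix[jj[j]]], lg = g, parent = par,
              child = kids$child[k], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(snp = character(), lg = character(), parent = character(),
               child = character(), stringsAsFactors = FALSE)
}

#' Infer null alleles from opposing-homozygote duos and intensity
#'
#' An opposing-homozygote parent-offspring duo whose two members both sit at
#' reduced R (below `r_frac` of their called cluster's median R at that
#' SNP) is the null-allele signature: both are recoded as carrying N
#' (AA -> AN, BB -> BN). Individuals with R below `r_null_abs` of the SNP's
#' overall median are recoded to the double null `NN*`, and parents of an
#' `NN*` individual that are visibly homozygous at reduced R are forced to
#' carriers. SNPs whose carrier count stays at or below `rare_max` are
#' flagged rare (the SNP remains includable).
#'
#' @param matrix a [call_matrix] (visible codes).
#' @param intens intensity data.frame for the same platform; `NULL` degrades
#'   to pedigree-only evidence (flagged low confidence).
#' @param ped a [pedigree].
#' @param r_frac cluster-relative R threshold for carrier recoding.
#' @param r_null_abs SNP-relative R threshold for the double null.
#' @param rare_max maximum carriers for the "rare null" flag.
#' @return list: `null_calls` (data.frame snp, individual, recoded,
#'   evidence), `matrix` (recoded [call_matrix]), `snp_summary` (snp,
#'   n_carriers, rare).
#' @export
infer_null_alleles <- function(matrix, intens, ped, r_frac = 0.6,
                               r_null_abs = 0.1, rare_max = 3L) {
  m <- unclass(matrix)
  has_intens <- !is.null(intens)
  rmat <- NULL
  if (has_intens) {
    snps <- rownames(m); inds <- colnames(m)
    rmat <- matrix(NA_real_, length(snps), length(inds), dimnames = list(snps, inds))
    sel <- intens$snp %in% snps & intens$individual %in% inds
    rmat[cbind(match(intens$snp[sel], snps), match(intens$individual[sel], inds))] <-
      intens$r[sel]
  }
  scan <- scan_mendelian_errors(matrix, ped)
  duo_err <- scan$errors[scan$errors$code == "opposing-homozygote-duo", , drop = FALSE]
  calls <- list()
  low_r_cluster <- function(snp, ind) {
    if (!has_intens) return(NA)
    r <- rmat[snp, ind]
    if (is.na(r)) return(NA)
    cl <- visible_calls(m[snp, , drop = FALSE])[1L, ]
    if (is.na(cl[[ind]])) return(NA)
    same <- which(!is.na(cl) & cl == cl[[ind]])
    # upper-quartile reference: the called cluster is itself contaminated
    # by carriers when the null is common, which would drag a median down
    ref <- q_lin(rmat[snp, same], 0.75)
    r < r_frac * ref
  }
  recode <- function(snp, ind, ev) {
    cur <- m[snp, ind]
    new <- switch(cur, AA = "AN", BB = "BN", cur)
    if (!identical(new, cur)) {
      m[snp, ind] <<- new
      calls[[length(calls) + 1L]] <<- data.frame(
        snp = snp, individual = ind, recoded = new, evidence = ev,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(duo_err)) {
    for (k in seq_len(nrow(duo_err))) {
      snp <- duo_err$snp[k]; child <- duo_err$child[k]
      par <- duo_err$parent1[k]
      # identify which parent opposes the child when the record is a trio
      if (!is.na(duo_err$parent2[k])) {
        for (p in c(duo_err$parent1[k], duo_err$parent2[k]))
          if (isTRUE(duo_inconsistent(m[snp, p], m[snp, child]))) { par <- p; break }
      }
      ev <- if (has_intens) "duo+intensity" else "duo-only"
      lp <- low_r_cluster(snp, par); lc <- low_r_cluster(snp, child)
      if (!has_intens || (isTRUE(lp) && isTRUE(lc))) {
        recode(snp, par, ev); recode(snp, child, ev)
      }
    }
  }
  # double-null: near-zero R with no confident call or homozygous call
  if (has_intens) {
    for (snp in rownames(m)) {
      med <- stats::median(rmat[snp, ], na.rm = TRUE)
      if (!is.finite(med) || med <= 0) next
      low <- which(!is.na(rmat[snp, ]) & rmat[snp, ] < r_null_abs * med)
      for (j in low) {
        ind <- colnames(m)[j]
        if (is.na(m[snp, ind]) || m[snp, ind] %in% c("AA", "BB")) {
          if (!identical(m[snp, ind], "NN*")) {
            m[snp, ind] <- "NN*"
            calls[[length(calls) + 1L]] <- data.frame(
              snp = snp, individual = ind, recoded = "NN*",
              evidence = "near-zero-R", stringsAsFactors = FALSE)
          }
          # transmission forces both parents to carry N
          row <- ped[ped$id == ind, , drop = FALSE]
          if (nrow(row)) for (p in c(row$mother, row$father)) {
            if (!is.na(p) && p %in% colnames(m) &&
                !is.na(m[snp, p]) && m[snp, p] %in% c("AA", "BB") &&
                isTRUE(low_r_cluster(snp, p)))
              recode(snp, p, "forced-by-NN-offspring")
          }
        }
      }
    }
  }
  null_calls <- if (length(calls)) unique(do.call(rbind, calls)) else
    data.frame(snp = character(), individual = character(), recoded = character(),
               evidence = character(), stringsAsFactors = FALSE)
  carriers <- table(factor(null_calls$snp, levels = rownames(m)))
  snp_summary <- data.frame(snp = rownames(m), n_carriers = as.integer(carriers),
                            stringsAsFactors = FALSE)
  snp_summary$rare <- snp_summary$n_carriers > 0 & snp_summary$n_carriers <= rare_max
  if (!has_intens)
    attr(null_calls, "confidence") <- "low (pedigree-only evidence)"
  list(null_calls = null_calls,
       matrix = call_matrix(m, attr(matrix, "platform")),
       snp_summary = snp_summary)
}
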