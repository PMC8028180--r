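# Genetic map revision constrained by physical coordinates.

#' Select a physical position for a probe from its BLAST hits
#'
#' Among hits with E-value strictly below `e_max` on the expected
#' chromosome and lying inside the interval spanned by the genetically
#' flanking SNPs, the hit with the lowest E-value wins (ties: highest bit
#' score, then first).
#'
#' @param hits data.frame of BLAST hits for one probe ([read_blast_tab]).
#' @param expected_chrom chromosome implied by the linkage group.
#' @param flank_interval optional c(lo, hi) physical interval from the
#'   flanking SNPs; NULL = unconstrained.
#' @param e_max E-value threshold (default 1e-12).
#' @return list(bp, hit) or NULL when no hit qualifies.
#' @export
select_physical_position <- function(hits, expected_chrom, flank_interval = NULL,
                                     e_max = 1e-12) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  keep <- hits$evalue < e_max & hits$sseqid == expected_chrom
  if (!is.null(flank_interval)) {
    mid <- (hits$sstart + hits$send) / 2
    keep <- keep & mid >= flank_interval[1] & mid <= flank_interval[2]
  }
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(h$evalue, -h$bitscore), , drop = FALSE]
  list(bp = (h$sstart[1L] + h$send[1L]) / 2, hit = h[1L, ])
}

#' Interpolate a cM position from physical flanks
#'
#' Linear interpolation on relative physical distance:
#' `cM = left_cM + (right_cM - left_cM) * (bp - left_bp)/(right_bp - left_bp)`.
#' A zero physical span falls back to the midpoint with a warning.
#'
#' @param target_bp physical position to place.
#' @param left,right numeric c(bp, cM) of the flanking SNPs.
#' @return cM position.
#' @export
interpolate_cm <- function(target_bp, left, right) {
  if (right[1] == left[1]) {
    ab_warn("zero physical span between flanks; using midpoint")
    return(midpoint_cm(left[2], right[2]))
  }
  left[2] + (right[2] - left[2]) * (target_bp - left[1]) / (right[1] - left[1])
}

#' Midpoint cM fallback
#' @param left_cM,right_cM flanking cM positions (left <= right).
#' @return equidistant cM position.
#' @export
midpoint_cm <- function(left_cM, right_cM) (left_cM + right_cM) / 2

# longest non-decreasing subsequence (indices), O(n^2); ties in value allowed
.lnds <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (v[j] <= v[i] && len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; prev[i] <- j }
  }
  i <- which.max(len)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Revise a genetic map against physical coordinates
#'
#' Per linkage group, SNPs with a physical anchor are put in physical
#' order; the largest set already consistent between cM and bp order (a
#' longest non-decreasing subsequence of cM along bp order) is kept, and
#' each conflicting SNP is moved to a cM position interpolated from its
#' nearest kept physical flanks - but only if the displacement is at most
#' `max_move_cM` and, when a `mendel_hook` is supplied, the
#' consistent-error count on the provided families does not increase.
#' Flank fallback ladder: nearest kept flanks, then the alternative
#' adjacent kept SNP, then the midpoint of the genetic flanks. SNPs absent
#' from the map but present in `positions` (with an `lg` column) are placed
#' by interpolation (`placed_new`). Unanchored SNPs keep their positions.
#'
#' @param map genetic map data.frame (snp, lg, cM, bp).
#' @param positions data.frame (snp, bp, and lg for SNPs to place anew),
#'   e.g. from [select_physical_position].
#' @param mendel_hook optional function(candidate_map) -> numeric count of
#'   Mendelian consistent errors; a move is rejected if it increases.
#' @param max_move_cM displacement cap (default 2 cM).
#' @return list: `map` (revised, sorted by cM with bp tiebreak),
#'   `revision` (audit data.frame: snp, lg, old_cM, new_cM, bp, method).
#' @export
revise_map <- function(map, positions, mendel_hook = NULL, max_move_cM = 2) {
  map <- as.data.frame(map)
  positions <- as.data.frame(positions)
  pos_bp <- stats::setNames(positions$bp, positions$snp)
  audit <- list()
  new_cm <- stats::setNames(map$cM, map$snp)
  method <- stats::setNames(rep("kept", nrow(map)), map$snp)
  base_err <- if (!is.null(mendel_hook)) mendel_hook(map) else NULL
  for (g in unique(map$lg)) {
    sub <- map[map$lg == g, , drop = FALSE]
    anchored <- sub$snp[sub$snp %in% names(pos_bp)]
    if (length(anchored) < 2L) {
      if (length(anchored) < nrow(sub)) ab_warn("LG %s: <2 anchored SNPs, skipped", g)
      next
    }
    bp <- pos_bp[anchored]
    ord <- order(bp)
    snps_bp <- anchored[ord]
    cm_bp <- map$cM[match(snps_bp, map$snp)]
    keep_idx <- .lnds(cm_bp)
    kept <- snps_bp[keep_idx]
    movers <- setdiff(snps_bp, kept)
    kept_bp <- pos_bp[kept]; kept_cm <- new_cm[kept]
    for (s in movers) {
      tb <- pos_bp[[s]]
      li <- which(kept_bp < tb); ri <- which(kept_bp > tb)
      cand <- NULL; meth <- NULL
      if (length(li) && length(ri)) {
        l <- li[which.max(kept_bp[li])]; r <- ri[which.min(kept_bp[ri])]
        if (kept_cm[l] <= kept_cm[r]) {
          cand <- interpolate_cm(tb, c(kept_bp[l], kept_cm[l]),
                                 c(kept_bp[r], kept_cm[r]))
          meth <- "interpolated"
        } else if (length(li) > 1L || length(ri) > 1L) {
          # alternative adjacent flank with a consistent pair
          alt <- NULL
          if (length(li) > 1L) {
            l2 <- li[order(kept_bp[li], decreasing = TRUE)][2L]
            if (kept_cm[l2] <= kept_cm[r]) alt <- c(l2, r)
          }
          if (is.null(alt) && length(ri) > 1L) {
            r2 <- ri[order(kept_bp[ri])][2L]
            if (kept_cm[l] <= kept_cm[r2]) alt <- c(l, r2)
          }
          if (!is.null(alt)) {
            cand <- interpolate_cm(tb, c(kept_bp[alt[1]], kept_cm[alt[1]]),
                                   c(kept_bp[alt[2]], kept_cm[alt[2]]))
            meth <- "interpolated"
          }
        }
        if (is.null(cand)) {
          cand <- midpoint_cm(min(kept_cm[l], kept_cm[r]), max(kept_cm[l], kept_cm[r]))
          meth <- "midpoint"
        }
      } else if (length(li)) {
        cand <- kept_cm[li[which.max(kept_bp[li])]]; meth <- "midpoint"
      } else if (length(ri)) {
        cand <- kept_cm[ri[which.min(kept_bp[ri])]]; meth <- "midpoint"
      }
      if (is.null(cand)) next
      old <- new_cm[[s]]
      if (abs(cand - old) > max_move_cM) {
        audit[[length(audit) + 1L]] <- data.frame(
          snp = s, lg = g, old_cM = old, new_cM = old, bp = tb,
          method = "kept_conflict", stringsAsFactors = FALSE)
        next
      }
      if (!is.null(mendel_hook)) {
        cand_map <- map
        cand_map$cM[cand_map$snp == s] <- cand
        cand_map <- cand_map[order(cand_map$lg, cand_map$cM,
                                   ifelse(is.na(cand_map$bp), Inf, cand_map$bp)), ]
        if (mendel_hook(cand_map) > base_err) {
          audit[[length(audit) + 1L]] <- data.frame(
            snp = s, lg = g, old_cM = old, new_cM = old, bp = tb,
            method = "kept_conflict", stringsAsFactors = FALSE)
          next
        }
      }
      new_cm[[s]] <- cand
      method[[s]] <- meth
      audit[[length(audit) + 1L]] <- data.frame(
        snp = s, lg = g, old_cM = old, new_cM = cand, bp = tb,
        method = meth, stringsAsFactors = FALSE)
    }
    # place SNPs new to the map on this LG
    new_snps <- positions$snp[!(positions$snp %in% map$snp)]
    if (length(new_snps) && "lg" %in% names(positions)) {
      new_snps <- new_snps[positions$lg[match(new_snps, positions$snp)] == g]
      for (s in new_snps) {
        tb <- pos_bp[[s]]
        li <- which(kept_bp < tb); ri <- which(kept_bp > tb)
        if (!length(li) || !length(ri)) next
        l <- li[which.max(kept_bp[li])]; r <- ri[which.min(kept_bp[ri])]
        cand <- interpolate_cm(tb, c(kept_bp[l], kept_cm[l]),
                               c(kept_bp[r], kept_cm[r]))
        map <- rbind(map, data.frame(snp = s, lg = g, cM = cand, bp = tb,
                                     stringsAsFactors = FALSE))
        new_cm[[s]] <- cand
        method[[s]] <- "placed_new"
        audit[[length(audit) + 1L]] <- data.frame(
          snp = s, lg = g, old_cM = NA_real_, new_cM = cand, bp = tb,
          method = "placed_new", stringsAsFactors = FALSE)
      }
    }
  }
  map$cM <- new_cm[map$snp]
  map$bp <- ifelse(map$snp %in% names(pos_bp), pos_bp[map$snp], map$bp)
  map <- map[order(map$lg, map$cM, ifelse(is.na(map$bp), Inf, map$bp)), ]
  rownames(map) <- NULL
  revision <- if (length(audit)) do.call(rbind, audit) else
    data.frame(snp = character(), lg = character(), old_cM = numeric(),
               new_cM = numeric(), bp = numeric(), method = character(),
               stringsAsFactors = FALSE)
  list(map = map, revision = revision)
}
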