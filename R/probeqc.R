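# Probe-level failure quantification: off-target hits, perfect-match
# status, secondary polymorphisms with 3'-distance, stratified rates.

#' Count BLAST hits per E-value threshold
#'
#' Counts are of hits with E strictly below each threshold and are
#' therefore non-increasing as the threshold tightens. The perfect-match
#' flag requires full query coverage, 100% identity and zero gap opens -
#' never the E-value, which depends on database size.
#'
#' @param hits BLAST hits for one probe ([read_blast_tab]).
#' @param thresholds E-value thresholds (default 1e-12, 1e-14, 1e-16).
#' @param probe_len probe length for the full-coverage test.
#' @return list: `counts` (named per threshold), `best_e`, `perfect_match`.
#' @export
count_hits <- function(hits, thresholds = c(1e-12, 1e-14, 1e-16), probe_len = 50L) {
  counts <- vapply(thresholds, function(t) sum(hits$evalue < t), integer(1))
  names(counts) <- formatC(thresholds, format = "e", digits = 0)
  perfect <- nrow(hits) > 0 && any(hits$qstart == 1L & hits$qend == probe_len &
                                   hits$pident == 100 & hits$gapopen == 0L)
  list(counts = counts,
       best_e = if (nrow(hits)) min(hits$evalue) else NA_real_,
       perfect_match = perfect)
}

#' Physical interval of a probe and its 3'-distance convention
#'
#' The probe runs up to (not including) the targeted SNP on its strand, so
#' the interval of `probe_len` bases ends adjacent to the target. Distance
#' from the 3' end is d = 1 for the base adjacent to the target SNP and
#' d = probe_len at the 5' terminus; an off-by-one here silently corrupts
#' every distance-stratified analysis, hence the explicit statement.
#'
#' @param chrom chromosome name.
#' @param pos 1-based target SNP position.
#' @param strand `"+"` or `"-"` (probe strand).
#' @param probe_len probe length.
#' @return list: chrom, start, end (1-based inclusive), strand, `d_of` a
#'   function mapping a genomic position inside the interval to its
#'   3'-distance, `truncated` flag when the interval ran off the
#'   chromosome start.
#' @export
probe_interval <- function(chrom, pos, strand = "+", probe_len = 50L) {
  truncated <- FALSE
  if (strand == "+") {
    start <- pos - probe_len; end <- pos - 1L
    if (start < 1L) { start <- 1L; truncated <- TRUE }
    d_of <- function(p) pos - p
  } else {
    start <- pos + 1L; end <- pos + probe_len
    d_of <- function(p) p - pos
  }
  if (truncated) ab_warn("probe interval truncated at chromosome start")
  list(chrom = chrom, start = as.integer(start), end = as.integer(end),
       strand = strand, d_of = d_of, truncated = truncated)
}

#' Filter secondary polymorphisms in a probe interval
#'
#' Variants are retained when their alternate allele is carried by at
#' least `min_carrier` of the sequenced individuals and no more than
#' `max_missing` of the individuals are missing; the 3'-distance d is
#' attached via the interval's orientation. An indel is counted once, at
#' its 3'-most overlapping position.
#'
#' @param variants data.frame from [read_vcf_probe_variants] (one probe).
#' @param interval a [probe_interval].
#' @param min_carrier carrier-fraction floor (default 0.10).
#' @param max_missing missing-fraction ceiling (default 0.25).
#' @return data.frame: pos, ref, alt, carrier_fraction, missing_fraction, d.
#' @export
extract_secondary_polymorphisms <- function(variants, interval,
                                            min_carrier = 0.10, max_missing = 0.25) {
  if (!nrow(variants))
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      carrier_fraction = numeric(), missing_fraction = numeric(),
                      d = integer(), stringsAsFactors = FALSE))
  cf <- variants$n_carriers / pmax(variants$n_samples, 1L)
  mf <- variants$n_missing / pmax(variants$n_samples, 1L)
  keep <- cf >= min_carrier & mf <= max_missing
  v <- variants[keep, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      carrier_fraction = numeric(), missing_fraction = numeric(),
                      d = integer(), stringsAsFactors = FALSE))
  d <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    span <- seq(v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
    span <- span[span >= interval$start & span <= interval$end]
    d[i] <- if (length(span)) min(interval$d_of(span)) else NA_integer_
  }
  out <- data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
                    carrier_fraction = cf[keep], missing_fraction = mf[keep],
                    d = d, stringsAsFactors = FALSE)
  out[!is.na(out$d), , drop = FALSE]
}

#' Build a per-SNP probe report
#'
#' @param snp_id SNP id.
#' @param hits BLAST hits for the probe.
#' @param interval a [probe_interval].
#' @param variants variant records for the probe (may be empty).
#' @param probe_len probe length.
#' @return one-row data.frame with hit counts per threshold, best E,
#'   perfect-match flag, polymorphism count and (for single-polymorphism
#'   probes) the 3'-distance.
#' @export
probe_report <- function(snp_id, hits, interval, variants, probe_len = 50L) {
  ch <- count_hits(hits, probe_len = probe_len)
  sp <- extract_secondary_polymorphisms(variants, interval)
  data.frame(snp = snp_id, probe_len = probe_len,
             hits_1e12 = ch$counts[[1]], hits_1e14 = ch$counts[[2]],
             hits_1e16 = ch$counts[[3]], best_e = ch$best_e,
             perfect_match = ch$perfect_match,
             n_secondary = nrow(sp),
             d_single = if (nrow(sp) == 1L) sp$d[1L] else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Stratified inclusion and compatibility rates
#'
#' Groups SNPs by BLAST hit count (counts above 10 pooled into one "11+"
#' group) or by the 3'-distance of a single secondary polymorphism
#' (multi-polymorphism probes are excluded from the distance analysis), and
#' reports the inclusion rate, the compatibility rate among included SNPs
#' with and without class C counted compatible, and optionally the mean
#' cluster space. Strata with fewer than `min_stratum` SNPs are dropped
#' from the cluster-space summary.
#'
#' @param verdicts verdict data.frame (snp, status, class, compatible).
#' @param reports probe-report data.frame ([probe_report] rows).
#' @param by `"hits"` or `"distance"`.
#' @param hits_col which threshold column to stratify on.
#' @param cluster_space optional named numeric per-SNP cluster space.
#' @param min_stratum minimum SNPs for the cluster-space summary.
#' @return data.frame: stratum, n, inclusion_rate, compat_rate_with_c,
#'   compat_rate_without_c, mean_cluster_space.
#' @export
stratified_rates <- function(verdicts, reports, by = c("hits", "distance"),
                             hits_col = "hits_1e12", cluster_space = NULL,
                             min_stratum = 10L) {
  by <- match.arg(by)
  df <- merge(verdicts, reports, by = "snp")
  if (by == "hits") {
    h <- df[[hits_col]]
    strat <- ifelse(h > 10, "11+", as.character(h))
    lev <- c(as.character(0:10), "11+")
  } else {
    df <- df[df$n_secondary == 1L & !is.na(df$d_single), , drop = FALSE]
    strat <- as.character(df$d_single)
    lev <- as.character(sort(unique(df$d_single)))
  }
  strat <- factor(strat, levels = lev)
  out <- do.call(rbind, lapply(levels(strat), function(s) {
    i <- which(strat == s)
    if (!length(i)) return(NULL)
    inc <- df$status[i] == "included"
    inc_i <- i[inc]
    with_c <- df$compatible[inc_i]
    without_c <- df$compatible[inc_i] & df$class[inc_i] != "C"
    cs <- NA_real_
    if (!is.null(cluster_space) && length(i) >= min_stratum)
      cs <- mean(cluster_space[df$snp[i]], na.rm = TRUE)
    data.frame(stratum = s, n = length(i), inclusion_rate = mean(inc),
               compat_rate_with_c = if (length(inc_i)) mean(with_c) else NA_real_,
               compat_rate_without_c = if (length(inc_i)) mean(without_c) else NA_real_,
               mean_cluster_space = cs, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
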