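# Rule engine fusing concordance, Mendelian, cluster and probe evidence
# into per-SNP verdicts, the class-specific curation adjustments, and the
# integrated dataset.
#
# The original classifications were manual, by cluster-plot inspection;
# every quantitative trigger here is a config-exposed operationalization of
# the corresponding class description (see default_thresholds()).

#' Default classification thresholds
#'
#' All triggers behind the verdict ladders, exposed as one config object:
#' `mono_frac` (call share making a SNP monomorphic), `sep_min`
#' (first-platform poor-clustering floor on the minimum class-interval
#' gap), `inf_miss` and `inf_width` (first-platform poor-clustering arms
#' on missingness and class width), `err_max` (> err_max unresolvable
#' inconsistent errors = illogical segregation / class P), `cons_max` and
#' `unrelated_min` (class P consistent-error arm), `rare_max` (max null
#' carriers still "rare"), `between_trigger` (class B fraction of calls
#' between clusters), `cs_poor` + `jk_width` (class J: compressed cluster
#' space with degraded intervals), `miss_poor` (class O missingness
#' floor), `width_max` and `k_discord` (class K), `d_max` (class D: max
#' discordant duplicate pairs), `enrich_min`, `sep_ratio` and
#' `resolve_min` (class C sub-cluster evidence, separability and
#' resolution requirements), `founder_lineage` (ids anchoring classes
#' E/H).
#' @return named list.
#' @export
default_thresholds <- function() {
  list(mono_frac = 0.99, sep_min = 0.05, err_max = 2L, cons_max = 5L,
       unrelated_min = 5L, rare_max = 3L, between_trigger = 0.01,
       cs_poor = 0.6, miss_poor = 0.15, inf_miss = 0.25, inf_width = 0.3,
       width_max = 0.12, jk_width = 0.2, d_max = 2L, k_discord = 10L,
       enrich_min = 0.5, sep_ratio = 3, resolve_min = 0.8,
       founder_lineage = character())
}

# Table-1-shaped exclusion categories
.inf_categories <- c("Poor clustering", "Overlapping null and homozygous clusters",
                     "Monomorphic", "Extra cluster(s) causing illogical segregation",
                     "Illogical segregation")

.compatible_classes <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "B/G")

#' Classify a SNP on the first (Infinium-side) platform
#'
#' Decision ladder, first match wins: monomorphic; poor clustering
#' (minimum class-interval gap below `sep_min`); overlapping null and
#' homozygous clusters (null carriers above `rare_max`); extra cluster(s)
#' causing illogical segregation (more density modes than call classes plus
#' at least one unresolvable inconsistent error); illogical segregation
#' (more than `err_max` unresolvable inconsistent errors); else included.
#'
#' @param evidence list: `profile` ([cluster_profile] row), `n_inconsistent`
#'   (unresolvable count after null curation), `null_carriers`,
#'   `call_shares` (named fractions of non-missing calls per class).
#' @param th thresholds ([default_thresholds]).
#' @return list(status, category).
#' @export
classify_infinium <- function(evidence, th = default_thresholds()) {
  pr <- evidence$profile
  if (length(evidence$call_shares) && max(evidence$call_shares) >= th$mono_frac)
    return(list(status = "excluded", category = "Monomorphic"))
  poor <- (!is.na(pr$separation) && pr$n_classes >= 2L && pr$separation < th$sep_min) ||
          pr$missing_fraction > th$inf_miss ||
          (!is.na(pr$width_max) && pr$width_max > th$inf_width) ||
          (!is.na(pr$cluster_space) && pr$cluster_space < th$cs_poor &&
           !is.na(pr$width_max) && pr$width_max > th$jk_width)
  if (poor)
    return(list(status = "excluded", category = "Poor clustering"))
  nullc <- evidence$null_carriers %||% 0L
  if (nullc > th$rare_max ||
      (nullc >= 1L && (evidence$n_inconsistent %||% 0L) > th$err_max))
    return(list(status = "excluded",
                category = "Overlapping null and homozygous clusters"))
  if (pr$n_modes > pr$n_classes && (evidence$n_inconsistent %||% 0L) >= 1L)
    return(list(status = "excluded",
                category = "Extra cluster(s) causing illogical segregation"))
  if ((evidence$n_inconsistent %||% 0L) > th$err_max)
    return(list(status = "excluded", category = "Illogical segregation"))
  list(status = "included", category = NA_character_)
}

#' Classify an included SNP's second-platform (Axiom-side) data
#'
#' Decision ladder (first match wins), in order: R (absent from the
#' platform); C (separable, evidence-backed heterozygous sub-cluster whose
#' recode accounts for the SNP's discordance); J (poor differentiation:
#' compressed cluster space with degraded class intervals); K (a called
#' class concealing a merged heterozygous cluster: over-wide interval, or
#' an unseparable secondary mode alongside heavy discordance); O (a
#' cluster present on the first platform missing here, with elevated
#' missingness); B (calls between clusters, set-to-missing resolvable;
#' B/G when rare nulls co-occur); I/G (null alleles resolved via the
#' other platform / rare and hard to call); E (discordance confined to a
#' designated founder lineage); L (no differentiation at all: a single
#' mode where several classes are expected); N (extra unsupported mode
#' plus inconsistent errors); D (1-2 discordant duplicate pairs as the
#' only issue); P (more than `err_max` unresolvable inconsistent errors
#' and/or more than `cons_max` consistent errors in more than
#' `unrelated_min` unrelated individuals); Q (common null not callable);
#' M (residual irresolvable discordance); else A. Geometry-driven classes
#' precede the error-count class P, matching the class description
#' "normal clustering but ...".
#'
#' @param evidence list with components `in_axiom`, `profile` (axiom
#'   [cluster_profile] row), `n_classes_first` (call classes on the first
#'   platform), `dup_discord` (discordant duplicate pairs), `subcluster`
#'   ([detect_het_subcluster] result), `between_individuals`,
#'   `null_carriers`, `null_rare`, `null_resolved_by_axiom`,
#'   `n_inconsistent`, `n_consistent`, `n_consistent_unrelated`,
#'   `discordant_ids`.
#' @param th thresholds ([default_thresholds]).
#' @return list(class, adjustments) where adjustments is a data.frame
#'   (individual, action, new_call, reason).
#' @export
classify_axiom <- function(evidence, th = default_thresholds()) {
  adj <- function(ids, action, new_call, reason) {
    if (!length(ids)) return(NULL)
    data.frame(individual = ids, action = action, new_call = new_call,
               reason = reason, stringsAsFactors = FALSE)
  }
  no_adj <- data.frame(individual = character(), action = character(),
                       new_call = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (!isTRUE(evidence$in_axiom))
    return(list(class = "R", adjustments = no_adj))
  pr <- evidence$profile
  sub <- evidence$subcluster %||% list(proposal = NULL, unsupported = NULL)
  discord <- evidence$dup_discord %||% 0L
  nullc <- evidence$null_carriers %||% 0L

  # C first: a verified sub-cluster proposal (separable, evidence-backed,
  # and accounting for essentially all of the SNP's discordance) is a
  # rescue; anything weaker falls through to the incompatibility geometry
  # classes below. J is strictly a geometry class (compressed space plus
  # degraded class intervals); high missingness alone is the dropout
  # signature of class O, not J.
  if (!is.null(sub$proposal))
    return(list(class = "C",
                adjustments = adj(sub$proposal, "recode", "AB", "class C sub-cluster")))
  if (!is.na(pr$cluster_space) && pr$cluster_space < th$cs_poor &&
      ((!is.na(pr$width_max) && pr$width_max > th$jk_width) ||
       (!is.na(pr$separation) && pr$separation < 0)))
    return(list(class = "J", adjustments = no_adj))
  if ((!is.na(pr$width_max) && pr$width_max > th$width_max) ||
      (!is.null(sub$unsupported) && discord >= th$k_discord))
    return(list(class = "K", adjustments = no_adj))
  if ((pr$n_classes < evidence$n_classes_first || isTRUE(evidence$ab_depleted)) &&
      pr$missing_fraction > th$miss_poor)
    return(list(class = "O", adjustments = no_adj))
  if (pr$between_fraction > th$between_trigger) {
    cls <- if (nullc > 0L && isTRUE(evidence$null_rare)) "B/G" else "B"
    return(list(class = cls,
                adjustments = adj(evidence$between_individuals %||% character(),
                                  "set_missing", NA_character_,
                                  "between-cluster call")))
  }
  if (isTRUE(evidence$null_resolved_by_axiom))
    return(list(class = "I", adjustments = no_adj))
  if (nullc > 0L && isTRUE(evidence$null_rare))
    return(list(class = "G", adjustments = no_adj))
  if (discord > 0L && length(th$founder_lineage) &&
      length(evidence$discordant_ids %||% character()) &&
      all(evidence$discordant_ids %in% th$founder_lineage))
    return(list(class = "E", adjustments = no_adj))
  if (pr$n_modes <= 1L && evidence$n_classes_first >= 2L)
    return(list(class = "L", adjustments = no_adj))
  if (pr$n_modes > pr$n_classes && (evidence$n_inconsistent %||% 0L) >= 1L)
    return(list(class = "N", adjustments = no_adj))
  if (discord >= 1L && discord <= th$d_max)
    return(list(class = "D",
                adjustments = adj(evidence$discordant_ids %||% character(),
                                  "set_missing", NA_character_,
                                  "isolated discordant duplicate call")))
  if ((evidence$n_inconsistent %||% 0L) > th$err_max ||
      ((evidence$n_consistent %||% 0L) > th$cons_max &&
       (evidence$n_consistent_unrelated %||% 0L) > th$unrelated_min))
    return(list(class = "P", adjustments = no_adj))
  if (nullc > th$rare_max)
    return(list(class = "Q", adjustments = no_adj))
  if (discord > th$d_max)
    return(list(class = "M", adjustments = no_adj))
  list(class = "A", adjustments = no_adj)
}

#' Apply curation adjustments to a call matrix
#'
#' Applies set-missing and recode actions from the verdicts; idempotent
#' (reapplication changes nothing); every change is logged. An adjustment
#' naming an unknown individual or SNP is a consistency breach and aborts.
#'
#' @param matrix a [call_matrix].
#' @param adjustments data.frame: snp, individual, action
#'   (`set_missing`/`recode`), new_call, reason.
#' @return list: `matrix` (curated), `log` (data.frame snp, individual,
#'   old, new, reason - only actual changes).
#' @export
apply_adjustments <- function(matrix, adjustments) {
  m <- unclass(matrix)
  log <- list()
  if (!is.null(adjustments) && nrow(adjustments)) {
    for (k in seq_len(nrow(adjustments))) {
      s <- adjustments$snp[k]; i <- adjustments$individual[k]
      if (!(s %in% rownames(m))) ab_stop("adjustment for unknown SNP '%s'", s)
      if (!(i %in% colnames(m))) ab_stop("adjustment for unknown individual '%s'", i)
      old <- m[s, i]
      new <- if (adjustments$action[k] == "set_missing") NA_character_
             else adjustments$new_call[k]
      if (!identical(old, new)) {
        m[s, i] <- new
        log[[length(log) + 1L]] <- data.frame(
          snp = s, individual = i, old = old %||% NA_character_, new = new,
          reason = adjustments$reason[k], stringsAsFactors = FALSE)
      }
    }
  }
  list(matrix = call_matrix(m, attr(matrix, "platform")),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(snp = character(), individual = character(),
                    old = character(), new = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Integrate curated call matrices into one dataset
#'
#' Keeps compatible SNPs only. Columns present in both matrices, and
#' members of a clone group, are collapsed to one consensus column:
#' unanimity among non-missing calls, else missing (logged as a conflict).
#' Per-SNP minor-allele frequency is computed on the collapsed columns,
#' i.e. across all individuals except genetic duplicates.
#'
#' @param infinium,axiom curated [call_matrix] objects.
#' @param clone_groups list of id vectors to collapse (beyond the implicit
#'   cross-platform pairing of identically named columns).
#' @param verdicts verdict data.frame (snp, compatible).
#' @return list: `calls` (merged [call_matrix]), `maf` (named numeric),
#'   `conflicts` (data.frame snp, group), `summary` (class counts).
#' @export
integrate_platforms <- function(infinium, axiom, clone_groups = list(), verdicts) {
  snps <- verdicts$snp[verdicts$compatible]
  snps <- intersect(snps, rownames(infinium))
  a <- visible_calls(infinium[snps, , drop = FALSE])
  b <- visible_calls(axiom[intersect(snps, rownames(axiom)), , drop = FALSE])
  all_ids <- union(colnames(a), colnames(b))
  groups <- clone_groups
  grouped <- unlist(groups)
  for (id in setdiff(all_ids, grouped)) groups <- c(groups, list(id))
  out <- matrix(NA_character_, length(snps), length(groups))
  rownames(out) <- snps
  colnames(out) <- vapply(groups, `[[`, "", 1L)
  conflicts <- list()
  getcol <- function(mat, id) {
    v <- rep(NA_character_, length(snps))
    if (id %in% colnames(mat)) {
      common <- intersect(snps, rownames(mat))
      v[match(common, snps)] <- mat[common, id]
    }
    v
  }
  for (j in seq_along(groups)) {
    mem <- groups[[j]]
    cols <- cbind(vapply(mem, getcol, character(length(snps)), mat = a),
                  vapply(mem, getcol, character(length(snps)), mat = b))
    cols <- matrix(cols, nrow = length(snps))
    cons <- apply(cols, 1L, function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) == 1L) u else NA_character_
    })
    n_nonmiss <- apply(cols, 1L, function(v) length(unique(v[!is.na(v)])))
    bad <- which(n_nonmiss > 1L)
    if (length(bad))
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        snp = snps[bad], group = colnames(out)[j], stringsAsFactors = FALSE)
    out[, j] <- cons
  }
  b_count <- rowSums(out == "BB", na.rm = TRUE) * 2 + rowSums(out == "AB", na.rm = TRUE)
  n_called <- rowSums(!is.na(out))
  p <- ifelse(n_called > 0, b_count / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  list(calls = call_matrix(out, "merged"),
       maf = stats::setNames(maf, snps),
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(snp = character(), group = character(), stringsAsFactors = FALSE),
       summary = table(verdicts$class[verdicts$snp %in% snps]))
}
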