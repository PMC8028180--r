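# Cluster-plot analytics: the quantitative evidence behind classification.

#' Cluster space of a SNP
#'
#' The difference between the 5% and 95% quantiles of the observed Theta
#' values (linear-interpolation quantiles), i.e. the contrast-axis spread
#' available to the genotype clusters; robust to occasional outliers, unlike
#' max - min.
#'
#' @param theta_values numeric Theta values (NAs dropped).
#' @return scalar in \[0, 1\] (NA if fewer than 2 values); flagged with
#'   attribute `low_n` when fewer than 20 values support it.
#' @export
cluster_space <- function(theta_values) {
  x <- theta_values[!is.na(theta_values)]
  if (length(x) < 2L) return(NA_real_)
  out <- q_lin(x, 0.95) - q_lin(x, 0.05)
  if (length(x) < 20L) attr(out, "low_n") <- TRUE
  out
}

#' Detect Theta density modes
#'
#' Local maxima of a Gaussian kernel density estimate (Silverman bandwidth
#' unless given). Modes supported by less than `min_weight` of the points
#' (nearest-mode assignment) are discarded as noise. Deterministic.
#'
#' @param theta_values numeric values.
#' @param bandwidth optional KDE bandwidth.
#' @param min_weight minimum fraction of mass per retained mode.
#' @param max_modes cap on reported modes.
#' @return sorted numeric mode positions; attribute `unstable` when n < 20.
#' @export
detect_modes <- function(theta_values, bandwidth = NULL, min_weight = 0.02,
                         max_modes = 6L) {
  x <- theta_values[!is.na(theta_values)]
  if (length(x) < 2L) return(numeric(0))
  if (stats::sd(x) < 1e-9) {
    out <- mean(x)
    if (length(x) < 20L) attr(out, "unstable") <- TRUE
    return(out)
  }
  bw <- bandwidth %||% stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 512)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(loc)) loc <- which.max(y)
  modes <- d$x[loc]
  # mass-based noise guard
  assign <- apply(abs(outer(x, modes, "-")), 1L, which.min)
  w <- tabulate(assign, nbins = length(modes)) / length(x)
  modes <- modes[w >= min_weight]
  if (!length(modes)) modes <- d$x[which.max(y)]
  modes <- sort(modes)
  if (length(modes) > max_modes) modes <- modes[seq_len(max_modes)]
  if (length(x) < 20L) attr(modes, "unstable") <- TRUE
  modes
}

#' Fraction of points between clusters
#'
#' Called points farther than `band_mult` robust SDs (MAD, floored at
#' `band_floor`) from every called class's Theta mean, and lying strictly
#' between the outermost class means, are "between-cluster" calls - the
#' class-B adjustment targets. Uncalled (missing) points do not count:
#' the class describes errant calls, not no-calls.
#'
#' @param theta named numeric Theta per individual.
#' @param calls named character calls (visible codes) per individual.
#' @param band_mult band half-width in robust SDs.
#' @param band_floor lower bound on the per-class robust SD.
#' @return list: `fraction`, `individuals` (ids of between-cluster points).
#' @export
between_cluster_fraction <- function(theta, calls, band_mult = 3, band_floor = 0.03) {
  cl_all <- visible_calls(matrix(calls, ncol = 1, dimnames = list(names(calls), NULL)))[, 1L]
  ok <- !is.na(theta) & !is.na(cl_all)
  th <- theta[ok]
  cl <- cl_all[ok]
  classes <- intersect(c("AA", "AB", "BB"), unique(cl))
  if (length(classes) < 2L || !length(th))
    return(list(fraction = 0, individuals = character(0)))
  mu <- vapply(classes, function(c_) mean(th[cl == c_]), numeric(1))
  sdv <- vapply(classes, function(c_) {
    v <- th[cl == c_]
    max(stats::mad(v), band_floor)
  }, numeric(1))
  inside <- rep(FALSE, length(th))
  for (j in seq_along(classes))
    inside <- inside | abs(th - mu[j]) <= band_mult * sdv[j]
  between <- !inside & th > min(mu) & th < max(mu)
  ids <- names(theta)[ok][between]
  list(fraction = sum(between) / length(th), individuals = ids)
}

#' Per-SNP cluster profile
#'
#' Summarizes one SNP's cluster-plot geometry: per-class Theta summaries,
#' KDE mode count, cluster space, the minimum gap between adjacent class
#' 5-95% Theta intervals (negative = overlap), the maximum class interval
#' width, the between-cluster fraction, and the low-R fraction.
#'
#' @param theta,r named numeric vectors per individual.
#' @param calls named character calls per individual.
#' @param r_null_abs low-R threshold relative to the SNP median R.
#' @return one-row data.frame plus a `classes` attribute with the per-class
#'   summary table.
#' @export
cluster_profile <- function(theta, calls, r = NULL, r_null_abs = 0.1) {
  ok <- !is.na(theta)
  cl <- visible_calls(matrix(calls, ncol = 1, dimnames = list(names(calls), NULL)))[, 1L]
  classes <- intersect(c("AA", "AB", "BB"), unique(cl[!is.na(cl)]))
  bf <- between_cluster_fraction(theta, calls)
  # between-cluster points are errant calls; excluding them keeps the
  # class interval summaries from being inflated by their own outliers
  btw <- names(theta) %in% bf$individuals
  per <- do.call(rbind, lapply(classes, function(c_) {
    v <- theta[ok & !btw & !is.na(cl) & cl == c_]
    data.frame(class = c_, n = length(v), mean = mean(v),
               q5 = q_lin(v, 0.05), q95 = q_lin(v, 0.95),
               stringsAsFactors = FALSE)
  }))
  sep <- NA_real_
  if (!is.null(per) && nrow(per) >= 2L) {
    per <- per[order(per$mean), , drop = FALSE]
    gaps <- per$q5[-1L] - per$q95[-nrow(per)]
    sep <- min(gaps)
  }
  width_max <- if (!is.null(per) && nrow(per)) max(per$q95 - per$q5) else NA_real_
  modes <- detect_modes(theta[ok])
  low_r <- NA_real_
  if (!is.null(r)) {
    med <- stats::median(r[ok], na.rm = TRUE)
    low_r <- mean(r[ok] < r_null_abs * med, na.rm = TRUE)
  }
  out <- data.frame(n = sum(ok), n_classes = length(classes),
                    n_modes = length(modes),
                    cluster_space = as.numeric(cluster_space(theta[ok])),
                    separation = sep, width_max = width_max,
                    between_fraction = bf$fraction,
                    missing_fraction = mean(is.na(calls[names(theta)])),
                    low_r_fraction = low_r,
                    stringsAsFactors = FALSE)
  attr(out, "classes") <- per
  attr(out, "between_individuals") <- bf$individuals
  out
}

#' Detect a heterozygous sub-cluster hidden in a homozygote call class
#'
#' Looks, inside each homozygote-called class, for a secondary Theta mode
#' displaced toward the heterozygous center; the sub-cluster is proposed
#' for recoding to AB (the class-C curation) only when (i) the mode is
#' separable from the class's main mode (`min_gap`, `sep_ratio`), (ii) at
#' least `enrich_min` of its members carry independent evidence -
#' cross-platform duplicate discordance when available, otherwise
#' Mendelian errors - and (iii) the recode accounts for at least
#' `resolve_min` of the SNP's discordant individuals. A separable mode
#' without evidence is reported as an unsupported mode, with no recode.
#'
#' @param theta named numeric Theta per individual.
#' @param calls named character calls per individual.
#' @param error_ids individuals implicated in Mendelian errors at this SNP.
#' @param discordant_ids individuals with discordant duplicate calls here.
#' @param het_center Theta position of the heterozygous cluster.
#' @param enrich_min evidence fraction required among members.
#' @param sep_ratio separability floor: the gap between the two modes must
#'   be at least `sep_ratio` times the larger of the two sides' robust SDs
#'   (MAD of the points assigned to each mode, floored at 0.01), otherwise
#'   the modes are considered merged (overlapping, class-K territory) and
#'   no recode is proposed.
#' @return list: `proposal` (ids to recode AB, or NULL), `from_class`,
#'   `unsupported` (ids of an evidence-free mode, or NULL).
#' @export
detect_het_subcluster <- function(theta, calls, error_ids = character(),
                                  discordant_ids = character(),
                                  het_center = 0.5, enrich_min = 0.5,
                                  sep_ratio = 3, min_gap = 0.08,
                                  resolve_min = 0.8) {
  cl <- visible_calls(matrix(calls, ncol = 1, dimnames = list(names(calls), NULL)))[, 1L]
  # discordance is the sharper evidence when present: a genuinely miscalled
  # sub-cluster is discordant with its duplicates, whereas Mendelian errors
  # also name the innocent relatives of miscalled individuals
  evidence <- if (length(discordant_ids)) discordant_ids else error_ids
  for (hom in c("AA", "BB")) {
    mem_all <- names(theta)[!is.na(cl) & cl == hom & !is.na(theta)]
    if (length(mem_all) < 8L) next
    v <- theta[mem_all]
    if (stats::sd(v) < 1e-9) next
    modes <- detect_modes(v, min_weight = 0.05)
    if (length(modes) < 2L) next
    # candidate = mode closest to the het center; main = farthest from it
    cand <- modes[which.min(abs(modes - het_center))]
    main <- modes[which.max(abs(modes - het_center))]
    if (abs(cand - main) < min_gap) next  # noise shoulder, not a cluster
    assign_cand <- abs(v - cand) < abs(v - main)
    spread <- max(stats::mad(v[assign_cand]), stats::mad(v[!assign_cand]), 0.01,
                  na.rm = TRUE)
    if (abs(cand - main) / spread < sep_ratio) next
    members <- mem_all[assign_cand]
    if (!length(members)) next
    frac <- mean(members %in% evidence)
    supported <- length(evidence) && frac >= enrich_min
    # the recode must account for (almost) all of the discordance: a
    # sub-cluster explaining only part of it points at a broader problem
    # (poor differentiation), not a mislabeled heterozygous cluster
    if (supported && length(discordant_ids))
      supported <- mean(discordant_ids %in% members) >= resolve_min
    if (supported)
      return(list(proposal = members, from_class = hom, unsupported = NULL))
    return(list(proposal = NULL, from_class = hom, unsupported = members))
  }
  list(proposal = NULL, from_class = NA_character_, unsupported = NULL)
}
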