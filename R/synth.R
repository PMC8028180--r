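# Synthetic two-platform SNP-array data with planted artifacts.
#
# The generator states a small world: pedigreed diploid inheritance with
# Haldane recombination over a simulated map, a three-cluster Theta geometry
# per SNP, and artifact mechanisms (secondary polymorphisms with a
# 3'-distance-dependent binding penalty, null alleles as a third allele N
# with near-zero signal, paralogous binding that adds constant off-target
# signal) whose downstream phenotypes every analysis module must recover.

#' Platform signal model
#'
#' @param name `"infinium"` (50-mer probes) or `"axiom"` (35-mer probes).
#' @param probe_len probe length in nucleotides.
#' @param cluster_centers noise-free Theta positions of the AA/AB/BB
#'   clusters; must be strictly increasing in \[0, 1\].
#' @param theta_sd Gaussian noise SD on the raw allelic-contrast axis.
#' @param r_mean,r_sd scale and noise of the normalized total intensity R
#'   (a two-allele-dosage individual with no artifacts has expected R =
#'   `r_mean`).
#' @param null_r_factor signal emitted by a null (N) allele relative to a
#'   functional allele; near zero.
#' @param lambda decay length (nt) of the secondary-polymorphism penalty:
#'   binding retention at distance d from the 3' end is `1 - exp(-d/lambda)`
#'   (1 beyond the probe). The 35-mer chemistry is more sensitive near the
#'   3' end (larger lambda).
#' @param paralog_sensitivity platform-specific multiplier on the paralog
#'   signal fraction; the shorter-probe platform is fully exposed while the
#'   50-mer chemistry partially suppresses off-target binding.
#' @return list of class `platform_model`.
#' @export
platform_model <- function(name = c("infinium", "axiom"),
                           probe_len = NULL,
                           cluster_centers = c(0.05, 0.5, 0.95),
                           theta_sd = 0.03, r_mean = 1, r_sd = 0.08,
                           null_r_factor = 0.05,
                           lambda = NULL,
                           paralog_sensitivity = NULL) {
  name <- match.arg(name)
  probe_len <- probe_len %||% if (name == "infinium") 50L else 35L
  lambda <- lambda %||% if (name == "infinium") 3 else 8
  paralog_sensitivity <- paralog_sensitivity %||% if (name == "infinium") 0.35 else 1
  stopifnot(length(cluster_centers) == 3L, all(diff(cluster_centers) > 0),
            all(cluster_centers >= 0 & cluster_centers <= 1),
            theta_sd >= 0, r_mean > 0, r_sd >= 0,
            null_r_factor >= 0, null_r_factor < 1)
  structure(list(name = name, probe_len = as.integer(probe_len),
                 cluster_centers = cluster_centers, theta_sd = theta_sd,
                 r_mean = r_mean, r_sd = r_sd, null_r_factor = null_r_factor,
                 lambda = lambda, paralog_sensitivity = paralog_sensitivity),
            class = "platform_model")
}

#' Secondary-polymorphism binding retention
#'
#' Retention is non-decreasing in the distance d from the probe's 3' end
#' (d = 1 is the base adjacent to the target SNP) and 1 beyond the probe.
#' @param d distance(s) from the 3' end, >= 1.
#' @param platform a [platform_model].
#' @return retention in \[0, 1\].
#' @export
retention <- function(d, platform) {
  stopifnot(all(d >= 1))
  ifelse(d > platform$probe_len, 1, 1 - exp(-d / platform$lambda))
}

#' Per-SNP probe artifact plan
#'
#' @param snp_id SNP identifier.
#' @param secondary data.frame with columns `d` (distance from 3' end, >= 1),
#'   `carrier_frequency` in \[0, 1\] and `linked_allele` (`"A"`, `"B"` or NA;
#'   when set, carriage rides on haplotypes bearing that marker allele,
#'   otherwise carriage segregates as an independent linked flag).
#' @param null_allele_frequency population frequency of the null haplotype.
#' @param paralog_signal_fraction fraction s in \[0, 0.5\] of total signal
#'   contributed by a fixed non-target locus.
#' @param paralog_allele marker allele the paralog emits (`"A"` or `"B"`).
#' @param theta_sd_mult named per-platform multipliers on theta noise.
#' @param het_dropout named per-platform logicals: heterozygote
#'   hybridization collapse (R driven near zero for true AB individuals).
#' @return list of class `probe_effect`.
#' @export
probe_effect <- function(snp_id,
                         secondary = NULL,
                         null_allele_frequency = 0,
                         paralog_signal_fraction = 0,
                         paralog_allele = "A",
                         theta_sd_mult = c(infinium = 1, axiom = 1),
                         het_dropout = c(infinium = FALSE, axiom = FALSE)) {
  stopifnot(null_allele_frequency >= 0, null_allele_frequency <= 1,
            paralog_signal_fraction >= 0, paralog_signal_fraction <= 0.5,
            paralog_allele %in% c("A", "B"))
  if (!is.null(secondary)) {
    stopifnot(all(c("d", "carrier_frequency") %in% names(secondary)),
              all(secondary$d >= 1))
    if (is.null(secondary$linked_allele)) secondary$linked_allele <- NA_character_
    # carrier frequency may be NA for allele-linked polymorphisms (it is
    # then the linked allele's frequency)
    cf <- secondary$carrier_frequency
    free <- is.na(secondary$linked_allele)
    stopifnot(all(!is.na(cf[free])), all(cf[free] >= 0 & cf[free] <= 1),
              all(is.na(cf) | (cf >= 0 & cf <= 1)))
  }
  structure(list(snp_id = snp_id, secondary = secondary,
                 null_allele_frequency = null_allele_frequency,
                 paralog_signal_fraction = paralog_signal_fraction,
                 paralog_allele = paralog_allele,
                 theta_sd_mult = theta_sd_mult, het_dropout = het_dropout),
            class = "probe_effect")
}

#' Simulation configuration
#'
#' @param n_founders number of unrelated founders (> 0).
#' @param families data.frame with columns `mother`, `father`,
#'   `n_offspring`; parents must be founders or offspring of earlier rows.
#' @param n_snps total SNP count (> 0), split evenly across linkage groups.
#' @param n_linkage_groups number of linkage groups.
#' @param map_length_cM genetic length per linkage group.
#' @param founder_maf_range interval in (0, 0.5\] for the per-SNP B-allele
#'   frequency among founders.
#' @param platforms list with entries `infinium` and `axiom`
#'   ([platform_model]s).
#' @param effects named list of [probe_effect]s keyed by SNP id.
#' @param duplicates character vector of individuals emitted on both
#'   platforms for duplicate screening (in this generator every individual
#'   is assayed on both platforms; `duplicates` marks the designated
#'   replicate accessions).
#' @param call_error_rate per-call probability of a random miscall, in
#'   \[0, 1).
#' @param seed integer seed; all outputs are deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders, families, n_snps,
                       n_linkage_groups = 3, map_length_cM = 80,
                       founder_maf_range = c(0.2, 0.5),
                       platforms = list(infinium = platform_model("infinium"),
                                        axiom = platform_model("axiom")),
                       effects = list(),
                       duplicates = character(),
                       call_error_rate = 5e-4,
                       seed = 1L) {
  if (!is_count(n_founders) || n_founders < 1) ab_stop("need >= 1 founder")
  if (!is_count(n_snps) || n_snps < 1) ab_stop("need >= 1 SNP")
  stopifnot(founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            founder_maf_range[1] <= founder_maf_range[2],
            call_error_rate >= 0, call_error_rate < 1)
  founder_ids <- sprintf("F%03d", seq_len(n_founders))
  known <- founder_ids
  if (!is.null(families) && nrow(families)) {
    for (i in seq_len(nrow(families))) {
      if (!(families$mother[i] %in% known) || !(families$father[i] %in% known))
        ab_stop("family %d: parents must exist among founders or prior offspring", i)
      known <- c(known, sprintf("X%02d_O%02d", i, seq_len(families$n_offspring[i])))
    }
  }
  structure(list(n_founders = n_founders, families = families, n_snps = n_snps,
                 n_linkage_groups = n_linkage_groups, map_length_cM = map_length_cM,
                 founder_maf_range = founder_maf_range, platforms = platforms,
                 effects = effects, duplicates = duplicates,
                 call_error_rate = call_error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# allele codes in haplotype matrices
.AL_A <- 1L; .AL_B <- 2L; .AL_N <- 3L

#' Simulate pedigreed true genotypes
#'
#' Founders are drawn from Hardy-Weinberg proportions at per-SNP MAF;
#' gametes recombine per linkage group with crossover probability between
#' adjacent SNPs given by Haldane's map function of the cM gap d,
#' \eqn{(1 - e^{-2d/100})/2}. Null haplotypes segregate as a third
#' allele N where the artifact plan specifies a positive null frequency.
#' Offspring are Mendelian-consistent with their parents by construction.
#'
#' @param config a [sim_config].
#' @return list of class `truth_bundle`: `map`, haplotype matrices `hap1`,
#'   `hap2` (SNP x individual, codes 1=A, 2=B, 3=N), carriage flags `car1`,
#'   `car2` for unlinked secondary polymorphisms, `genotypes` (true
#'   null-aware [call_matrix]), `pedigree`, `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_lg <- config$n_linkage_groups
  per_lg <- diff(round(seq(0, config$n_snps, length.out = n_lg + 1L)))
  map <- do.call(rbind, lapply(seq_len(n_lg), function(g) {
    n <- per_lg[g]
    bp <- sort(sample.int(3e7, n))
    cm <- if (n > 1) (bp - bp[1]) / max(bp[n] - bp[1], 1) * config$map_length_cM
          else rep(0, n)
    data.frame(snp = character(n), lg = sprintf("LG%d", g), cM = cm, bp = bp,
               stringsAsFactors = FALSE)
  }))
  map$snp <- sprintf("SNP%05d", seq_len(nrow(map)))
  rownames(map) <- NULL
  n_snp <- nrow(map)

  maf <- stats::runif(n_snp, config$founder_maf_range[1], config$founder_maf_range[2])
  null_f <- rep(0, n_snp)
  # unlinked secondary-polymorphism carrier frequency per SNP (0 = none)
  sec_f <- rep(0, n_snp)
  for (ef in config$effects) {
    i <- match(ef$snp_id, map$snp)
    if (is.na(i)) ab_stop("probe_effect for unknown SNP '%s'", ef$snp_id)
    null_f[i] <- ef$null_allele_frequency
    if (!is.null(ef$secondary)) {
      un <- is.na(ef$secondary$linked_allele)
      if (any(un)) sec_f[i] <- max(ef$secondary$carrier_frequency[un])
    }
  }
  # allow maf overrides (e.g. monomorphic plants) via attribute on effects
  maf_override <- attr(config$effects, "maf_override")
  if (!is.null(maf_override)) {
    i <- match(names(maf_override), map$snp)
    maf[i[!is.na(i)]] <- unname(maf_override[!is.na(i)])
  }

  founder_ids <- sprintf("F%03d", seq_len(config$n_founders))
  draw_hap <- function() {
    al <- ifelse(stats::runif(n_snp) < maf, .AL_B, .AL_A)
    nn <- null_f > 0 & stats::runif(n_snp) < null_f
    al[nn] <- .AL_N
    car <- sec_f > 0 & stats::runif(n_snp) < sec_f
    list(al = al, car = car)
  }
  ids <- founder_ids
  hap1 <- matrix(0L, n_snp, 0); hap2 <- matrix(0L, n_snp, 0)
  car1 <- matrix(FALSE, n_snp, 0); car2 <- matrix(FALSE, n_snp, 0)
  for (f in founder_ids) {
    h <- draw_hap(); g <- draw_hap()
    hap1 <- cbind(hap1, h$al); hap2 <- cbind(hap2, g$al)
    car1 <- cbind(car1, h$car); car2 <- cbind(car2, g$car)
  }

  # per-LG crossover probabilities between adjacent SNPs (Haldane)
  lg_idx <- split(seq_len(n_snp), map$lg)
  rec_p <- lapply(lg_idx, function(ix) {
    d <- diff(map$cM[ix])
    (1 - exp(-2 * d / 100)) / 2
  })

  make_gamete <- function(col) {
    sel <- integer(n_snp)
    for (g in seq_along(lg_idx)) {
      ix <- lg_idx[[g]]
      n <- length(ix)
      s <- integer(n)
      s[1] <- sample.int(2L, 1L)
      if (n > 1) {
        x <- stats::runif(n - 1) < rec_p[[g]]
        s <- 1L + (cumsum(c(s[1] - 1L, x)) %% 2L)
      }
      sel[ix] <- s
    }
    al <- ifelse(sel == 1L, hap1[, col], hap2[, col])
    car <- ifelse(sel == 1L, car1[, col], car2[, col])
    list(al = al, car = as.logical(car))
  }

  if (!is.null(config$families) && nrow(config$families)) {
    for (i in seq_len(nrow(config$families))) {
      fam <- config$families[i, ]
      mi <- match(fam$mother, ids); fi <- match(fam$father, ids)
      for (k in seq_len(fam$n_offspring)) {
        gm <- make_gamete(mi); gf <- make_gamete(fi)
        ids <- c(ids, sprintf("X%02d_O%02d", i, k))
        hap1 <- cbind(hap1, gm$al); hap2 <- cbind(hap2, gf$al)
        car1 <- cbind(car1, gm$car); car2 <- cbind(car2, gf$car)
      }
    }
  }
  colnames(hap1) <- colnames(hap2) <- colnames(car1) <- colnames(car2) <- ids
  rownames(hap1) <- rownames(hap2) <- rownames(car1) <- rownames(car2) <- map$snp

  ped_entries <- data.frame(id = ids, mother = NA_character_, father = NA_character_,
                            stringsAsFactors = FALSE)
  if (!is.null(config$families) && nrow(config$families)) {
    for (i in seq_len(nrow(config$families))) {
      kid <- grepl(sprintf("^X%02d_", i), ids)
      ped_entries$mother[kid] <- config$families$mother[i]
      ped_entries$father[kid] <- config$families$father[i]
    }
  }
  ped <- pedigree(ped_entries, clone_groups = list())

  geno <- true_genotype_codes(hap1, hap2)
  structure(list(map = map, hap1 = hap1, hap2 = hap2, car1 = car1, car2 = car2,
                 genotypes = call_matrix(geno, "merged"), pedigree = ped,
                 maf = stats::setNames(maf, map$snp), config = config),
            class = "truth_bundle")
}

# haplotype pair -> null-aware genotype code
true_genotype_codes <- function(hap1, hap2) {
  lo <- pmin(hap1, hap2); hi <- pmax(hap1, hap2)
  code <- matrix(NA_character_, nrow(hap1), ncol(hap1),
                 dimnames = dimnames(hap1))
  code[lo == .AL_A & hi == .AL_A] <- "AA"
  code[lo == .AL_A & hi == .AL_B] <- "AB"
  code[lo == .AL_B & hi == .AL_B] <- "BB"
  code[lo == .AL_A & hi == .AL_N] <- "AN"
  code[lo == .AL_B & hi == .AL_N] <- "BN"
  code[lo == .AL_N & hi == .AL_N] <- "NN*"
  code
}

# piecewise-linear map from the raw contrast axis (0, 0.5, 1 for pure
# AA/AB/BB) onto the platform's cluster centers
.map_theta <- function(raw, centers) {
  lo <- raw <= 0.5
  out <- numeric(length(raw))
  out[lo] <- centers[1] + (raw[lo] / 0.5) * (centers[2] - centers[1])
  out[!lo] <- centers[2] + ((raw[!lo] - 0.5) / 0.5) * (centers[3] - centers[2])
  out
}

#' Simulate cluster-plot intensities for one platform
#'
#' Allele signals are dosage-proportional, scaled by the
#' secondary-polymorphism retention for carrying haplotypes and by
#' `null_r_factor` for N alleles; a paralogous locus adds constant signal on
#' its emitted allele. Theta is the (2/pi) arctan of the B/A signal ratio
#' mapped onto the platform's cluster centers; R is the mean allele signal
#' scaled by `r_mean` with Gaussian noise.
#'
#' @param truth a `truth_bundle` from [simulate_genotypes].
#' @param platform a [platform_model].
#' @param effects named list of [probe_effect]s (defaults to the plan in the
#'   truth's config).
#' @param seed seed for the noise draws.
#' @param noise set `FALSE` for the noise-free signal model (used by tests).
#' @return intensity data.frame (snp, individual, theta, r).
#' @export
simulate_intensities <- function(truth, platform, effects = truth$config$effects,
                                 seed = truth$config$seed + 1L, noise = TRUE) {
  stopifnot(inherits(truth, "truth_bundle"), inherits(platform, "platform_model"))
  for (ef in effects)
    if (!(ef$snp_id %in% truth$map$snp))
      ab_stop("probe_effect for unknown SNP '%s'", ef$snp_id)
  set.seed(seed)
  n_snp <- nrow(truth$map); n_ind <- ncol(truth$hap1)
  ids <- colnames(truth$hap1)
  ef_idx <- stats::setNames(effects, vapply(effects, `[[`, "", "snp_id"))

  theta <- matrix(0, n_snp, n_ind); rr <- matrix(0, n_snp, n_ind)
  for (i in seq_len(n_snp)) {
    snp <- truth$map$snp[i]
    ef <- ef_idx[[snp]]
    w1 <- rep(1, n_ind); w2 <- rep(1, n_ind)
    a1 <- truth$hap1[i, ]; a2 <- truth$hap2[i, ]
    if (!is.null(ef) && !is.null(ef$secondary)) {
      for (k in seq_len(nrow(ef$secondary))) {
        ret <- retention(ef$secondary$d[k], platform)
        la <- ef$secondary$linked_allele[k]
        if (is.na(la)) {
          w1 <- w1 * ifelse(truth$car1[i, ], ret, 1)
          w2 <- w2 * ifelse(truth$car2[i, ], ret, 1)
        } else {
          lac <- if (la == "A") .AL_A else .AL_B
          w1 <- w1 * ifelse(a1 == lac, ret, 1)
          w2 <- w2 * ifelse(a2 == lac, ret, 1)
        }
      }
    }
    nullw <- platform$null_r_factor
    w1[a1 == .AL_N] <- nullw; w2[a2 == .AL_N] <- nullw
    # N alleles emit faint non-specific background split over both channels
    a_sig <- (a1 == .AL_A) * w1 + (a2 == .AL_A) * w2 +
             ((a1 == .AL_N) * w1 + (a2 == .AL_N) * w2) / 2
    b_sig <- (a1 == .AL_B) * w1 + (a2 == .AL_B) * w2 +
             ((a1 == .AL_N) * w1 + (a2 == .AL_N) * w2) / 2
    if (!is.null(ef) && ef$paralog_signal_fraction > 0) {
      s <- ef$paralog_signal_fraction * platform$paralog_sensitivity
      p <- 2 * s / (1 - s)
      if (ef$paralog_allele == "A") a_sig <- a_sig + p else b_sig <- b_sig + p
    }
    raw <- ifelse(a_sig + b_sig <= 0, 0.5, (2 / pi) * atan2(b_sig, a_sig))
    sdm <- 1
    if (!is.null(ef)) sdm <- unname(ef$theta_sd_mult[platform$name]) %||% 1
    if (noise && platform$theta_sd > 0)
      raw <- raw + stats::rnorm(n_ind, 0, platform$theta_sd * sdm)
    raw <- pmin(1, pmax(0, raw))
    theta[i, ] <- .map_theta(raw, platform$cluster_centers)
    r <- (a_sig + b_sig) / 2 * platform$r_mean
    if (!is.null(ef) && isTRUE(unname(ef$het_dropout[platform$name]))) {
      het <- (a1 == .AL_A & a2 == .AL_B) | (a1 == .AL_B & a2 == .AL_A)
      r[het] <- r[het] * 0.02
    }
    if (noise && platform$r_sd > 0) r <- r + stats::rnorm(n_ind, 0, platform$r_sd)
    rr[i, ] <- pmax(0, r)
  }
  data.frame(snp = rep(truth$map$snp, times = n_ind),
             individual = rep(ids, each = n_snp),
             theta = as.vector(theta), r = as.vector(rr),
             stringsAsFactors = FALSE)
}

# deterministic 1-D Gaussian mixture EM with fixed initialization
.fit_gmm1d <- function(x, mu0, maxit = 60L, tol = 1e-7) {
  k <- length(mu0)
  n <- length(x)
  mu <- mu0; sd <- rep(0.05, k); w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    dens <- matrix(dens, n, k)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    post <- dens / tot
    nk <- colSums(post)
    w <- nk / n
    keep <- nk > 1e-8
    mu[keep] <- colSums(post[, keep, drop = FALSE] * x) / nk[keep]
    sd[keep] <- sqrt(colSums(post[, keep, drop = FALSE] *
                             (outer(x, mu[keep], "-"))^2) / nk[keep])
    sd <- pmax(sd, 1e-3)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd, w = w, loglik = ll, post = post, k = k)
}

#' Call genotypes from intensities by 1-D Gaussian mixtures on Theta
#'
#' Per SNP, mixtures with 1-3 components are fitted on Theta (fixed
#' initialization at the platform's cluster centers; model selection by
#' BIC) and components are assigned to AA/AB/BB by nearest platform center.
#' Calls with maximum posterior below `p_min` or with R below
#' `r_min_frac` times the SNP's reference R are set missing; the reference
#' is the SNP median floored at half the experiment-wide median, so a SNP
#' where most of the cohort has failed hybridization still gates its
#' failed samples out. Deterministic.
#'
#' @param intens intensity data.frame (snp, individual, theta, r).
#' @param platform a [platform_model].
#' @param p_min posterior floor for a confident call.
#' @param r_min_frac missing-call floor on R relative to the SNP median.
#' @return a [call_matrix] tagged with the platform name.
#' @export
call_genotypes <- function(intens, platform, p_min = 0.85, r_min_frac = 0.25) {
  stopifnot(inherits(platform, "platform_model"))
  centers <- platform$cluster_centers
  snps <- unique(intens$snp)
  inds <- unique(intens$individual)
  th <- matrix(NA_real_, length(snps), length(inds), dimnames = list(snps, inds))
  rm_ <- th
  th[cbind(match(intens$snp, snps), match(intens$individual, inds))] <- intens$theta
  rm_[cbind(match(intens$snp, snps), match(intens$individual, inds))] <- intens$r
  out <- matrix(NA_character_, length(snps), length(inds), dimnames = list(snps, inds))
  classes <- c("AA", "AB", "BB")
  inits <- list(mean(centers), centers[c(1, 3)], centers)
  global_med_r <- stats::median(intens$r, na.rm = TRUE)
  for (i in seq_along(snps)) {
    x <- th[i, ]; r <- rm_[i, ]
    ok <- !is.na(x)
    if (!any(ok)) { ab_warn("SNP %s: all intensities missing", snps[i]); next }
    xs <- x[ok]
    fits <- lapply(inits, function(m0) .fit_gmm1d(xs, m0))
    bic <- vapply(fits, function(f) -2 * f$loglik + (3 * f$k - 1) * log(length(xs)),
                  numeric(1))
    fit <- fits[[which.min(bic)]]
    # components -> classes by nearest platform center; a tie between equal
    # means is broken in favor of the heavier component (it wins the
    # posterior anyway)
    comp_class <- vapply(fit$mu, function(m) which.min(abs(m - centers)), integer(1))
    post_max <- apply(fit$post, 1, max)
    comp_best <- apply(fit$post, 1, which.max)
    call <- classes[comp_class[comp_best]]
    call[post_max < p_min] <- NA_character_
    ref_r <- max(stats::median(r[ok]), 0.5 * global_med_r)
    low_r <- r[ok] < r_min_frac * ref_r
    call[low_r] <- NA_character_
    out[i, ok] <- call
  }
  call_matrix(out, platform = platform$name)
}

#' Perturb calls with random genotyping error
#'
#' Each non-missing call is replaced, with probability `rate`, by one of the
#' two other visible codes (chosen uniformly). Emulates residual
#' auto-calling error.
#' @param cm a [call_matrix].
#' @param rate per-call error probability.
#' @param seed seed.
#' @return a [call_matrix].
#' @export
perturb_calls <- function(cm, rate, seed = 1L) {
  if (rate <= 0) return(cm)
  set.seed(seed)
  m <- unclass(cm)
  idx <- which(!is.na(m) & m %in% c("AA", "AB", "BB") & stats::runif(length(m)) < rate)
  for (j in idx) {
    others <- setdiff(c("AA", "AB", "BB"), m[[j]])
    m[[j]] <- others[sample.int(2L, 1L)]
  }
  call_matrix(m, attr(cm, "platform"))
}
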