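#' @import data.table
NULL

# Canonical call codes. Null-aware codes extend the visible codes so that a
# curated matrix stays distinguishable from an uncurated one: "AN"/"BN" are
# heterozygous-null (visible as AA/BB on the array), "NN*" is the
# double-null (near-zero intensity, typically not called at all).
.call_codes <- c("AA", "AB", "BB", "AN", "BN", "NN*")

#' Construct a validated call matrix
#'
#' A call matrix holds biallelic genotype calls (rows = SNPs, columns =
#' individuals) in the codes `AA`, `AB`, `BB`, missing (`NA`), plus the
#' null-aware codes `AN`, `BN`, `NN*` produced by null-allele curation.
#'
#' @param calls character matrix with rownames (SNP ids) and colnames
#'   (individual ids); missing calls are `NA`.
#' @param platform one of `"infinium"`, `"axiom"`, `"merged"`.
#' @return an object of class `call_matrix` (a character matrix with a
#'   `platform` attribute).
#' @export
call_matrix <- function(calls, platform = c("merged", "infinium", "axiom")) {
  platform <- match.arg(platform)
  if (!is.matrix(calls) || !is.character(calls))
    ab_stop("calls must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    ab_stop("calls must have SNP rownames and individual colnames")
  if (anyDuplicated(rownames(calls)))
    ab_stop("duplicated SNP ids: %s",
            paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    ab_stop("duplicated individual ids: %s",
            paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% .call_codes)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    ab_stop("invalid call token '%s' at SNP '%s', individual '%s'",
            calls[bad][1L], rownames(calls)[i[1L]], colnames(calls)[i[2L]])
  }
  structure(calls, platform = platform, class = c("call_matrix", class(calls)))
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d SNPs x %d individuals [%s], %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "platform"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype call matrix
#'
#' Reads a TSV/CSV file with a header of individual ids and a first column
#' of SNP ids. Unknown tokens are an error, never silently coerced to
#' missing; the tokens that *do* mean missing are supplied via `dialect`.
#'
#' @param path file path (TSV by default; `.csv` files use comma).
#' @param dialect named list; `missing_tokens` is a character vector of
#'   tokens mapped to missing (default `c("NC", "--", "NoCall", "-")`).
#' @param platform platform tag to attach.
#' @return a [call_matrix].
#' @export
read_call_matrix <- function(path, dialect = list(), platform = "merged") {
  miss <- dialect$missing_tokens %||% c("NC", "--", "NoCall", "-")
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                          na.strings = NULL, fill = FALSE)
  if (ncol(dt) < 2L) ab_stop("%s: expected SNP id column plus >=1 individual", path)
  snps <- dt[[1L]]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- snps
  m[m %in% miss | m == ""] <- NA_character_
  bad <- !is.na(m) & !(m %in% .call_codes)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    ab_stop("%s: unknown call token '%s' (row %s, column %s)",
            path, m[bad][1L], snps[i[1L]], colnames(m)[i[2L]])
  }
  call_matrix(m, platform = platform)
}

#' Write a call matrix (missing as `NC`)
#' @param x a [call_matrix]
#' @param path output path; `.csv` writes comma-separated.
#' @export
write_call_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- unclass(x)
  m[is.na(m)] <- "NC"
  dt <- data.table::data.table(snp = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read a per-sample intensity table
#'
#' Expects columns `snp`, `individual`, `theta`, `r`; Theta must lie in
#' \[0, 1\] and R must be non-negative; (snp, individual) must be unique.
#' @param path TSV path.
#' @return data.frame with the four canonical columns.
#' @export
read_intensity_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("snp", "individual", "theta", "r")
  if (!all(need %in% names(dt)))
    ab_stop("%s: intensity table needs columns %s", path, paste(need, collapse = ", "))
  dt <- as.data.frame(dt)[, need]
  dt$snp <- as.character(dt$snp); dt$individual <- as.character(dt$individual)
  if (any(!is.finite(dt$theta)) || any(dt$theta < 0 | dt$theta > 1))
    ab_stop("%s: theta outside [0,1] (first bad row %d)", path,
            which(!is.finite(dt$theta) | dt$theta < 0 | dt$theta > 1)[1L])
  if (any(!is.finite(dt$r)) || any(dt$r < 0))
    ab_stop("%s: r must be >= 0 (first bad row %d)", path,
            which(!is.finite(dt$r) | dt$r < 0)[1L])
  if (anyDuplicated(dt[c("snp", "individual")]))
    ab_stop("%s: duplicated (snp, individual) pair", path)
  dt
}

#' @rdname read_intensity_table
#' @param x intensity data.frame
#' @export
write_intensity_table <- function(x, path) {
  data.table::fwrite(x[, c("snp", "individual", "theta", "r")], path, sep = "\t")
  invisible(path)
}

#' Construct a validated pedigree
#'
#' @param entries data.frame with columns `id`, `mother`, `father` (NA =
#'   unknown). Parent references must resolve to other ids or be unknown and
#'   the ancestry graph must be acyclic.
#' @param clone_groups optional list of character vectors; disjoint sets of
#'   individual ids that represent one genotype (duplicate accessions).
#' @return data.frame of class `pedigree` with a `clone_groups` attribute.
#' @export
pedigree <- function(entries, clone_groups = list()) {
  need <- c("id", "mother", "father")
  if (!all(need %in% names(entries))) ab_stop("pedigree needs columns id, mother, father")
  entries <- as.data.frame(entries)[, need]
  for (j in need) entries[[j]] <- as.character(entries[[j]])
  entries$mother[entries$mother %in% c("", "NA")] <- NA_character_
  entries$father[entries$father %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(entries$id))
    ab_stop("duplicated pedigree id: %s", entries$id[duplicated(entries$id)][1L])
  refs <- c(entries$mother, entries$father)
  unresolved <- setdiff(refs[!is.na(refs)], entries$id)
  if (length(unresolved))
    ab_stop("parent id(s) not in pedigree: %s", paste(unresolved, collapse = ", "))
  # Kahn topological sort to prove acyclicity.
  order <- character(0); known <- character(0)
  remaining <- entries
  repeat {
    ready <- (is.na(remaining$mother) | remaining$mother %in% known) &
             (is.na(remaining$father) | remaining$father %in% known)
    if (!any(ready)) break
    known <- c(known, remaining$id[ready])
    order <- c(order, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  if (nrow(remaining))
    ab_stop("pedigree contains a cycle involving: %s",
            paste(utils::head(remaining$id, 5L), collapse = ", "))
  if (length(clone_groups)) {
    all_members <- unlist(clone_groups)
    if (anyDuplicated(all_members)) ab_stop("clone groups must be disjoint")
  }
  structure(entries, clone_groups = clone_groups, topo_order = order,
            class = c("pedigree", "data.frame"))
}

#' Read a pedigree CSV (`id,mother,father[,clone_group]`)
#'
#' Empty fields mean unknown parents. An optional `clone_group` column
#' labels duplicate accessions of one genotype.
#' @param path CSV path.
#' @return a [pedigree].
#' @export
read_pedigree <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                        colClasses = "character", na.strings = NULL))
  if (!all(c("id", "mother", "father") %in% names(dt)))
    ab_stop("%s: pedigree needs columns id, mother, father", path)
  cg <- list()
  if ("clone_group" %in% names(dt)) {
    lab <- dt$clone_group
    keep <- !is.na(lab) & lab != ""
    cg <- split(dt$id[keep], lab[keep])
    cg <- unname(cg[lengths(cg) >= 1L])
  }
  pedigree(dt[, c("id", "mother", "father")], clone_groups = cg)
}

#' @rdname read_pedigree
#' @param ped a [pedigree]
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  cg <- attr(ped, "clone_groups")
  if (length(cg)) {
    lab <- rep(NA_character_, nrow(df))
    for (k in seq_along(cg)) lab[df$id %in% cg[[k]]] <- sprintf("G%03d", k)
    df$clone_group <- lab
  }
  df[is.na(df)] <- ""
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Read a genetic map (`snp  lg  cM  bp`)
#'
#' Within each linkage group the stored order must be non-decreasing in cM
#' (ties allowed); `bp` may be missing (NA) for SNPs without a physical
#' anchor.
#' @param path TSV path.
#' @return data.frame with columns snp, lg, cM, bp.
#' @export
read_genetic_map <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("snp", "lg", "cM", "bp")
  if (!all(need %in% names(dt))) ab_stop("%s: map needs columns %s", path,
                                         paste(need, collapse = ", "))
  dt <- dt[, need]
  dt$snp <- as.character(dt$snp); dt$lg <- as.character(dt$lg)
  if (anyDuplicated(dt$snp)) ab_stop("%s: duplicated SNP in map", path)
  if (any(!is.finite(dt$cM)) || any(dt$cM < 0)) ab_stop("%s: cM must be >= 0", path)
  for (g in unique(dt$lg)) {
    cm <- dt$cM[dt$lg == g]
    if (is.unsorted(cm)) ab_stop("%s: stored order not non-decreasing in cM on LG %s", path, g)
  }
  dt
}

#' @rdname read_genetic_map
#' @param map map data.frame
#' @export
write_genetic_map <- function(map, path) {
  data.table::fwrite(map[, c("snp", "lg", "cM", "bp")], path, sep = "\t")
  invisible(path)
}

#' Read tabular BLAST output (outfmt 6)
#'
#' Standard 12 columns: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore. Minus-strand hits
#' (sstart > send) are normalized so sstart <= send with `strand = "-"`.
#' @param path path to the tab-separated hit table (may be empty).
#' @return data.frame of hits with a `strand` column.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(), character(), numeric(), integer(), integer(),
                 integer(), integer(), integer(), integer(), integer(),
                 numeric(), numeric(), character(), stringsAsFactors = FALSE),
      c(cols, "strand")))
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(dt) != 12L)
    ab_stop("%s: expected 12 tab-separated columns (outfmt 6), got %d", path, ncol(dt))
  names(dt) <- cols
  dt$qseqid <- as.character(dt$qseqid); dt$sseqid <- as.character(dt$sseqid)
  if (any(dt$evalue < 0)) ab_stop("%s: negative E-value", path)
  if (any(dt[c("qstart", "qend", "sstart", "send")] < 1))
    ab_stop("%s: coordinates must be positive (1-based)", path)
  dt$strand <- ifelse(dt$sstart <= dt$send, "+", "-")
  flip <- dt$strand == "-"
  tmp <- dt$sstart[flip]; dt$sstart[flip] <- dt$send[flip]; dt$send[flip] <- tmp
  dt
}

#' Read variants overlapping probe intervals from a minimal VCF
#'
#' Parses an uncompressed VCF v4.x with GT-bearing sample columns, keeps
#' records overlapping the supplied 1-based inclusive intervals, and splits
#' multi-allelic records into one row per ALT allele. Carrier counts are per
#' split allele.
#'
#' @param path VCF path.
#' @param probe_intervals data.frame with columns `snp`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return data.frame: snp, chrom, pos, ref, alt, n_samples, n_carriers,
#'   n_missing, line.
#' @export
read_vcf_probe_variants <- function(path, probe_intervals) {
  need <- c("snp", "chrom", "start", "end")
  if (!all(need %in% names(probe_intervals)))
    ab_stop("probe_intervals needs columns %s", paste(need, collapse = ", "))
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  out <- vector("list", length(body_idx))
  k <- 0L
  for (ln in body_idx) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      ab_stop("%s: malformed VCF line %d (%d fields, expected >= 8)", path, ln, length(f))
    pos <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(pos)) ab_stop("%s: malformed POS on line %d", path, ln)
    ref <- f[[4L]]; alts <- strsplit(f[[5L]], ",", fixed = TRUE)[[1L]]
    span <- pos + nchar(ref) - 1L
    ov <- probe_intervals$chrom == f[[1L]] &
          probe_intervals$start <= span & probe_intervals$end >= pos
    if (!any(ov)) next
    gts <- character(0)
    if (length(f) >= 10L) {
      fmt <- strsplit(f[[9L]], ":", fixed = TRUE)[[1L]]
      gi <- match("GT", fmt)
      if (is.na(gi)) ab_stop("%s: no GT key in FORMAT on line %d", path, ln)
      gts <- vapply(f[10:length(f)],
                    function(s) strsplit(s, ":", fixed = TRUE)[[1L]][gi], "")
    }
    for (ai in seq_along(alts)) {
      al <- strsplit(gsub("\\|", "/", gts), "/", fixed = FALSE)
      is_missing <- vapply(al, function(a) any(a == "."), logical(1))
      carries <- vapply(al, function(a) any(a == as.character(ai)), logical(1))
      for (pi in which(ov)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          snp = probe_intervals$snp[pi], chrom = f[[1L]], pos = pos,
          ref = ref, alt = alts[[ai]], n_samples = length(gts),
          n_carriers = sum(carries & !is_missing), n_missing = sum(is_missing),
          line = ln, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(snp = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), n_samples = integer(),
                      n_carriers = integer(), n_missing = integer(), line = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Write / read a per-SNP verdict table
#'
#' Columns: snp, status, class, compatible, n_adjustments. Round-trips
#' losslessly.
#' @param v verdict data.frame.
#' @param path TSV path.
#' @export
write_verdict_table <- function(v, path) {
  data.table::fwrite(v[, c("snp", "status", "class", "compatible", "n_adjustments")],
                     path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_verdict_table
#' @export
read_verdict_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = "NA"))
  need <- c("snp", "status", "class", "compatible", "n_adjustments")
  if (!all(need %in% names(dt))) ab_stop("%s: verdict table needs columns %s",
                                         path, paste(need, collapse = ", "))
  dt$snp <- as.character(dt$snp)
  dt
}
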