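# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

ab_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ab_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Union-find over character ids; returns a list of groups (size >= 2 only
# when keep_singletons is FALSE).
uf_groups <- function(pairs_a, pairs_b, keep_singletons = FALSE) {
  ids <- unique(c(pairs_a, pairs_b))
  if (length(ids) == 0L) return(list())
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(pairs_a)) {
    ra <- find(match(pairs_a[[k]], ids))
    rb <- find(match(pairs_b[[k]], ids))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  grps <- split(ids, roots)
  names(grps) <- NULL
  if (!keep_singletons) grps <- grps[lengths(grps) >= 2L]
  grps
}

# Quantile convention used package-wide: linear interpolation between order
# statistics (type 7), stated explicitly because the cluster-space statistic
# depends on it.
q_lin <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
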