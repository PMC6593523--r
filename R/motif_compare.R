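# Column-correlation motif comparison with a permutation null, in the spirit
# of TOMTOM: the statistic is the best (over ungapped offsets with >= 4
# overlapping columns, both orientations) mean per-column Pearson correlation
# between the two probability matrices.

# standardise PWM columns so that crossprod gives per-column Pearson r
std_cols <- function(prob) {
  z <- sweep(prob, 2, colMeans(prob))
  nrm <- sqrt(colSums(z^2))
  nrm[nrm == 0] <- Inf   # flat column correlates 0 with everything
  sweep(z, 2, nrm, "/")
}

# best diagonal of a wq x wt cross-correlation matrix over ungapped
# alignments with overlap >= min_overlap. The per-column correlations are
# averaged over ALL query columns (columns outside the overlap contribute
# zero), so short accidental alignments cannot dominate; a full-width
# perfect alignment still scores 1. Returns list(stat, offset).
best_diag <- function(M, min_overlap = 4) {
  wq <- nrow(M); wt <- ncol(M)
  best <- -Inf; boff <- NA_integer_
  for (o in (-(wq - min_overlap)):(wt - min_overlap)) {
    i <- max(1, 1 - o):min(wq, wt - o)
    if (length(i) < min_overlap) next
    m <- sum(M[cbind(i, i + o)]) / wq
    if (m > best) { best <- m; boff <- o }
  }
  list(stat = best, offset = boff)
}

#' Compare two motifs by column correlation with a permutation null
#'
#' Aligns the query PWM against the target PWM (all ungapped offsets with at
#' least 4 overlapping columns, forward and reverse-complement orientation)
#' and scores each alignment by the per-column Pearson correlations of the
#' probability columns averaged over all query columns (columns outside the
#' overlap count as zero, so a short accidental alignment cannot outrank a
#' full-width match). Significance comes from `n_null` column-shuffled
#' versions of the target, with add-one correction:
#' `p = (1 + #(null >= observed)) / (n_null + 1)`.
#'
#' @param query,target `pwm` objects (widths >= 4).
#' @param n_null number of column permutations (>= 100 recommended; a warning
#'   is emitted below that).
#' @param seed RNG seed for the permutations.
#' @return object of class `motif_match`: query, target, offset, orientation,
#'   statistic, p_value, q_value (NA here; filled by
#'   [motif_similarity_table()]).
#' @export
compare_motifs <- function(query, target, n_null = 1000, seed = 1) {
  if (pwm_width(query) < 4 || pwm_width(target) < 4)
    stopf("both motifs must have width >= 4")
  if (n_null < 100)
    warning("n_null < 100: permutation p-values will be coarse")
  Zq <- std_cols(query$prob)
  Zt <- std_cols(target$prob)
  Ztc <- std_cols(target$prob[4:1, , drop = FALSE]) # complemented rows
  Cf <- crossprod(Zq, Zt)                            # fwd target columns
  Cc <- crossprod(Zq, Ztc)                           # complemented columns
  wt <- pwm_width(target)

  obs_f <- best_diag(Cf)
  obs_r <- best_diag(Cc[, rev(seq_len(wt)), drop = FALSE])
  if (obs_f$stat >= obs_r$stat) {
    obs <- obs_f; orientation <- "forward"
  } else {
    obs <- obs_r; orientation <- "reverse-complement"
  }

  null_stats <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    perm <- sample.int(wt)
    max(best_diag(Cf[, perm, drop = FALSE])$stat,
        best_diag(Cc[, rev(perm), drop = FALSE])$stat)
  }, numeric(1)))
  p <- (1 + sum(null_stats >= obs$stat)) / (n_null + 1)

  structure(list(query = query$name, target = target$name,
                 offset = obs$offset, orientation = orientation,
                 statistic = obs$stat, p_value = p, q_value = NA_real_,
                 n_null = n_null),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("motif match %s vs %s: r = %.3f at offset %d (%s), p = %.3g\n",
              x$query, x$target, x$statistic, x$offset, x$orientation,
              x$p_value))
  invisible(x)
}

#' Compare a query motif against a collection, with BH-corrected q-values
#'
#' @param query a `pwm`.
#' @param targets list of `pwm` objects.
#' @inheritParams compare_motifs
#' @return data.frame: target, offset, orientation, statistic, p_value,
#'   q_value; one row per target, ordered by p.
#' @export
motif_similarity_table <- function(query, targets, n_null = 1000, seed = 1) {
  res <- lapply(seq_along(targets), function(i)
    compare_motifs(query, targets[[i]], n_null = n_null,
                   seed = child_seed(seed, i)))
  labels <- names(targets) %||% vapply(res, `[[`, character(1), "target")
  df <- data.frame(
    target = labels,
    offset = vapply(res, `[[`, integer(1), "offset"),
    orientation = vapply(res, `[[`, character(1), "orientation"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  df$q_value <- bh_adjust(df$p_value)
  df[order(df$p_value), , drop = FALSE]
}
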