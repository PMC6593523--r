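#' Median-of-ratios count normalization
#'
#' Size factors are the per-sample median ratio to the per-gene geometric
#' mean reference (genes with any zero excluded from the reference);
#' normalized values are counts divided by the size factor.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return list(normalized, size_factors).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (all(counts == 0)) stopf("count matrix is all zero")
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) stopf("no gene has positive counts in every sample")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logref)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Per-gene fold change (induced / control) with a pseudo-count
#'
#' `FC = (mean_induced + pseudo) / (mean_control + pseudo)`.
#'
#' @param normalized normalized count matrix, genes x samples.
#' @param condition character vector (one per column) with values
#'   `control` / `induced` (or the names given in `control`, `induced`).
#' @param pseudo pseudo-count in normalized units (default 0.5; must be > 0).
#' @param control,induced condition labels.
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(normalized, condition, pseudo = 0.5,
                        control = "control", induced = "induced") {
  if (pseudo <= 0) stopf("pseudo must be > 0")
  mc <- rowMeans(normalized[, condition == control, drop = FALSE])
  mi <- rowMeans(normalized[, condition == induced, drop = FALSE])
  (mi + pseudo) / (mc + pseudo)
}

# Method-of-moments per-gene NB dispersion, shrunk toward a lowess trend on
# the mean. With few replicates the per-gene estimate is dominated by the
# trend (weight df / (df + prior_df)).
estimate_dispersion <- function(normalized, condition, prior_df = 20,
                                floor = 1e-4) {
  groups <- split(seq_along(condition), condition)
  n <- length(condition); C <- length(groups)
  df <- n - C
  means <- sapply(groups, function(j)
    rowMeans(normalized[, j, drop = FALSE]))
  vars <- sapply(groups, function(j)
    apply(normalized[, j, drop = FALSE], 1, var))
  wts <- vapply(groups, length, numeric(1)) - 1
  v <- as.numeric(vars %*% wts) / max(df, 1)
  mu <- as.numeric(means %*% vapply(groups, length, numeric(1))) / n
  raw <- (v - mu) / mu^2
  raw[!is.finite(raw)] <- NA
  use <- !is.na(raw) & mu > 0
  if (sum(use) >= 10) {
    # iter = 0: the robust re-weighting of the default lowess downweights
    # the long right tail of the skewed per-gene estimates and deflates
    # the trend by ~20%, making the test liberal
    fit <- lowess(log10(mu[use]), raw[use], f = 0.5, iter = 0)
    trend <- approx(fit$x, fit$y, xout = log10(pmax(mu, 1e-8)), rule = 2)$y
  } else {
    med <- stats::median(raw[use], na.rm = TRUE)
    trend <- rep(if (is.finite(med)) med else 0.1, length(mu))
  }
  trend <- pmax(trend, floor)
  w <- df / (df + prior_df)
  phi <- w * pmax(ifelse(is.na(raw), trend, raw), floor) + (1 - w) * trend
  pmax(phi, floor)
}

# exact conditional NB test for one gene: condition-sum counts ta, tb from
# na, nb replicates, common dispersion phi
nb_exact_p <- function(ta, tb, na, nb, phi) {
  t <- ta + tb
  if (t == 0) return(1)
  mu <- t / (na + nb)
  k <- 0:t
  lp <- dnbinom(k, size = na / phi, mu = na * mu, log = TRUE) +
    dnbinom(t - k, size = nb / phi, mu = nb * mu, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  min(1, sum(p[lp <= lp[ta + 1] + 1e-10]) / sum(p))
}

#' Exact-style negative-binomial test for two-condition counts
#'
#' Two-sided p-values from a negative-binomial model: counts are normalized
#' by median-of-ratios size factors, the per-gene dispersion is a
#' method-of-moments estimate shrunk toward a lowess mean-dispersion trend,
#' and the test conditions on the per-gene total of the (rounded) normalized
#' condition sums — the sum of the probabilities of all outcomes no more
#' likely than the observed one. All-zero genes get p = 1.
#'
#' @param counts genes x samples non-negative matrix.
#' @param condition per-column condition labels (two levels).
#' @param size_factors optional per-sample size factors (estimated when
#'   `NULL`).
#' @param dispersion optional per-gene (or scalar) dispersion; estimated when
#'   `NULL`.
#' @return named numeric vector of p-values.
#' @export
nb_test <- function(counts, condition, size_factors = NULL,
                    dispersion = NULL) {
  counts <- as.matrix(counts)
  lev <- unique(condition)
  if (length(lev) != 2L) stopf("condition must have exactly two levels")
  if (is.null(size_factors))
    size_factors <- normalize_counts(counts)$size_factors
  normalized <- sweep(counts, 2, size_factors, "/")
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(normalized, condition)
  phi <- rep_len(dispersion, nrow(counts))
  y <- round(normalized)
  a <- condition == lev[1]; b <- condition == lev[2]
  ta <- rowSums(y[, a, drop = FALSE]); tb <- rowSums(y[, b, drop = FALSE])
  na <- sum(a); nb <- sum(b)
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_p(ta[i], tb[i], na, nb, phi[i]), numeric(1))
  setNames(p, rownames(counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`):
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`, capped
#' at 1.
#'
#' @param p numeric p-values in \[0, 1\]; NA/NaN is an error.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stopf("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression table for a two-condition count matrix
#'
#' Normalizes, computes fold changes (induced/control), exact-style NB
#' p-values and BH q-values, and calls each gene up / down / unchanged at
#' the given thresholds (boundaries inclusive: fold change at least `fc_min`
#' and q at most `q_max`).
#'
#' @inheritParams nb_test
#' @param pseudo pseudo-count for fold changes.
#' @param fc_min,q_max selection thresholds (defaults 3 and 0.01).
#' @param control,induced condition labels.
#' @return data.frame of class `de_table`: gene_id, mean_control,
#'   mean_induced, fold_change, p_value, q_value, call.
#' @export
de_table <- function(counts, condition, pseudo = 0.5, fc_min = 3,
                     q_max = 0.01, control = "control", induced = "induced",
                     dispersion = NULL) {
  counts <- as.matrix(counts)
  norm <- normalize_counts(counts)
  fc <- fold_change(norm$normalized, condition, pseudo = pseudo,
                    control = control, induced = induced)
  p <- nb_test(counts, condition, size_factors = norm$size_factors,
               dispersion = dispersion)
  q <- bh_adjust(p)
  call <- rep("unchanged", length(fc))
  call[fc >= fc_min & q <= q_max] <- "up"
  call[fc <= 1 / fc_min & q <= q_max] <- "down"
  structure(data.frame(
    gene_id = rownames(counts) %||% sprintf("gene_%05d", seq_along(fc)),
    mean_control = rowMeans(norm$normalized[, condition == control,
                                            drop = FALSE]),
    mean_induced = rowMeans(norm$normalized[, condition == induced,
                                            drop = FALSE]),
    fold_change = unname(fc), p_value = unname(p), q_value = unname(q),
    call = call, row.names = NULL, stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"),
    thresholds = c(fc_min = fc_min, q_max = q_max))
}

#' @export
print.de_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "DE table: %d genes; %d up, %d down at FC >= %g and q <= %g\n",
    nrow(x), sum(x$call == "up"), sum(x$call == "down"), th[1], th[2]))
  NextMethod()
}

#' Write a DE table as TSV (gene_id, fold change, p, q, call)
#' @param de a `de_table`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Select regulated genes at fold-change and FDR thresholds
#'
#' Up-set: fold change at least `fc_min` (induced/control) and q at most
#' `q_max` (both boundaries inclusive); down-set symmetric with fold change
#' at most `1/fc_min`.
#'
#' @param de a `de_table` (or data.frame with gene_id, fold_change,
#'   q_value).
#' @param fc_min,q_max thresholds (defaults 3 and 0.01, both > 0).
#' @return list(up, down) of gene ids.
#' @export
select_regulated <- function(de, fc_min = 3, q_max = 0.01) {
  if (fc_min <= 0 || q_max <= 0) stopf("thresholds must be > 0")
  list(up = de$gene_id[de$fold_change >= fc_min & de$q_value <= q_max],
       down = de$gene_id[de$fold_change <= 1 / fc_min & de$q_value <= q_max])
}

#' ddCq qPCR fold change
#'
#' Per condition, `dCq = Cq_target - mean(Cq_references)` within each
#' replicate, averaged over replicates; `ddCq = dCq_induced - dCq_control`;
#' fold change `2^-ddCq`.
#'
#' @param cq a `cq_table` (long data.frame: gene, condition, replicate, cq).
#' @param target target gene id.
#' @param ref_genes reference gene ids (default: the table's `ref_genes`
#'   attribute).
#' @param control,induced condition labels.
#' @return fold change (induced relative to control).
#' @export
ddcq_fold_change <- function(cq, target, ref_genes = NULL,
                             control = "control", induced = "induced") {
  ref_genes <- ref_genes %||% attr(cq, "ref_genes")
  if (is.null(ref_genes) || !length(ref_genes))
    stopf("no reference genes given")
  if (!target %in% cq$gene) stopf("target gene %s not in Cq table", target)
  missing <- setdiff(ref_genes, cq$gene)
  if (length(missing)) stopf("reference gene %s missing from Cq table",
                             missing[1])
  dcq <- function(cond) {
    sub <- cq[cq$condition == cond, ]
    if (!nrow(sub)) stopf("condition %s absent from Cq table", cond)
    reps <- sort(unique(sub$replicate))
    mean(vapply(reps, function(r) {
      tgt <- sub$cq[sub$gene == target & sub$replicate == r]
      ref <- sub$cq[sub$gene %in% ref_genes & sub$replicate == r]
      if (!length(tgt) || !length(ref))
        stopf("replicate %s lacks target or reference Cq in %s", r, cond)
      mean(tgt) - mean(ref)
    }, numeric(1)))
  }
  2^-(dcq(induced) - dcq(control))
}
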