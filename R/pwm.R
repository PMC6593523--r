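#' Position-weight matrices
#'
#' A `pwm` object stores a per-position probability distribution over
#' A, C, G, T — the standard probabilistic model of a transcription-factor
#' binding motif. Columns are motif positions; scoring against sequence is
#' log2 odds relative to a 0-order background.
#'
#' @param prob 4 x w numeric matrix with rows A, C, G, T; columns must each
#'   sum to 1.
#' @param name motif name.
#' @param nsites number of sites the matrix was estimated from (optional).
#' @param pseudocount pseudocount used during construction (bookkeeping).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(prob, name = "motif", nsites = NA_integer_,
                    pseudocount = NA_real_) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 4L) stopf("PWM must have 4 rows (A,C,G,T)")
  rownames(prob) <- DNA_BASES
  cs <- colSums(prob)
  if (any(abs(cs - 1) > 1e-9)) stopf("PWM columns must sum to 1")
  if (any(prob < 0)) stopf("PWM probabilities must be non-negative")
  structure(list(prob = prob, name = name, nsites = nsites,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM from aligned binding sites
#'
#' Column frequencies are `(count + pseudocount/4) / (n + pseudocount)`.
#' The default pseudocount is positive so that every probability is non-zero
#' and log-odds scores stay finite; an explicit `pseudocount = 0` is allowed
#' but columns with a zero count then produce `-Inf` log odds (a warning is
#' emitted).
#'
#' @param sites character vector of equal-length sequences over A,C,G,T.
#' @param pseudocount total pseudocount added per column (default 0.5).
#' @param name motif name.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, name = "motif") {
  if (length(sites) < 1L) stopf("need at least one site")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) stopf("sites must have equal length")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  codes <- encode_dna(toupper(sites))
  if (any(vapply(codes, function(z) any(z == 0L), logical(1))))
    stopf("sites must contain only A, C, G, T")
  w <- lens[1]
  m <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  for (cd in codes) m[cbind(cd, seq_len(w))] <- m[cbind(cd, seq_len(w))] + 1
  prob <- (m + pseudocount / 4) / (length(sites) + pseudocount)
  if (pseudocount == 0 && any(prob == 0))
    warning("pseudocount 0 with zero counts: log-odds scores will be -Inf")
  new_pwm(prob, name = name, nsites = length(sites), pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, %s sites, IC %.2f bits\n",
              x$name, pwm_width(x),
              ifelse(is.na(x$nsites), "?", x$nsites),
              information_content(x)))
  cat("consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' @export
#' @rdname new_pwm
pwm_width <- function(prob) {
  if (inherits(prob, "pwm")) ncol(prob$prob) else ncol(prob)
}

#' Consensus string (most probable base per column)
#' @param pwm a `pwm`.
#' @export
consensus_string <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Total information content in bits (uniform background)
#' @param pwm a `pwm`.
#' @export
information_content <- function(pwm) {
  p <- pwm$prob
  sum(p * log2(pmax(p, 1e-12) / 0.25))
}

#' Reverse complement of a PWM
#' @param pwm a `pwm`.
#' @export
pwm_reverse_complement <- function(pwm) {
  prob <- pwm$prob[4:1, rev(seq_len(pwm_width(pwm))), drop = FALSE]
  rownames(prob) <- DNA_BASES
  new_pwm(prob, name = paste0(pwm$name, "_rc"), nsites = pwm$nsites,
          pseudocount = pwm$pseudocount)
}

#' Background base frequencies
#'
#' 0-order background model: either uniform or estimated from a set of
#' sequences (the promoter set being scanned, by default, mirroring
#' FIMO-style scanning practice).
#'
#' @param seqs character vector of sequences; `NULL` for uniform.
#' @export
background_frequencies <- function(seqs = NULL) {
  if (is.null(seqs)) return(setNames(rep(0.25, 4), DNA_BASES))
  codes <- unlist(encode_dna(toupper(seqs)), use.names = FALSE)
  codes <- codes[codes > 0L]
  if (!length(codes)) stopf("no A/C/G/T bases to estimate background from")
  f <- tabulate(codes, 4)
  # keep strictly positive
  f <- (f + 1) / (sum(f) + 4)
  setNames(f, DNA_BASES)
}

check_background <- function(background) {
  if (is.null(background)) background <- background_frequencies()
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stopf("background must be 4 strictly positive frequencies summing to 1")
  setNames(as.numeric(background), DNA_BASES)
}

log_odds_matrix <- function(pwm, background = NULL) {
  bg <- check_background(background)
  log2(pwm$prob / bg)
}

#' Log-odds score of a word under a PWM
#'
#' `sum_i log2(p_i(word_i) / bg(word_i))`, in bits.
#'
#' @param pwm a `pwm`.
#' @param word character string of the motif width over A,C,G,T.
#' @param background length-4 frequency vector (default uniform).
#' @export
log_odds_score <- function(pwm, word, background = NULL) {
  w <- pwm_width(pwm)
  if (nchar(word) != w) stopf("word length %d != motif width %d", nchar(word), w)
  cd <- encode_dna(toupper(word))[[1]]
  if (any(cd == 0L)) stopf("word contains non-ACGT characters")
  lo <- log_odds_matrix(pwm, background)
  sum(lo[cbind(cd, seq_len(w))])
}

#' Maximum and minimum attainable log-odds scores
#' @inheritParams log_odds_score
#' @export
max_score <- function(pwm, background = NULL) {
  sum(apply(log_odds_matrix(pwm, background), 2, max))
}

#' @rdname max_score
#' @export
min_score <- function(pwm, background = NULL) {
  sum(apply(log_odds_matrix(pwm, background), 2, min))
}

# Discretised exact distribution of the score of a random background word.
# Returns list(support_bins, pmf, tail, origin, granularity).
score_distribution <- function(pwm, background = NULL, granularity = 1e-3) {
  bg <- check_background(background)
  lo <- log_odds_matrix(pwm, bg)
  if (any(!is.finite(lo))) stopf("log-odds matrix has non-finite entries; use a positive pseudocount")
  bins <- matrix(as.integer(round(lo / granularity)), 4, pwm_width(pwm))
  pmf <- score_pmf_cpp(bins, as.numeric(bg))
  origin <- attr(pmf, "origin")
  tail <- rev(cumsum(rev(as.numeric(pmf))))
  # rounding each column's score to a bin displaces a word's total by at
  # most w/2 bins; lookups shift by that slack so that P(score >= s) is
  # never understated (in particular p(min_score) is exactly 1)
  list(pmf = as.numeric(pmf), tail = tail, origin = origin,
       granularity = granularity,
       shift = ceiling(pwm_width(pwm) / 2) + 1L)
}

#' Exact p-value of a PWM score
#'
#' `P(score(W) >= s)` for a random background word `W`, computed by dynamic
#' programming over the discretised per-column score distributions (the exact
#' method FIMO uses), at granularity `granularity` bits.
#'
#' @inheritParams log_odds_score
#' @param score observed log-odds score (bits).
#' @param granularity score discretisation step in bits (default 1e-3).
#' @export
score_pvalue <- function(pwm, score, background = NULL, granularity = 1e-3) {
  dist <- score_distribution(pwm, background, granularity)
  lookup_tail(dist, score)
}

lookup_tail <- function(dist, score) {
  bin <- as.integer(round(score / dist$granularity))
  idx <- bin - dist$origin + 1 - dist$shift
  n <- length(dist$tail)
  p <- numeric(length(idx))
  p[idx <= 0] <- 1
  p[idx > n] <- 0
  inside <- idx >= 1 & idx <= n
  p[inside] <- dist$tail[idx[inside]]
  p
}

#' Palindromicity score of a PWM
#'
#' Bacterial TF operators are typically palindromic (bound by homodimers).
#' The score is the maximum, over contiguous sub-windows of length at least
#' `k_min`, of the mean per-column Pearson correlation between the sub-PWM
#' and its own reverse complement, mapped from \[-1, 1\] to \[0, 1\]. A perfect
#' palindrome scores 1.
#'
#' @param pwm a `pwm`.
#' @param k_min minimum sub-window width considered (default 8).
#' @return numeric score in \[0, 1\].
#' @export
palindromicity <- function(pwm, k_min = 8) {
  p <- pwm$prob
  w <- ncol(p)
  if (w < k_min) k_min <- w
  best <- -1
  for (len in k_min:w) {
    for (s in 1:(w - len + 1)) {
      sub <- p[, s:(s + len - 1), drop = FALSE]
      rc <- sub[4:1, rev(seq_len(len)), drop = FALSE]
      r <- vapply(seq_len(len), function(k) {
        x <- sub[, k]; y <- rc[, k]
        if (sd(x) == 0 || sd(y) == 0) return(ifelse(all(x == y), 1, 0))
        cor(x, y)
      }, numeric(1))
      best <- max(best, mean(r))
    }
  }
  (best + 1) / 2
}

#' Simple-repeat detection for a motif
#'
#' Flags motifs whose consensus is a short tandem repeat (period 1-3), such
#' as CGCGCGCG..., which are unusual for bacterial TF binding motifs. The
#' consensus autocorrelation (fraction of positions matching under shift s)
#' must reach `r_min` for some s in 1..3 and the mean column information
#' content must be at least `ic_min` bits (so degenerate motifs are not
#' flagged).
#'
#' @param pwm a `pwm`.
#' @param r_min autocorrelation threshold (default 0.8).
#' @param ic_min mean per-column information content guard (default 1 bit).
#' @return list(is_simple_repeat, period, match_fraction)
#' @export
repeat_score <- function(pwm, r_min = 0.8, ic_min = 1) {
  cons <- strsplit(consensus_string(pwm), "")[[1]]
  w <- length(cons)
  mean_ic <- information_content(pwm) / w
  fracs <- vapply(1:3, function(s) {
    if (w - s < 1) return(0)
    mean(cons[seq_len(w - s)] == cons[seq_len(w - s) + s])
  }, numeric(1))
  hit <- which(fracs >= r_min)
  flagged <- length(hit) > 0 && mean_ic >= ic_min
  list(is_simple_repeat = flagged,
       period = if (length(hit)) hit[1] else NA_integer_,
       match_fraction = fracs)
}
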