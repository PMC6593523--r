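# Seeded ZOOPS EM motif discovery.
#
# For each trial width on a coarse grid, the top over-represented exact
# 8-mers seed PWMs that are refined by expectation-maximisation under the
# ZOOPS occurrence model (zero or one occurrence per sequence, both
# strands). Found motifs' occurrences are masked before the next motif is
# sought. Significance is a permutation E-value: the best same-width EM
# log-likelihood ratio on base-shuffled promoter sets, with a Gaussian tail
# fit so that E-values far below the permutation resolution can be bounded.

SEED_K <- 8L

key_to_codes <- function(key, k = SEED_K) {
  (key %/% 4^(0:(k - 1))) %% 4 + 1
}

revcomp_codes <- function(x) rev(ifelse(x == 0L, 0L, 5L - x))

# per-sequence 8-mer index over both orientations, built once and shared by
# seed ranking and seed-PWM construction
build_seed_context <- function(codes, k = SEED_K) {
  lapply(codes, function(x) {
    rc <- revcomp_codes(x)
    list(x = x, rc = rc,
         f = kmer_index_cpp(x, k), r = kmer_index_cpp(rc, k))
  })
}

# top over-represented 8-mers (both strands), as integer code vectors
top_seed_words <- function(ctx, bg, n_seeds, k = SEED_K) {
  keys <- unlist(lapply(ctx, function(ci) c(ci$f$keys, ci$r$keys)),
                 use.names = FALSE)
  if (!length(keys)) return(list())
  cnt <- tabulate(keys + 1L, 4^k)
  seen <- which(cnt >= 2L)
  if (!length(seen)) seen <- which(cnt > 0L)
  word_codes <- lapply(seen - 1L, key_to_codes, k = k)
  expct <- length(keys) * vapply(word_codes, function(wc)
    prod(bg[wc]), numeric(1))
  ratio <- (cnt[seen] + 1) / (expct + 1)
  ord <- order(-ratio, -cnt[seen])
  word_codes[utils::head(ord, n_seeds)]
}

# seed PWM of width w from occurrences of an exact 8-mer
seed_pwm <- function(ctx, word, w, k = SEED_K) {
  left <- (w - k) %/% 2L
  target <- as.integer(sum((word - 1) * 4^(seq_len(k) - 1)))
  cnt <- matrix(0, 4, w)
  nocc <- 0L
  for (ci in ctx) {
    for (side in c("f", "r")) {
      s <- if (side == "f") ci$x else ci$rc
      idx <- ci[[side]]
      for (p in idx$pos[idx$keys == target]) {
        a <- p - left; b <- a + w - 1L
        if (a >= 1 && b <= length(s)) {
          win <- s[a:b]
          if (all(win > 0L)) {
            cnt[cbind(win, seq_len(w))] <- cnt[cbind(win, seq_len(w))] + 1
            nocc <- nocc + 1L
          }
        }
      }
    }
  }
  if (nocc > 0) {
    phat <- sweep(cnt + 1, 2, colSums(cnt) + 4, "/")
    return(0.75 * phat + 0.25 * 0.25)
  }
  # fall back to the bare word, centred
  prob <- matrix(0.25, 4, w)
  for (i in seq_len(k)) {
    j <- left + i
    if (j >= 1 && j <= w) { prob[, j] <- 0.4 / 3; prob[word[i], j] <- 0.6 }
  }
  prob
}

# best ZOOPS motif of width w on a coded sequence set: evaluate all seeds
# with a short EM, then refine the best one to convergence
fit_best_motif <- function(codes, w, bg, n_seeds = 20, short_iter = 2,
                           max_iter = 200, tol = 1e-4, pseudocount = 0.5,
                           gamma0 = 0.3, seed = 1, ctx = NULL) {
  if (is.null(ctx)) ctx <- build_seed_context(codes)
  words <- top_seed_words(ctx, bg, n_seeds)
  if (!length(words)) return(NULL)
  shorts <- lapply(words, function(word)
    em_zoops_cpp(codes, seed_pwm(ctx, word, w), as.numeric(bg),
                 gamma0, short_iter, 0, pseudocount))
  llrs <- vapply(shorts, function(f) f$llr[length(f$llr)], numeric(1))
  best <- shorts[[which.max(llrs)]]
  fit <- em_zoops_cpp(codes, best$pwm, as.numeric(bg), best$gamma,
                      max_iter, tol, pseudocount)
  list(pwm = fit$pwm, gamma = fit$gamma,
       llr = fit$llr[length(fit$llr)], objective = fit$objective,
       iterations = fit$iterations, width = w)
}

# null distribution of the best width-w LLR on base-shuffled sequences
null_best_llrs <- function(codes, w, bg, n_null, n_seeds = 3, max_iter = 40,
                           tol = 1e-4, seed = 1) {
  vapply(seq_len(n_null), function(i) {
    sh <- with_seed(child_seed(seed, i), lapply(codes, sample))
    f <- fit_best_motif(sh, w, bg, n_seeds = n_seeds, max_iter = max_iter,
                        tol = tol, seed = child_seed(seed, i + 100000L))
    if (is.null(f)) 0 else f$llr
  }, numeric(1))
}

evalue_from_llr <- function(llr, null_llrs, n_tests) {
  b <- sum(null_llrs >= llr)
  p_perm <- (b + 1) / (length(null_llrs) + 1)
  s <- sd(null_llrs)
  p_gauss <- if (is.finite(s) && s > 0)
    pnorm(llr, mean(null_llrs), s, lower.tail = FALSE)
  else as.numeric(llr <= mean(null_llrs))
  min(p_perm, p_gauss) * n_tests
}

#' Discover over-represented motifs in a promoter set (ZOOPS EM)
#'
#' For each width on a coarse grid spanning `w_min`..`w_max`, the top
#' `n_seeds` over-represented exact 8-mers are extended to the trial width
#' and refined by ZOOPS expectation-maximisation (zero-or-one occurrence
#' per sequence, both strands) to convergence. The best motif across widths
#' (smallest E-value) is reported, its occurrences are masked, and the
#' search repeats up to `n_report` times. E-values come from a per-width
#' permutation null (see [motif_evalue()]); the reported list is ordered by
#' E-value.
#'
#' @param promoters promoter set (a `promoter_set`, named character vector,
#'   or DNAStringSet); at least 5 sequences, each at least `w_min` long.
#' @param w_min,w_max motif width limits (defaults 8 and 50).
#' @param n_report maximum number of motifs reported (default 20).
#' @param mode occurrence model; only `"ZOOPS"` is implemented.
#' @param width_grid trial widths (default 8, 11, 15, 21, 29, 39, 50
#'   clipped to the limits).
#' @param n_seeds EM starting points per width.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   penalised log likelihood.
#' @param background length-4 background (default: estimated from the
#'   promoters).
#' @param n_null permutation replicates per width for E-values.
#' @param null_n_seeds,null_max_iter EM effort per permutation replicate.
#' @param seed RNG seed (default 1817).
#' @return object of class `discovered_motifs`: list of motif records
#'   (`pwm`, `e_value`, `llr`, `gamma`, `n_sequences`, `rank`) plus the
#'   background and null-calibration metadata.
#' @export
discover_motifs <- function(promoters, w_min = 8, w_max = 50, n_report = 20,
                            mode = "ZOOPS", width_grid = NULL, n_seeds = 20,
                            max_iter = 200, tol = 1e-4, background = NULL,
                            n_null = 40, null_n_seeds = 2,
                            null_max_iter = 30, seed = 1817) {
  mode <- match.arg(mode, "ZOOPS")
  seqs <- promoter_seqs(promoters)
  if (length(seqs) < 5) stopf("promoter set too small (need >= 5 sequences)")
  if (any(nchar(seqs) < w_min))
    stopf("all promoters must be at least w_min (%d) bp", w_min)
  bg <- if (is.null(background)) background_frequencies(seqs)
        else check_background(background)
  codes <- encode_dna(seqs)
  maxw <- min(nchar(seqs))
  widths <- width_grid %||% c(8L, 11L, 15L, 21L, 29L, 39L, 50L)
  widths <- widths[widths >= w_min & widths <= min(w_max, maxw)]
  if (!length(widths)) widths <- as.integer(w_min)
  n_tests <- length(widths) * n_seeds

  # two-tier permutation null per width: a small pilot sample ranks the
  # per-width candidates; the full null is computed only for the width of
  # the selected motif (both cached across rounds, drawn from the original
  # unmasked promoters)
  n_pilot <- min(6L, n_null)
  pilot_cache <- new.env(parent = emptyenv())
  null_cache <- new.env(parent = emptyenv())
  get_pilot <- function(w) {
    key <- as.character(w)
    if (is.null(pilot_cache[[key]]))
      pilot_cache[[key]] <- null_best_llrs(
        codes, w, bg, n_pilot, n_seeds = null_n_seeds,
        max_iter = null_max_iter, seed = child_seed(seed, 5000L + w))
    pilot_cache[[key]]
  }
  get_null <- function(w) {
    key <- as.character(w)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- c(
        get_pilot(w),
        null_best_llrs(codes, w, bg, n_null - n_pilot,
                       n_seeds = null_n_seeds, max_iter = null_max_iter,
                       seed = child_seed(seed, 7000L + w)))
    null_cache[[key]]
  }

  masked <- codes
  records <- list()
  for (m in seq_len(n_report)) {
    ctx <- build_seed_context(masked)
    fits <- lapply(seq_along(widths), function(wi)
      fit_best_motif(masked, widths[wi], bg, n_seeds = n_seeds,
                     max_iter = max_iter, tol = tol,
                     seed = child_seed(seed, m * 100L + wi), ctx = ctx))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) break
    evs_pilot <- vapply(fits, function(f)
      evalue_from_llr(f$llr, get_pilot(f$width), n_tests), numeric(1))
    pick <- order(evs_pilot, -vapply(fits, `[[`, numeric(1), "llr"))[1]
    f <- fits[[pick]]
    ev <- evalue_from_llr(f$llr, get_null(f$width), n_tests)
    sites <- zoops_map_sites_cpp(masked, f$pwm, as.numeric(bg), f$gamma)
    occ <- which(!is.na(sites$start) & sites$posterior >= 0.5)
    # mask occurrences so later motifs are disjoint
    for (i in occ) {
      a <- sites$start[i]; b <- a + f$width - 1L
      masked[[i]][a:b] <- 0L
    }
    occ_df <- data.frame(
      seq_id = names(seqs)[occ], start = sites$start[occ],
      end = sites$start[occ] + f$width - 1L,
      strand = ifelse(sites$strand[occ] == 1L, "+", "-"),
      posterior = sites$posterior[occ], stringsAsFactors = FALSE)
    records[[m]] <- list(
      pwm = new_pwm(f$pwm, name = sprintf("motif_%02d", m),
                    nsites = length(occ), pseudocount = 0.5),
      e_value = ev, llr = f$llr, gamma = f$gamma,
      width = f$width, n_sequences = length(occ),
      sites = occ_df, objective = f$objective)
  }
  ord <- order(vapply(records, `[[`, numeric(1), "e_value"))
  records <- records[ord]
  for (i in seq_along(records)) records[[i]]$rank <- i
  structure(list(motifs = records, background = bg, widths = widths,
                 n_tests = n_tests,
                 null_llrs = as.list(null_cache), seed = seed),
            class = "discovered_motifs")
}

#' @export
print.discovered_motifs <- function(x, ...) {
  cat(sprintf("%d discovered motifs (widths tried: %s)\n",
              length(x$motifs), paste(x$widths, collapse = ", ")))
  for (m in x$motifs)
    cat(sprintf("  %2d. %s w=%d E=%.3g llr=%.1f seqs=%d  %s\n",
                m$rank, m$pwm$name, m$width, m$e_value, m$llr,
                m$n_sequences, consensus_string(m$pwm)))
  invisible(x)
}

#' Permutation E-value of a motif on a promoter set
#'
#' The observed statistic is the ZOOPS log-likelihood ratio of the motif on
#' the promoters (EM-refined from the given PWM). The null is the best
#' same-width LLR on `n_null` base-shuffled copies of the promoter set. The
#' p-value is the smaller of the add-one permutation estimate
#' `(b+1)/(n_null+1)` and a Gaussian tail fitted to the null sample (which
#' lets strong motifs be bounded far below the permutation resolution);
#' the E-value multiplies by `n_tests`, the effective number of motifs
#' examined during discovery. Monotone decreasing in the observed LLR.
#'
#' @param motif a `pwm`, or a record from [discover_motifs()].
#' @param promoters the promoter set the motif was discovered on.
#' @param n_null number of shuffled promoter sets (>= 50 required).
#' @param seed RNG seed.
#' @param background length-4 background (default estimated).
#' @param n_tests effective number of motifs tested (default 7 widths x 20
#'   seeds = 140).
#' @param null_n_seeds,null_max_iter EM effort per shuffled set.
#' @param observed_llr optional LLR override (skips re-fitting).
#' @return the E-value (numeric).
#' @export
motif_evalue <- function(motif, promoters, n_null = 50, seed = 1,
                         background = NULL, n_tests = 140,
                         null_n_seeds = 2, null_max_iter = 30,
                         observed_llr = NULL) {
  if (n_null < 50) stopf("n_null must be >= 50")
  seqs <- promoter_seqs(promoters)
  bg <- if (is.null(background)) background_frequencies(seqs)
        else check_background(background)
  codes <- encode_dna(seqs)
  pw <- if (inherits(motif, "pwm")) motif else motif$pwm
  w <- pwm_width(pw)
  if (is.null(observed_llr)) {
    if (!inherits(motif, "pwm") && !is.null(motif$llr)) {
      observed_llr <- motif$llr
    } else {
      fit <- em_zoops_cpp(codes, pw$prob, as.numeric(bg), 0.3,
                          null_max_iter, 1e-4, 0.5)
      observed_llr <- fit$llr[length(fit$llr)]
    }
  }
  nulls <- null_best_llrs(codes, w, bg, n_null, n_seeds = null_n_seeds,
                          max_iter = null_max_iter,
                          seed = child_seed(seed, 7000L + w))
  evalue_from_llr(observed_llr, nulls, n_tests)
}

#' Apply the three motif-candidacy criteria
#'
#' A discovered motif is a credible transcription-factor motif when it
#' (1) is statistically significant (E-value at most `e_max`), (2) contains
#' a palindrome (palindromicity at least `palindrome_min` over a window of
#' at least `k_min` columns), and (3) is not a simple repeat of period 1-3.
#'
#' @param motifs a `discovered_motifs` object, or a list of records each
#'   with elements `pwm` and `e_value`.
#' @param e_max significance threshold (default 1e-5).
#' @param palindrome_min palindromicity threshold (default 0.8).
#' @param k_min minimum palindrome window (default 8).
#' @param repeat_r_min,ic_min simple-repeat autocorrelation threshold and
#'   information-content guard (defaults 0.8 and 1 bit).
#' @return data.frame of class `candidacy_verdicts`: motif, e_value,
#'   palindromicity, repeat_period, passes_significance, passes_palindrome,
#'   passes_repeat, is_candidate.
#' @export
filter_candidates <- function(motifs, e_max = 1e-5, palindrome_min = 0.8,
                              k_min = 8, repeat_r_min = 0.8, ic_min = 1) {
  recs <- if (inherits(motifs, "discovered_motifs")) motifs$motifs else motifs
  rows <- lapply(recs, function(r) {
    pal <- palindromicity(r$pwm, k_min = k_min)
    rep_ <- repeat_score(r$pwm, r_min = repeat_r_min, ic_min = ic_min)
    s <- r$e_value <= e_max
    p <- pal >= palindrome_min
    nr <- !rep_$is_simple_repeat
    data.frame(motif = r$pwm$name, e_value = r$e_value,
               palindromicity = pal,
               repeat_period = rep_$period %||% NA_integer_,
               passes_significance = s, passes_palindrome = p,
               passes_repeat = nr, is_candidate = s && p && nr,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("candidacy_verdicts", "data.frame"))
}
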