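scan_all_positions <- function(pwm, seqs, background) {
  lo <- log_odds_matrix(pwm, background)
  codes <- encode_dna(seqs)
  raw <- score_windows_cpp(codes, lo)
  w <- pwm_width(pwm)
  ids <- names(seqs)
  data.frame(gene_id = ids[raw$seq],
             start = raw$start, end = raw$start + w - 1L,
             strand = ifelse(raw$strand == 1L, "+", "-"),
             score = raw$score, stringsAsFactors = FALSE)
}

hit_words <- function(hits, seqs) {
  if (!nrow(hits)) return(character(0))
  word <- substr(seqs[hits$gene_id], hits$start, hits$end)
  neg <- hits$strand == "-"
  if (any(neg)) word[neg] <- revcomp_chr(word[neg])
  unname(word)
}

# greedy per-promoter resolution of overlapping hits: best score, then
# leftmost, then forward strand
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$gene_id, -hits$score, hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (g in split(seq_len(nrow(hits)), hits$gene_id)) {
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in g) {
      if (!any(hits$start[i] <= taken_e & hits$end[i] >= taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, hits$start[i])
        taken_e <- c(taken_e, hits$end[i])
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
}

#' Scan promoters for motif sites with exact p-values and an FDR cut
#'
#' FIMO-style scheme: every position of every promoter is scored on both
#' orientations; p-values come from the exact (dynamic-programming) score
#' distribution under the 0-order background; Benjamini-Hochberg q-values
#' are computed across all scored positions of the whole scan, and hits
#' with q at most `q_max` are kept. Overlapping hits of the same motif in
#' one promoter are resolved to the best-scoring one (ties: leftmost, then
#' forward strand).
#'
#' @param pwm a `pwm`.
#' @param promoters promoter set (`promoter_set`, named character vector,
#'   or DNAStringSet).
#' @param background length-4 background (default: estimated from the
#'   promoter set being scanned).
#' @param q_max FDR threshold (default 0.01).
#' @param granularity score discretisation (bits) for the p-value DP.
#' @return data.frame of hits: gene_id, start, end (1-based, promoter
#'   coordinates), strand (relative to the promoter), word, score (bits),
#'   p_value, q_value, scheme = "A".
#' @export
scan_scheme_a <- function(pwm, promoters, background = NULL, q_max = 0.01,
                          granularity = 1e-3) {
  seqs <- promoter_seqs(promoters)
  if (!length(seqs)) stopf("promoter set is empty")
  bg <- if (is.null(background)) background_frequencies(seqs)
        else check_background(background)
  all_pos <- scan_all_positions(pwm, seqs, bg)
  if (!nrow(all_pos)) {
    all_pos$word <- character(0); all_pos$p_value <- numeric(0)
    all_pos$q_value <- numeric(0); all_pos$scheme <- character(0)
    return(all_pos)
  }
  dist <- score_distribution(pwm, bg, granularity)
  all_pos$p_value <- lookup_tail(dist, all_pos$score)
  all_pos$q_value <- bh_adjust(all_pos$p_value)
  hits <- all_pos[all_pos$q_value <= q_max, , drop = FALSE]
  hits <- resolve_overlaps(hits)
  hits$word <- hit_words(hits, seqs)
  hits$scheme <- rep("A", nrow(hits))
  rownames(hits) <- NULL
  hits[, c("gene_id", "start", "end", "strand", "word", "score",
           "p_value", "q_value", "scheme")]
}

#' Scan promoters by fraction of the maximum possible score
#'
#' UGENE-style scheme: a position is a putative site when its normalized
#' score fraction `(score - min) / (max - min)` is at least `f_min` (85%
#' by default), on either orientation. The normalized-fraction convention
#' is used because a raw score/max ratio is ill-defined for negative
#' log-odds scores.
#'
#' @inheritParams scan_scheme_a
#' @param f_min minimum score fraction (default 0.85).
#' @return data.frame of hits: gene_id, start, end, strand, word, score,
#'   score_fraction, scheme = "B".
#' @export
scan_scheme_b <- function(pwm, promoters, background = NULL, f_min = 0.85) {
  seqs <- promoter_seqs(promoters)
  if (!length(seqs)) stopf("promoter set is empty")
  bg <- if (is.null(background)) background_frequencies(seqs)
        else check_background(background)
  mx <- max_score(pwm, bg); mn <- min_score(pwm, bg)
  if (mx - mn < 1e-12)
    stopf("degenerate PWM: maximum score equals minimum score")
  all_pos <- scan_all_positions(pwm, seqs, bg)
  all_pos$score_fraction <- (all_pos$score - mn) / (mx - mn)
  hits <- all_pos[all_pos$score_fraction >= f_min, , drop = FALSE]
  hits$word <- hit_words(hits, seqs)
  hits$scheme <- rep("B", nrow(hits))
  rownames(hits) <- NULL
  hits[, c("gene_id", "start", "end", "strand", "word", "score",
           "score_fraction", "scheme")]
}

#' Merge the two scanning schemes into consensus sites
#'
#' Hits from scheme A (p/q-based) and scheme B (fraction-of-max) on the
#' same promoter and orientation are paired when they overlap by at least
#' `overlap_min` of the motif width; pairs get support `both`. Unpaired
#' hits survive only when their promoter's operon is up-regulated
#' (support `A_only_upstream_upregulated` / `B_only_upstream_upregulated`);
#' all other singletons are dropped.
#'
#' @param hits_a,hits_b data.frames from [scan_scheme_a()] and
#'   [scan_scheme_b()] for the same motif and promoter set.
#' @param upregulated_operons character vector of up-regulated operon ids.
#' @param operons an `operon_set` (maps promoter genes to operons).
#' @param overlap_min minimum overlap as a fraction of motif width.
#' @return data.frame of class `consensus_sites`: site_id, gene_id, start,
#'   end, strand, score, p_value, q_value, score_fraction, support.
#' @export
consensus_sites <- function(hits_a, hits_b, upregulated_operons, operons,
                            overlap_min = 0.5) {
  op_of <- setNames(operons$operon_id, operons$gene_id)
  upstream_up <- function(gene) {
    op <- op_of[gene]
    !is.na(op) & op %in% upregulated_operons
  }
  empty <- data.frame(site_id = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      score_fraction = numeric(0), support = character(0),
                      stringsAsFactors = FALSE)
  na <- if (is.null(hits_a)) 0L else nrow(hits_a)
  nb <- if (is.null(hits_b)) 0L else nrow(hits_b)
  rows <- list()
  used_b <- logical(nb)
  # a palindromic motif yields the same site on both orientations; a
  # singleton is redundant when it overlaps an accepted site on any strand
  overlaps_accepted <- function(gene, s, e, w) {
    for (r in rows) {
      if (r$gene_id != gene) next
      if (min(r$end, e) - max(r$start, s) + 1L >= overlap_min * w) return(TRUE)
    }
    FALSE
  }
  if (na) {
    ord <- order(-hits_a$score)
    for (i in ord) {
      w <- hits_a$end[i] - hits_a$start[i] + 1L
      j_cand <- which(!used_b & hits_b$gene_id == hits_a$gene_id[i] &
                        hits_b$strand == hits_a$strand[i])
      paired <- FALSE
      if (length(j_cand)) {
        ov <- pmin(hits_b$end[j_cand], hits_a$end[i]) -
          pmax(hits_b$start[j_cand], hits_a$start[i]) + 1L
        j_ok <- j_cand[ov >= overlap_min * w]
        if (length(j_ok)) {
          j <- j_ok[which.max(hits_b$score[j_ok])]
          used_b[j] <- TRUE
          paired <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = hits_a$gene_id[i], start = hits_a$start[i],
            end = hits_a$end[i], strand = hits_a$strand[i],
            score = hits_a$score[i], p_value = hits_a$p_value[i],
            q_value = hits_a$q_value[i],
            score_fraction = hits_b$score_fraction[j],
            support = "both", stringsAsFactors = FALSE)
        }
      }
      if (!paired && isTRUE(upstream_up(hits_a$gene_id[i])) &&
          !overlaps_accepted(hits_a$gene_id[i], hits_a$start[i],
                             hits_a$end[i], w))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = hits_a$gene_id[i], start = hits_a$start[i],
          end = hits_a$end[i], strand = hits_a$strand[i],
          score = hits_a$score[i], p_value = hits_a$p_value[i],
          q_value = hits_a$q_value[i], score_fraction = NA_real_,
          support = "A_only_upstream_upregulated", stringsAsFactors = FALSE)
    }
  }
  if (nb) {
    for (j in which(!used_b)[order(-hits_b$score[!used_b])]) {
      w <- hits_b$end[j] - hits_b$start[j] + 1L
      if (isTRUE(upstream_up(hits_b$gene_id[j])) &&
          !overlaps_accepted(hits_b$gene_id[j], hits_b$start[j],
                             hits_b$end[j], w))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = hits_b$gene_id[j], start = hits_b$start[j],
          end = hits_b$end[j], strand = hits_b$strand[j],
          score = hits_b$score[j], p_value = NA_real_, q_value = NA_real_,
          score_fraction = hits_b$score_fraction[j],
          support = "B_only_upstream_upregulated", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(structure(empty, class = c("consensus_sites", "data.frame")))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
  out <- data.frame(site_id = sprintf("cs%04d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("consensus_sites", "data.frame"))
}

#' Autoregulation check for a transcription factor
#'
#' TRUE when a consensus site lies in the promoter window of the first gene
#' of the TF's own operon — the operational reading of a binding site "near
#' the start codon" of the regulator itself.
#'
#' @param tf_gene_id gene id of the transcription factor.
#' @param sites `consensus_sites` (or any data.frame with a gene_id
#'   column naming the promoter each site sits in).
#' @param operons an `operon_set`.
#' @export
detect_autoregulation <- function(tf_gene_id, sites, operons) {
  if (!tf_gene_id %in% operons$gene_id)
    stopf("TF gene %s not present in the operon set", tf_gene_id)
  op <- operons$operon_id[operons$gene_id == tf_gene_id][1]
  first <- operons$gene_id[operons$operon_id == op &
                             operons$position == 1L][1]
  !is.null(sites) && nrow(sites) > 0 && first %in% sites$gene_id
}
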