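aln_matrix <- function(alignment) {
  if (inherits(alignment, "sim_alignment")) alignment <- alignment$alignment
  if (inherits(alignment, "AAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (length(unique(nchar(alignment))) != 1L)
    stopf("alignment sequences must have equal length")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Estimate per-column conservation ranks from an alignment
#'
#' A simplified entropy surrogate for phylogeny-aware conservation grading
#' (it is not ConSurf): per-column conservation is the relative entropy of
#' the column's residue frequencies against background amino-acid
#' frequencies; columns are binned into 9 equal-quantile ranks, rank 1
#' being the most conserved. All-gap columns get NA.
#'
#' @param alignment named character vector of aligned sequences (gaps `-`),
#'   an `AAStringSet`, or a `sim_alignment`.
#' @param background named length-20 amino-acid frequencies (default
#'   uniform).
#' @return data.frame: position, conservation (bits), rank (1-9 or NA).
#' @export
estimate_ranks <- function(alignment, background = NULL) {
  M <- aln_matrix(alignment)
  if (nrow(M) < 5) stopf("need at least 5 sequences to estimate ranks")
  bg <- background %||% setNames(rep(1 / 20, 20), AA_LETTERS)
  cons <- apply(M, 2, function(col) {
    col <- col[col %in% AA_LETTERS]
    if (!length(col)) return(NA_real_)
    f <- table(factor(col, levels = AA_LETTERS))
    f <- (as.numeric(f) + 0.5) / (sum(f) + 10)
    sum(f * log2(f / bg))
  })
  rank <- rep(NA_integer_, length(cons))
  ok <- !is.na(cons)
  if (any(ok)) {
    # rank 1 = most conserved = highest relative entropy
    qs <- quantile(cons[ok], probs = seq(0, 1, length.out = 10), type = 7)
    qs[1] <- -Inf; qs[10] <- Inf
    rank[ok] <- 10L - as.integer(cut(cons[ok], breaks = qs, labels = FALSE,
                                     include.lowest = TRUE))
  }
  data.frame(position = seq_along(cons), conservation = unname(cons),
             rank = rank)
}

#' Count query substitutions stratified by conservation rank
#'
#' For every alignment column where the query has a residue (non-gap) and a
#' rank is defined, a substitution is counted when the query residue
#' differs from the reference (majority consensus by default, or a named
#' sequence). Returns 9 counts, rank 1 (most conserved) to rank 9.
#'
#' @param alignment aligned sequences (as in [estimate_ranks()]).
#' @param ranks per-column ranks: a data.frame with columns position and
#'   rank, or an integer vector.
#' @param query_id name of the query sequence (default "query").
#' @param reference `"consensus"` or the name of a sequence in the
#'   alignment.
#' @return named integer vector of length 9 (`rank1`..`rank9`).
#' @export
count_substitutions_by_rank <- function(alignment, ranks,
                                        query_id = "query",
                                        reference = "consensus") {
  M <- aln_matrix(alignment)
  nm <- if (inherits(alignment, "sim_alignment")) names(alignment$alignment)
        else names(alignment) %||% rownames(M)
  rownames(M) <- nm
  if (!query_id %in% rownames(M)) stopf("query %s absent from alignment",
                                        query_id)
  rk <- if (is.data.frame(ranks)) {
    v <- rep(NA_integer_, ncol(M)); v[ranks$position] <- ranks$rank; v
  } else as.integer(ranks)
  if (length(rk) != ncol(M)) stopf("ranks must cover every alignment column")

  ref <- if (identical(reference, "consensus")) {
    apply(M[setdiff(rownames(M), query_id), , drop = FALSE], 2, function(col) {
      col <- col[col %in% AA_LETTERS]
      if (!length(col)) return(NA_character_)
      names(sort(table(col), decreasing = TRUE))[1]
    })
  } else {
    if (!reference %in% rownames(M))
      stopf("reference sequence %s absent from alignment", reference)
    M[reference, ]
  }
  q <- M[query_id, ]
  usable <- q %in% AA_LETTERS & ref %in% AA_LETTERS & !is.na(rk)
  sub <- usable & q != ref
  counts <- vapply(1:9, function(r) sum(sub & rk == r), integer(1))
  setNames(counts, paste0("rank", 1:9))
}
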