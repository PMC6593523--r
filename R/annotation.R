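as_operon_set <- function(df) {
  stopifnot(all(c("operon_id", "gene_id", "contig", "strand", "position")
                %in% names(df)))
  df <- df[order(df$operon_id, df$position), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("operon_set", "data.frame"))
}

empty_operon_set <- function() {
  as_operon_set(data.frame(operon_id = character(0), gene_id = character(0),
                           contig = character(0), strand = character(0),
                           position = integer(0), stringsAsFactors = FALSE))
}

#' First (5'-most) gene of every operon
#' @param operons an `operon_set`.
#' @return data.frame operon_id, gene_id.
#' @export
first_genes <- function(operons) {
  f <- operons[operons$position == 1L, c("operon_id", "gene_id")]
  rownames(f) <- NULL
  f
}

#' Parse a genome plus gene annotation into an annotation object
#'
#' Accepts file paths (FASTA via Biostrings, GFF3 via rtracklayer) or
#' in-memory objects (a `DNAStringSet` plus a data.frame with columns
#' gene_id, contig, start, end, strand). Records are validated — duplicate
#' IDs, unknown strand, coordinates outside the contig — with errors naming
#' the offending record, and returned in stable (contig, start) order.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param annotation GFF3 path, `GRanges`, or data.frame.
#' @return object of class `genome_annotation`: list(genome, genes).
#' @export
parse_annotation <- function(genome, annotation) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!inherits(genome, "DNAStringSet")) stopf("genome must be FASTA or DNAStringSet")
  names(genome) <- sub("\\s.*$", "", names(genome))

  if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation, format = "gff3")
    type <- as.character(S4Vectors::mcols(gr)$type)
    if (!is.null(type) && any(type == "gene")) gr <- gr[type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    genes <- data.frame(
      gene_id = as.character(ids),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else if (inherits(annotation, "GRanges")) {
    genes <- data.frame(
      gene_id = as.character(S4Vectors::mcols(annotation)$ID),
      contig = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(annotation, stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stopf("annotation must provide columns %s", paste(need, collapse = ", "))
  genes <- genes[, need]

  if (anyNA(genes$gene_id) || any(genes$gene_id == ""))
    stopf("annotation contains records without an ID")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stopf("duplicate gene ID: %s", dup[1])
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad)) stopf("gene %s has unknown strand '%s'",
                         genes$gene_id[bad[1]], genes$strand[bad[1]])
  bad <- which(genes$end < genes$start)
  if (length(bad)) stopf("gene %s has end < start", genes$gene_id[bad[1]])
  bad <- which(!genes$contig %in% names(genome))
  if (length(bad)) stopf("gene %s lies on unknown contig '%s'",
                         genes$gene_id[bad[1]], genes$contig[bad[1]])
  clen <- setNames(Biostrings::width(genome), names(genome))
  bad <- which(genes$start < 1 | genes$end > clen[genes$contig])
  if (length(bad)) stopf("gene %s has coordinates outside contig %s",
                         genes$gene_id[bad[1]], genes$contig[bad[1]])

  genes <- genes[order(genes$contig, genes$start), ]
  rownames(genes) <- NULL
  structure(list(genome = genome, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome annotation: %d contigs (%d bp), %d genes\n",
              length(x$genome), sum(Biostrings::width(x$genome)),
              nrow(x$genes)))
  invisible(x)
}

#' Call operons by intergenic distance (and optional co-expression)
#'
#' Consecutive genes (in genome order) on the same strand of the same contig
#' are merged into one operon when the intergenic gap is at most `gap_max`
#' bp; when a per-gene expression matrix is supplied, merging additionally
#' requires a Pearson correlation of at least `corr_min` between the two
#' genes' per-sample expression. Every gene belongs to exactly one operon.
#'
#' @param ann a `genome_annotation` (or a genes data.frame).
#' @param expression optional genes x samples matrix (rownames = gene ids).
#' @param gap_max maximum intergenic gap in bp (default 100).
#' @param corr_min expression-correlation threshold (default 0.7).
#' @return an `operon_set` data.frame (operon_id, gene_id, contig, strand,
#'   position), position 1 being the 5'-most gene in transcription order.
#' @export
call_operons <- function(ann, expression = NULL, gap_max = 100,
                         corr_min = 0.7) {
  genes <- if (inherits(ann, "genome_annotation")) ann$genes else ann
  if (!nrow(genes)) return(empty_operon_set())
  genes <- genes[order(genes$contig, genes$start), ]
  n <- nrow(genes)
  new_block <- logical(n); new_block[1] <- TRUE
  if (n > 1) for (i in 2:n) {
    same <- genes$contig[i] == genes$contig[i - 1] &&
      genes$strand[i] == genes$strand[i - 1]
    gap <- genes$start[i] - genes$end[i - 1] - 1L
    ok <- same && gap <= gap_max
    if (ok && !is.null(expression)) {
      a <- expression[genes$gene_id[i - 1], ]
      b <- expression[genes$gene_id[i], ]
      ok <- isTRUE(sd(a) > 0 && sd(b) > 0 && cor(a, b) >= corr_min)
    }
    new_block[i] <- !ok
  }
  block <- cumsum(new_block)
  rows <- lapply(split(seq_len(n), block), function(idx) {
    strand <- genes$strand[idx[1]]
    ord <- if (strand == "-") rev(idx) else idx
    data.frame(gene_id = genes$gene_id[ord], contig = genes$contig[idx[1]],
               strand = strand, position = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Map(function(df, b) {
    df$operon_id <- sprintf("op%04d", as.integer(b)); df
  }, rows, names(rows)))
  as_operon_set(out[, c("operon_id", "gene_id", "contig", "strand", "position")])
}

#' Extract promoter windows (500 bp upstream + 50 bp downstream of starts)
#'
#' For every requested gene, the window spans positions -upstream..-1 and
#' +1..+downstream relative to the first base of the start codon (+1 being
#' the first coding base, included in the downstream stretch), truncated at
#' contig edges. Minus-strand windows are reverse-complemented so the
#' returned sequence always reads 5'->3' of the gene. Ambiguity codes are
#' replaced by random bases (with a warning).
#'
#' @param ann a `genome_annotation`.
#' @param gene_ids genes to extract (default: all).
#' @param upstream,downstream window extents in bp (defaults 500 and 50).
#' @param seed seed for ambiguity masking.
#' @return data.frame of class `promoter_set`: gene_id, contig, start, end
#'   (genome coordinates of the window), strand, upstream_len,
#'   downstream_len, empty, seq.
#' @export
extract_promoters <- function(ann, gene_ids = NULL, upstream = 500,
                              downstream = 50, seed = 1) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (upstream > 500 || downstream > 50)
    stopf("window exceeds the supported 500+50 convention")
  genes <- ann$genes
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, genes$gene_id)
    if (length(missing)) stopf("unknown gene: %s", missing[1])
    genes <- genes[match(gene_ids, genes$gene_id), ]
  }
  if (!nrow(genes))
    return(structure(data.frame(gene_id = character(0), contig = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0),
                                upstream_len = integer(0),
                                downstream_len = integer(0),
                                empty = logical(0), seq = character(0),
                                stringsAsFactors = FALSE),
                     class = c("promoter_set", "data.frame")))
  clen <- setNames(Biostrings::width(ann$genome), names(ann$genome))
  plus <- genes$strand == "+"
  anchor <- ifelse(plus, genes$start, genes$end)  # first base of start codon
  win_start <- ifelse(plus, anchor - upstream, anchor - downstream + 1L)
  win_end <- ifelse(plus, anchor + downstream - 1L, anchor + upstream)
  win_start <- pmax(win_start, 1L)
  win_end <- pmin(win_end, clen[genes$contig])
  empty <- win_end < win_start
  up_len <- ifelse(plus, anchor - win_start, win_end - anchor)
  down_len <- ifelse(plus, win_end - anchor + 1L, anchor - win_start + 1L)
  up_len <- pmax(up_len, 0L); down_len <- pmax(down_len, 0L)

  seqs <- character(nrow(genes))
  ok <- which(!empty)
  for (i in ok) {
    s <- as.character(Biostrings::subseq(ann$genome[[genes$contig[i]]],
                                         win_start[i], win_end[i]))
    if (genes$strand[i] == "-") s <- revcomp_chr(s)
    seqs[i] <- s
  }
  if (any(grepl("[^ACGT]", seqs))) {
    warning("ambiguity codes in promoter windows replaced by random bases")
    seqs <- with_seed(seed, vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      bad <- !ch %in% DNA_BASES
      if (any(bad)) ch[bad] <- sample(DNA_BASES, sum(bad), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  structure(data.frame(gene_id = genes$gene_id, contig = genes$contig,
                       start = as.integer(win_start),
                       end = as.integer(win_end), strand = genes$strand,
                       upstream_len = as.integer(up_len),
                       downstream_len = as.integer(down_len),
                       empty = empty, seq = seqs, stringsAsFactors = FALSE),
            class = c("promoter_set", "data.frame"))
}

promoter_seqs <- function(promoters) {
  if (inherits(promoters, "promoter_set") ||
      (is.data.frame(promoters) && "seq" %in% names(promoters)))
    return(setNames(promoters$seq, promoters$gene_id))
  if (inherits(promoters, "DNAStringSet"))
    return(setNames(as.character(promoters), names(promoters)))
  if (is.character(promoters)) {
    if (is.null(names(promoters)))
      names(promoters) <- sprintf("seq_%04d", seq_along(promoters))
    return(promoters)
  }
  stopf("cannot interpret promoter set")
}

#' Write a promoter set as FASTA
#'
#' Headers follow `gene_id|contig|start-end|strand`.
#'
#' @param promoters a `promoter_set`.
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  keep <- !promoters$empty
  seqs <- Biostrings::DNAStringSet(promoters$seq[keep])
  names(seqs) <- sprintf("%s|%s|%d-%d|%s", promoters$gene_id[keep],
                         promoters$contig[keep], promoters$start[keep],
                         promoters$end[keep], promoters$strand[keep])
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write an operon set as TSV
#' @param operons an `operon_set`.
#' @param path output path.
#' @export
write_operons_tsv <- function(operons, path) {
  write.table(operons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Propagate binding sites to operon members
#'
#' A site found in the promoter of an operon's first gene is taken to
#' regulate every gene of that operon; sites in promoters of internal genes
#' are reported but flagged `internal` and not propagated.
#'
#' @param sites data.frame with columns site_id and gene_id (the gene whose
#'   promoter window contains the site).
#' @param operons an `operon_set`.
#' @return list: `operon_sites` (operon_id, site_id, via_gene, internal),
#'   `gene_sites` (gene_id, site_id, operon_id, internal).
#' @export
assign_sites_to_operons <- function(sites, operons) {
  if (is.null(sites) || !nrow(sites)) {
    return(list(
      operon_sites = data.frame(operon_id = character(0),
                                site_id = character(0),
                                via_gene = character(0), internal = logical(0),
                                stringsAsFactors = FALSE),
      gene_sites = data.frame(gene_id = character(0), site_id = character(0),
                              operon_id = character(0), internal = logical(0),
                              stringsAsFactors = FALSE)))
  }
  if (!"site_id" %in% names(sites))
    sites$site_id <- sprintf("s%04d", seq_len(nrow(sites)))
  unknown <- setdiff(sites$gene_id, operons$gene_id)
  if (length(unknown)) stopf("site references unknown gene: %s", unknown[1])
  op_of <- setNames(operons$operon_id, operons$gene_id)
  pos_of <- setNames(operons$position, operons$gene_id)

  op_rows <- data.frame(operon_id = unname(op_of[sites$gene_id]),
                        site_id = sites$site_id,
                        via_gene = sites$gene_id,
                        internal = unname(pos_of[sites$gene_id]) != 1L,
                        stringsAsFactors = FALSE)
  gene_rows <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    op <- op_of[[sites$gene_id[i]]]
    if (pos_of[[sites$gene_id[i]]] == 1L) {
      members <- operons$gene_id[operons$operon_id == op]
      data.frame(gene_id = members, site_id = sites$site_id[i],
                 operon_id = op, internal = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = sites$gene_id[i], site_id = sites$site_id[i],
                 operon_id = op, internal = TRUE, stringsAsFactors = FALSE)
    }
  }))
  rownames(gene_rows) <- NULL
  list(operon_sites = op_rows, gene_sites = gene_rows)
}
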