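#' Operons with at least one member in a gene set
#' @param operons an `operon_set`.
#' @param gene_ids character vector (e.g. the DE up-set).
#' @return character vector of operon ids.
#' @export
operons_with_genes <- function(operons, gene_ids) {
  unique(operons$operon_id[operons$gene_id %in% gene_ids])
}

#' Build the per-TF regulon report
#'
#' Propagates consensus sites through operons (a site before an operon's
#' first gene regulates all its members), summarises each regulated operon
#' (member genes, arithmetic-mean fold change, overlap with the DE up-set),
#' flags autoregulation for TFs whose own gene is given, and tabulates
#' co-occurrence with other TFs' site sets.
#'
#' @param sites `consensus_sites` for the primary TF motif.
#' @param operons an `operon_set`.
#' @param de a `de_table` (genes absent from it are flagged, not fatal).
#' @param other_tf_sites optional named list of `consensus_sites` for other
#'   TFs (co-occurrence).
#' @param tf_gene optional gene id of the primary TF (autoregulation flag).
#' @param fc_min,q_max thresholds used to mark operons as up-regulated.
#' @return object of class `regulon_report`: `operons` (one row per
#'   regulated operon), `genes` (per-gene assignment), `co_occurrence`
#'   (operon x TF logical matrix), `autoregulation`, `n_operons`,
#'   `n_genes`.
#' @export
build_regulon_report <- function(sites, operons, de,
                                 other_tf_sites = NULL, tf_gene = NULL,
                                 fc_min = 3, q_max = 0.01) {
  assign <- assign_sites_to_operons(sites, operons)
  reg_ops <- unique(assign$operon_sites$operon_id[!assign$operon_sites$internal])
  fc <- setNames(de$fold_change, de$gene_id)
  q <- setNames(de$q_value, de$gene_id)

  op_rows <- lapply(reg_ops, function(op) {
    members <- operons$gene_id[operons$operon_id == op]
    absent <- setdiff(members, de$gene_id)
    if (length(absent))
      warning(sprintf("gene %s has sites but is absent from the DE table",
                      absent[1]))
    mfc <- fc[intersect(members, de$gene_id)]
    n_up <- sum(mfc >= fc_min & q[names(mfc)] <= q_max, na.rm = TRUE)
    data.frame(operon_id = op, n_genes = length(members),
               genes = paste(members, collapse = ","),
               n_sites = sum(assign$operon_sites$operon_id == op &
                               !assign$operon_sites$internal),
               mean_fold_change = if (length(mfc)) mean(mfc) else NA_real_,
               n_up_members = n_up,
               upregulated = n_up > 0, stringsAsFactors = FALSE)
  })
  op_df <- if (length(op_rows)) do.call(rbind, op_rows)
  else data.frame(operon_id = character(0), n_genes = integer(0),
                  genes = character(0), n_sites = integer(0),
                  mean_fold_change = numeric(0), n_up_members = integer(0),
                  upregulated = logical(0), stringsAsFactors = FALSE)

  gene_df <- assign$gene_sites[!assign$gene_sites$internal, , drop = FALSE]
  rownames(gene_df) <- NULL

  tf_names <- c("primary", names(other_tf_sites))
  co <- matrix(FALSE, nrow = length(reg_ops), ncol = length(tf_names),
               dimnames = list(reg_ops, tf_names))
  if (length(reg_ops)) {
    co[, "primary"] <- TRUE
    for (tf in names(other_tf_sites)) {
      a <- assign_sites_to_operons(other_tf_sites[[tf]], operons)
      ops <- unique(a$operon_sites$operon_id[!a$operon_sites$internal])
      co[, tf] <- reg_ops %in% ops
    }
  }

  auto <- if (!is.null(tf_gene))
    detect_autoregulation(tf_gene, sites, operons) else NA

  structure(list(operons = op_df, genes = gene_df, co_occurrence = co,
                 autoregulation = auto,
                 internal_sites = assign$operon_sites[
                   assign$operon_sites$internal, , drop = FALSE],
                 n_operons = nrow(op_df),
                 n_genes = length(unique(gene_df$gene_id))),
            class = "regulon_report")
}

#' @export
print.regulon_report <- function(x, ...) {
  cat(sprintf("regulon report: %d operons, %d genes with consensus sites\n",
              x$n_operons, x$n_genes))
  if (x$n_operons) {
    up <- sum(x$operons$upregulated)
    cat(sprintf("  %d of %d operons up-regulated; mean operon fold change %.2f\n",
                up, x$n_operons,
                mean(x$operons$mean_fold_change, na.rm = TRUE)))
  }
  if (!is.na(x$autoregulation))
    cat(sprintf("  autoregulation: %s\n", x$autoregulation))
  invisible(x)
}

#' Write a regulon report as TSV and JSON
#'
#' @param report a `regulon_report`.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_regulon_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(operons = file.path(dir, "regulon_operons.tsv"),
             genes = file.path(dir, "regulon_genes.tsv"),
             json = file.path(dir, "regulon_report.json"))
  write.table(report$operons, paths["operons"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(n_operons = report$n_operons, n_genes = report$n_genes,
         autoregulation = report$autoregulation,
         operons = report$operons,
         co_occurrence = as.data.frame(report$co_occurrence)),
    paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write consensus sites as BED6 (promoter-relative and genome-projected)
#'
#' BED is 0-based half-open; the score column is the log-odds score x 100,
#' rounded. The genome projection uses the promoter windows' genome
#' coordinates and flips strand for minus-strand genes.
#'
#' @param sites `consensus_sites` (or scheme hits) with promoter-relative
#'   coordinates.
#' @param promoters the `promoter_set` the sites were found in.
#' @param path_promoter,path_genome output BED paths (`NULL` to skip one).
#' @return invisible list of the two BED data.frames.
#' @export
write_sites_bed <- function(sites, promoters, path_promoter = NULL,
                            path_genome = NULL) {
  ids <- if ("site_id" %in% names(sites)) sites$site_id
         else sprintf("s%04d", seq_len(nrow(sites)))
  prom_bed <- data.frame(chrom = sites$gene_id,
                         start = sites$start - 1L, end = sites$end,
                         name = ids,
                         score = as.integer(round(sites$score * 100)),
                         strand = sites$strand, stringsAsFactors = FALSE)
  idx <- match(sites$gene_id, promoters$gene_id)
  if (anyNA(idx)) stopf("site gene %s not in promoter set",
                        sites$gene_id[which(is.na(idx))[1]])
  plus <- promoters$strand[idx] == "+"
  gstart <- ifelse(plus, promoters$start[idx] + sites$start - 1L,
                   promoters$end[idx] - sites$end + 1L)
  gend <- ifelse(plus, promoters$start[idx] + sites$end - 1L,
                 promoters$end[idx] - sites$start + 1L)
  gstrand <- ifelse((sites$strand == "+") == plus, "+", "-")
  genome_bed <- data.frame(chrom = promoters$contig[idx],
                           start = gstart - 1L, end = gend,
                           name = ids,
                           score = as.integer(round(sites$score * 100)),
                           strand = gstrand, stringsAsFactors = FALSE)
  if (!is.null(path_promoter))
    write.table(prom_bed, path_promoter, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  if (!is.null(path_genome))
    write.table(genome_bed, path_genome, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(list(promoter = prom_bed, genome = genome_bed))
}

#' Run the full regulon-inference pipeline
#'
#' End-to-end orchestration: differential expression on the counts, operon
#' calling, promoter extraction (500+50 windows), motif discovery on the
#' promoters of up-regulated genes (unless a motif is supplied), dual-scheme
#' scanning of all promoters, consensus-site merging with the up-regulated
#' operon rescue rule, operon propagation and report building.
#'
#' @param ann a `genome_annotation`.
#' @param counts genes x samples count matrix.
#' @param condition per-column condition labels (`control` / `induced`).
#' @param motif optional `pwm` to scan with; when `NULL` the rank-1
#'   discovered motif is used.
#' @param gap_max operon-calling gap (bp).
#' @param upstream,downstream promoter window extents.
#' @param fc_min,q_max DE selection thresholds.
#' @param scan_q_max scheme-A FDR threshold.
#' @param f_min scheme-B score fraction threshold.
#' @param n_report,n_null,width_grid discovery parameters (see
#'   [discover_motifs()]).
#' @param tf_gene optional TF gene id for the autoregulation flag.
#' @param other_tf_motifs optional named list of `pwm`s (e.g. KstR) whose
#'   consensus sites are reported for co-occurrence.
#' @param seed RNG seed for discovery.
#' @return list of class `regulon_pipeline` with every stage's output:
#'   de, up, operons, promoters, discovery, motif, hits_a, hits_b,
#'   consensus, report.
#' @export
run_regulon_pipeline <- function(ann, counts, condition, motif = NULL,
                                 gap_max = 100, upstream = 500,
                                 downstream = 50, fc_min = 3, q_max = 0.01,
                                 scan_q_max = 0.01, f_min = 0.85,
                                 n_report = 3, n_null = 50,
                                 width_grid = NULL, tf_gene = NULL,
                                 other_tf_motifs = NULL, seed = 1817) {
  de <- de_table(counts, condition, fc_min = fc_min, q_max = q_max)
  up <- select_regulated(de, fc_min = fc_min, q_max = q_max)$up
  operons <- call_operons(ann, gap_max = gap_max)
  promoters <- extract_promoters(ann, upstream = upstream,
                                 downstream = downstream)
  promoters <- promoters[!promoters$empty, , drop = FALSE]
  discovery <- NULL
  if (is.null(motif)) {
    up_prom <- promoters[promoters$gene_id %in% up, , drop = FALSE]
    discovery <- discover_motifs(up_prom, n_report = n_report,
                                 n_null = n_null, width_grid = width_grid,
                                 seed = seed)
    motif <- discovery$motifs[[1]]$pwm
  }
  bg <- background_frequencies(promoters$seq)
  hits_a <- scan_scheme_a(motif, promoters, background = bg,
                          q_max = scan_q_max)
  hits_b <- scan_scheme_b(motif, promoters, background = bg, f_min = f_min)
  up_ops <- operons_with_genes(operons, up)
  consensus <- consensus_sites(hits_a, hits_b, up_ops, operons)
  other_sites <- NULL
  if (!is.null(other_tf_motifs)) {
    other_sites <- lapply(other_tf_motifs, function(p) {
      ha <- scan_scheme_a(p, promoters, background = bg, q_max = scan_q_max)
      hb <- scan_scheme_b(p, promoters, background = bg, f_min = f_min)
      consensus_sites(ha, hb, up_ops, operons)
    })
  }
  report <- build_regulon_report(consensus, operons, de,
                                 other_tf_sites = other_sites,
                                 tf_gene = tf_gene,
                                 fc_min = fc_min, q_max = q_max)
  structure(list(de = de, up = up, operons = operons,
                 promoters = promoters, discovery = discovery,
                 motif = motif, hits_a = hits_a, hits_b = hits_b,
                 consensus = consensus, report = report),
            class = "regulon_pipeline")
}

#' @export
print.regulon_pipeline <- function(x, ...) {
  cat(sprintf(
    "regulon pipeline: %d genes, %d up-regulated; motif '%s' (%s)\n",
    nrow(x$de), length(x$up), x$motif$name, consensus_string(x$motif)))
  cat(sprintf("  scheme A hits: %d, scheme B hits: %d, consensus sites: %d\n",
              nrow(x$hits_a), nrow(x$hits_b), nrow(x$consensus)))
  print(x$report)
  invisible(x)
}

#' Bundled synthetic stand-in motifs for KstR and KstR2
#'
#' The package ships reconstructed, clearly synthetic stand-ins for the
#' KstR and KstR2 operator motifs (the steroid-catabolism TetR-family
#' repressors); the originals are not distributed here. Useful for
#' exercising multi-TF co-occurrence reporting.
#'
#' @return named list of `pwm` objects.
#' @export
load_reference_motifs <- function() {
  path <- system.file("extdata", "kstr_motifs_synthetic.meme",
                      package = "regulonScout")
  if (path == "") stopf("bundled motif file missing")
  read_meme(path)
}
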