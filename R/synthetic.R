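#' Default planted motif: a 14-bp palindromic TetR-like operator
#'
#' The consensus `AAGTACGCGTACTT` is its own reverse complement. With the
#' default consensus probability 0.9 the motif carries about 19 bits of
#' information (about 1.4 bits/column), typical of a bacterial TetR-family
#' operator. `consensus_prob = 0.8` gives about 13.5 bits, a deliberately
#' weaker signal useful for discovery benchmarks.
#'
#' @param consensus palindromic consensus string.
#' @param consensus_prob per-column probability of the consensus base.
#' @export
default_planted_pwm <- function(consensus = "AAGTACGCGTACTT",
                                consensus_prob = 0.9) {
  cd <- encode_dna(toupper(consensus))[[1]]
  if (any(cd == 0L)) stopf("consensus must be over A,C,G,T")
  w <- length(cd)
  prob <- matrix((1 - consensus_prob) / 3, 4, w)
  prob[cbind(cd, seq_len(w))] <- consensus_prob
  new_pwm(prob, name = "planted_motif")
}

#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a multi-operon bacterial genome, a TF motif
#' planted in the promoters of a subset of operons, and a two-condition
#' (control vs induced), replicated, negative-binomially distributed count
#' matrix in which planted-regulon genes are up-regulated and background
#' genes are not. Defaults mirror a two-condition, two-replicate bacterial
#' RNA-seq design with a 5-fold induced regulon.
#'
#' @param n_genes number of genes.
#' @param genome_length optional total genome length; computed from the gene
#'   layout when `NULL`, and an error is raised if a supplied value cannot
#'   accommodate the layout.
#' @param operon_gap_max maximum intra-operon intergenic gap (bp).
#' @param n_operons_regulon number of operons carrying a planted site.
#' @param planted_pwm `pwm` the planted sites are sampled from.
#' @param site_position_range integer interval (relative to the start codon,
#'   negative = upstream) in which the planted site starts.
#' @param regulon_fold_change induced/control expression ratio of regulon
#'   genes (>= 1).
#' @param background_fold_change ratio for background genes (~1).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param mean_expression scale of per-gene mean counts; per-gene base means
#'   are drawn uniformly from 0.4x to 2x this value.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param gc_content genome GC content.
#' @param random_site_orientation plant sites in random orientation instead
#'   of the coding strand of the downstream gene.
#' @param seed integer seed; all generator randomness derives from it.
#' @export
sim_config <- function(n_genes = 300, genome_length = NULL,
                       operon_gap_max = 100, n_operons_regulon = 30,
                       planted_pwm = default_planted_pwm(),
                       site_position_range = c(-80L, -40L),
                       regulon_fold_change = 5, background_fold_change = 1,
                       nb_dispersion = 0.02, mean_expression = 500,
                       n_replicates = 2, gc_content = 0.5,
                       random_site_orientation = FALSE, seed = 1) {
  if (n_genes < 0) stopf("n_genes must be >= 0")
  if (regulon_fold_change < 1) stopf("regulon_fold_change must be >= 1")
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (mean_expression < 0) stopf("mean_expression must be >= 0")
  if (gc_content <= 0 || gc_content >= 1) stopf("gc_content must be in (0,1)")
  if (length(site_position_range) != 2L ||
      site_position_range[1] > site_position_range[2])
    stopf("site_position_range must be an increasing interval")
  if (site_position_range[2] + pwm_width(planted_pwm) - 1 > -1)
    stopf("planted sites must end upstream of the start codon")
  structure(list(n_genes = as.integer(n_genes), genome_length = genome_length,
                 operon_gap_max = as.integer(operon_gap_max),
                 n_operons_regulon = as.integer(n_operons_regulon),
                 planted_pwm = planted_pwm,
                 site_position_range = as.integer(site_position_range),
                 regulon_fold_change = regulon_fold_change,
                 background_fold_change = background_fold_change,
                 nb_dispersion = nb_dispersion,
                 mean_expression = mean_expression,
                 n_replicates = as.integer(n_replicates),
                 gc_content = gc_content,
                 random_site_orientation = random_site_orientation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sample_bases <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = probs)
}

sample_site <- function(pwm) {
  paste(vapply(seq_len(pwm_width(pwm)), function(k)
    sample(DNA_BASES, 1, prob = pwm$prob[, k]), character(1)), collapse = "")
}

#' Generate a synthetic annotated genome with planted binding sites
#'
#' Lays out genes in operons (runs of same-strand genes separated by short
#' intra-operon gaps, with at least 600 bp of intergenic space before each
#' operon's first gene), samples a background genome, and writes sites drawn
#' from `config$planted_pwm` into the promoter regions of the first genes of
#' the chosen regulon operons. The returned truth table records the regulon
#' gene set, the exact coordinates and sequence of every planted site, and
#' per-gene true fold changes.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome`: `genome` (DNAStringSet), `genes`
#'   (data.frame: gene_id, contig, start, end, strand), `operons`
#'   (operon_set data.frame), `truth` (class `sim_truth`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  contig <- "chr1"
  if (config$n_genes == 0L) {
    len <- config$genome_length %||% 1000L
    genome <- Biostrings::DNAStringSet(
      setNames(paste(sample_bases(len, config$gc_content), collapse = ""), contig))
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    operons <- empty_operon_set()
    truth <- new_sim_truth(character(0), empty_planted_sites(),
                           setNames(numeric(0), character(0)), config)
    return(structure(list(genome = genome, genes = genes, operons = operons,
                          truth = truth), class = "sim_genome"))
  }

  # operon sizes: mostly 1-3 genes
  sizes <- integer(0)
  while (sum(sizes) < config$n_genes)
    sizes <- c(sizes, sample(1:3, 1, prob = c(0.55, 0.30, 0.15)))
  excess <- sum(sizes) - config$n_genes
  if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0]
  n_op <- length(sizes)
  if (config$n_operons_regulon > n_op)
    stopf("n_operons_regulon (%d) exceeds total operons (%d)",
          config$n_operons_regulon, n_op)

  margin <- 650L
  gap_hi <- max(10L, min(80L, config$operon_gap_max))
  cursor <- margin
  gene_rows <- vector("list", n_op)
  op_strand <- character(n_op)
  gid <- 0L
  for (o in seq_len(n_op)) {
    strand <- sample(c("+", "-"), 1)
    op_strand[o] <- strand
    starts <- ends <- integer(sizes[o])
    for (g in seq_len(sizes[o])) {
      len <- sample(300:900, 1)
      starts[g] <- cursor + 1L
      ends[g] <- cursor + len
      cursor <- ends[g]
      if (g < sizes[o]) cursor <- cursor + sample(10:gap_hi, 1)
    }
    ids <- sprintf("g%04d", gid + seq_len(sizes[o]))
    gid <- gid + sizes[o]
    gene_rows[[o]] <- data.frame(gene_id = ids, contig = contig,
                                 start = starts, end = ends, strand = strand,
                                 operon_index = o, stringsAsFactors = FALSE)
    cursor <- cursor + sample(620:900, 1)
  }
  genes_all <- do.call(rbind, gene_rows)
  required <- max(genes_all$end) + margin
  glen <- config$genome_length %||% required
  if (glen < required)
    stopf("genome_length %d cannot accommodate %d genes (need >= %d)",
          glen, config$n_genes, required)

  base_vec <- sample_bases(glen, config$gc_content)

  # transcription order within operons
  op_list <- lapply(seq_len(n_op), function(o) {
    df <- gene_rows[[o]]
    if (op_strand[o] == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$position <- seq_len(nrow(df))
    df
  })
  operons <- do.call(rbind, lapply(seq_len(n_op), function(o) {
    df <- op_list[[o]]
    data.frame(operon_id = sprintf("op%04d", o), gene_id = df$gene_id,
               contig = contig, strand = op_strand[o],
               position = df$position, stringsAsFactors = FALSE)
  }))
  operons <- as_operon_set(operons)

  # plant sites
  reg_ops <- sort(sample(seq_len(n_op), config$n_operons_regulon))
  w <- pwm_width(config$planted_pwm)
  site_rows <- vector("list", length(reg_ops))
  for (i in seq_along(reg_ops)) {
    o <- reg_ops[i]
    first <- op_list[[o]][1, ]
    site <- sample_site(config$planted_pwm)
    d <- sample(config$site_position_range[1]:config$site_position_range[2], 1)
    if (first$strand == "+") {
      gstart <- first$start + d
      gend <- gstart + w - 1L
      written <- if (config$random_site_orientation && runif(1) < 0.5)
        revcomp_chr(site) else site
    } else {
      gend <- first$end - d
      gstart <- gend - w + 1L
      written <- if (config$random_site_orientation && runif(1) < 0.5)
        site else revcomp_chr(site)
    }
    base_vec[gstart:gend] <- strsplit(written, "")[[1]]
    site_rows[[i]] <- data.frame(
      site_id = sprintf("site%03d", i),
      operon_id = sprintf("op%04d", o), gene_id = first$gene_id,
      contig = contig, start = gstart, end = gend,
      strand = first$strand, seq = site, promoter_offset = d,
      stringsAsFactors = FALSE)
  }
  planted <- if (length(site_rows)) do.call(rbind, site_rows)
             else empty_planted_sites()

  genome <- Biostrings::DNAStringSet(
    setNames(paste(base_vec, collapse = ""), contig))

  regulon_genes <- operons$gene_id[operons$operon_id %in%
                                     sprintf("op%04d", reg_ops)]
  fold <- setNames(rep(config$background_fold_change, nrow(genes_all)),
                   genes_all$gene_id)
  fold[regulon_genes] <- config$regulon_fold_change

  genes <- genes_all[order(genes_all$start),
                     c("gene_id", "contig", "start", "end", "strand")]
  rownames(genes) <- NULL
  truth <- new_sim_truth(regulon_genes, planted, fold, config)
  structure(list(genome = genome, genes = genes, operons = operons,
                 truth = truth), class = "sim_genome")
}

empty_planted_sites <- function() {
  data.frame(site_id = character(0), operon_id = character(0),
             gene_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             seq = character(0), promoter_offset = integer(0),
             stringsAsFactors = FALSE)
}

new_sim_truth <- function(regulon_gene_ids, planted_sites, true_fold_change,
                          config) {
  structure(list(regulon_gene_ids = regulon_gene_ids,
                 planted_sites = planted_sites,
                 true_fold_change = true_fold_change,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic genome: %d bp, %d genes in %d operons, %d regulon genes, %d planted sites\n",
    sum(Biostrings::width(x$genome)), nrow(x$genes),
    length(unique(x$operons$operon_id)),
    length(x$truth$regulon_gene_ids), nrow(x$truth$planted_sites)))
  invisible(x)
}

#' Simulate a two-condition replicated count matrix
#'
#' Counts are negative-binomial with per-gene base means drawn uniformly from
#' 0.4x-2x `mean_expression`, multiplied by the gene's true fold change in
#' the induced condition and by log-normal(0, 0.1) library-size factors.
#'
#' @param truth a `sim_truth` (from [generate_genome()]).
#' @param config the matching [sim_config()].
#' @return list of class `sim_counts`: `counts` (genes x samples integer
#'   matrix, columns `control_1..control_n, induced_1..induced_n`),
#'   `size_factors`, `base_means`, `condition`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (config$mean_expression < 0) stopf("mean_expression must be >= 0")
  fold <- truth$true_fold_change
  if (any(is.na(fold))) stopf("truth lacks fold changes for some genes")
  with_seed(child_seed(config$seed, 2L), {
    n <- length(fold)
    nr <- config$n_replicates
    base <- runif(n, 0.4, 2) * config$mean_expression
    sf <- rlnorm(2L * nr, 0, 0.1)
    cond <- rep(c("control", "induced"), each = nr)
    cols <- paste(cond, rep(seq_len(nr), 2), sep = "_")
    counts <- matrix(0L, n, 2L * nr, dimnames = list(names(fold), cols))
    for (j in seq_len(2L * nr)) {
      mu <- base * sf[j]
      if (cond[j] == "induced") mu <- mu * fold
      counts[, j] <- rnbinom(n, size = 1 / config$nb_dispersion, mu = mu)
    }
    structure(list(counts = counts, size_factors = setNames(sf, cols),
                   base_means = setNames(base, names(fold)),
                   condition = setNames(cond, cols)),
              class = "sim_counts")
  })
}

#' Simulate a qPCR Cq table
#'
#' `Cq = baseline - log2(expression) + N(0, noise_sd)`, with control
#' expression 1 and induced expression equal to the gene's fold change.
#' Reference genes have fold 1; with `n_ref_genes = 3` they are named
#' rpoB, rpoD, ftsQ (the usual mycobacterial reference panel).
#'
#' @param true_fold named positive vector of per-target-gene fold changes.
#' @param n_ref_genes number of reference genes (>= 1).
#' @param noise_sd Gaussian Cq noise (cycles).
#' @param n_replicates replicates per condition.
#' @param baseline Cq of a unit-expression gene.
#' @param seed RNG seed.
#' @return data.frame of class `cq_table` (gene, condition, replicate, cq)
#'   with attribute `ref_genes`.
#' @export
simulate_cq <- function(true_fold, n_ref_genes = 3, noise_sd = 0.2,
                        n_replicates = 2, baseline = 25, seed = 1) {
  if (any(true_fold <= 0)) stopf("true_fold must be > 0")
  if (n_ref_genes < 1) stopf("need at least one reference gene")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.null(names(true_fold)))
    names(true_fold) <- sprintf("target_%02d", seq_along(true_fold))
  refs <- if (n_ref_genes == 3) c("rpoB", "rpoD", "ftsQ")
          else sprintf("ref_%02d", seq_len(n_ref_genes))
  fold <- c(true_fold, setNames(rep(1, n_ref_genes), refs))
  with_seed(seed, {
    grid <- expand.grid(gene = names(fold),
                        condition = c("control", "induced"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    expr <- ifelse(grid$condition == "induced", fold[grid$gene], 1)
    grid$cq <- baseline - log2(expr) + rnorm(nrow(grid), 0, noise_sd)
    structure(grid, class = c("cq_table", "data.frame"),
              ref_genes = refs)
  })
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a ranked protein alignment
#'
#' Generates a consensus protein sequence, homolog sequences whose
#' per-position substitution rate increases with the position's conservation
#' rank (1 = most conserved, 9 = least), and a query equal to the consensus
#' except at the requested substitutions.
#'
#' @param length alignment length.
#' @param n_seqs number of homolog sequences.
#' @param rank_profile integer vector (length `length`) of ranks 1..9.
#' @param query_subs optional data.frame(position, residue) of query
#'   substitutions; a residue equal to the consensus is rejected.
#' @param seed RNG seed.
#' @return list of class `sim_alignment`: `alignment` (named character,
#'   query first), `ranks` (data.frame position, rank), `consensus`.
#' @export
simulate_alignment <- function(length, n_seqs, rank_profile,
                               query_subs = NULL, seed = 1) {
  len <- as.integer(length)
  if (base::length(rank_profile) != len)
    stopf("rank_profile must have one rank per position")
  if (!all(rank_profile %in% 1:9)) stopf("ranks must be integers 1..9")
  with_seed(seed, {
    cons <- sample(AA_LETTERS, len, replace = TRUE)
    # substitution probability rises linearly with rank: 0.02 (rank 1,
    # essentially invariant) to 0.66 (rank 9, the consensus residue still
    # the single most frequent one)
    p_sub <- 0.02 + (rank_profile - 1) * 0.08
    homologs <- vapply(seq_len(n_seqs), function(i) {
      s <- cons
      hit <- runif(len) < p_sub
      if (any(hit))
        s[hit] <- vapply(which(hit), function(j)
          sample(setdiff(AA_LETTERS, cons[j]), 1), character(1))
      paste(s, collapse = "")
    }, character(1))
    query <- cons
    if (!is.null(query_subs) && nrow(query_subs) > 0) {
      if (any(query_subs$position < 1 | query_subs$position > len))
        stopf("query substitution positions out of range")
      for (i in seq_len(nrow(query_subs))) {
        pos <- query_subs$position[i]; res <- query_subs$residue[i]
        if (res == cons[pos])
          stopf("substitution at position %d equals the consensus residue", pos)
        query[pos] <- res
      }
    }
    aln <- c(query = paste(query, collapse = ""),
             setNames(homologs, sprintf("hom_%03d", seq_len(n_seqs))))
    structure(list(alignment = aln,
                   ranks = data.frame(position = seq_len(len),
                                      rank = as.integer(rank_profile)),
                   consensus = paste(cons, collapse = "")),
              class = "sim_alignment")
  })
}

#' Simulate a promoter set with planted motif occurrences
#'
#' A direct stand-in for the promoter extraction output: `n_promoters`
#' windows of `length` bp (position `length - downstream + 1` is the first
#' base of the start codon, mirroring a 500+50 window when `length = 550`),
#' with one site sampled from `pwm` planted in each of `n_planted`
#' promoters at an offset drawn from `position_range` (relative to the
#' start codon).
#'
#' @param n_promoters,length promoter count and width.
#' @param pwm planted `pwm`.
#' @param n_planted number of promoters receiving a site.
#' @param position_range start offset interval relative to the start codon.
#' @param downstream downstream bases included in the window (default 50).
#' @param gc_content background GC.
#' @param seed RNG seed.
#' @return list: `seqs` (named character), `planted` (data.frame seq_id,
#'   start, end, strand, seq in promoter coordinates), `pwm`.
#' @export
simulate_promoter_set <- function(n_promoters = 300, length = 550,
                                  pwm = default_planted_pwm(),
                                  n_planted = 60,
                                  position_range = c(-80L, -40L),
                                  downstream = 50, gc_content = 0.5,
                                  seed = 1) {
  if (n_planted > n_promoters) stopf("n_planted exceeds n_promoters")
  w <- pwm_width(pwm)
  anchor <- length - downstream  # promoter index of position -1
  with_seed(seed, {
    seqs <- vapply(seq_len(n_promoters), function(i)
      paste(sample_bases(length, gc_content), collapse = ""), character(1))
    names(seqs) <- sprintf("prom_%03d", seq_len(n_promoters))
    idx <- sort(sample(n_promoters, n_planted))
    rows <- vector("list", base::length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      site <- sample_site(pwm)
      d <- sample(position_range[1]:position_range[2], 1)
      s <- anchor + 1L + d          # promoter index of offset d
      if (s < 1 || s + w - 1L > length)
        stopf("planted site does not fit in the promoter window")
      substr(seqs[i], s, s + w - 1L) <- site
      rows[[k]] <- data.frame(seq_id = names(seqs)[i], start = s,
                              end = s + w - 1L, strand = "+", seq = site,
                              stringsAsFactors = FALSE)
    }
    list(seqs = seqs, planted = do.call(rbind, rows), pwm = pwm)
  })
}

#' Write a simulated genome, annotation, counts and truth to disk
#'
#' FASTA via Biostrings, GFF3 via rtracklayer, counts and truth as TSV,
#' truth additionally as JSON. Outputs are byte-deterministic for a fixed
#' config seed.
#'
#' @param sim a `sim_genome`.
#' @param dir output directory (created if needed).
#' @param counts optional `sim_counts` to write alongside.
#' @return invisible named vector of written paths.
#' @export
write_sim_genome <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             operons = file.path(dir, "operons.tsv"),
             truth_tsv = file.path(dir, "truth.tsv"),
             truth_json = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  gr <- GenomicRanges::GRanges(
    seqnames = sim$genes$contig,
    ranges = IRanges::IRanges(sim$genes$start, sim$genes$end),
    strand = sim$genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- sim$genes$gene_id
  rtracklayer::export(gr, paths["gff"], format = "gff3")
  write.table(sim$operons, paths["operons"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tf <- data.frame(gene_id = names(sim$truth$true_fold_change),
                   true_fold_change = unname(sim$truth$true_fold_change),
                   in_regulon = names(sim$truth$true_fold_change) %in%
                     sim$truth$regulon_gene_ids)
  write.table(tf, paths["truth_tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(regulon_gene_ids = sim$truth$regulon_gene_ids,
         planted_sites = sim$truth$planted_sites),
    paths["truth_json"], auto_unbox = TRUE, digits = NA)
  if (!is.null(counts)) {
    paths["counts"] <- file.path(dir, "counts.tsv")
    df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                     check.names = FALSE)
    write.table(df, paths["counts"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
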