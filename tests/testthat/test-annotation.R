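test_that("annotation parsing validates records and keeps stable order", {
  genome <- Biostrings::DNAStringSet(c(chr = rand_dna(2000, seed = 1)))
  one <- data.frame(gene_id = "g1", contig = "chr", start = 101, end = 400,
                    strand = "+", stringsAsFactors = FALSE)
  ann <- parse_annotation(genome, one)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(ann$genes$start, 101)

  bad <- one; bad$end <- 50
  expect_error(parse_annotation(genome, bad), "end < start")
  expect_error(parse_annotation(genome, rbind(one, one)), "duplicate")
  odd <- one; odd$strand <- "."
  expect_error(parse_annotation(genome, odd), "strand")
  off <- one; off$end <- 99999
  expect_error(parse_annotation(genome, off), "outside contig")
  lost <- one; lost$contig <- "nope"
  expect_error(parse_annotation(genome, lost), "unknown contig")
})

test_that("generator output round-trips through FASTA/GFF3 files", {
  cfg <- sim_config(n_genes = 30, n_operons_regulon = 3, seed = 8)
  sim <- generate_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_genome(sim, dir)
  ann <- parse_annotation(paths[["genome"]], paths[["gff"]])
  expect_equal(nrow(ann$genes), 30)
  expect_setequal(ann$genes$gene_id, sim$genes$gene_id)
  expect_equal(ann$genes[order(ann$genes$gene_id), ],
               sim$genes[order(sim$genes$gene_id), ],
               ignore_attr = TRUE)
})

test_that("operon calling follows the gap rule and partitions the genes", {
  genome <- Biostrings::DNAStringSet(c(chr = rand_dna(5000, seed = 2)))
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    contig = "chr",
    start = c(101, 511, 1000, 1500),   # a-b gap 10; b-c gap 98; c-d gap 99
    end = c(500, 900, 1400, 1900),
    strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  ann <- parse_annotation(genome, genes)
  ops <- call_operons(ann, gap_max = 100)
  opmap <- setNames(ops$operon_id, ops$gene_id)
  expect_equal(unname(opmap["a"]), unname(opmap["b"]))   # 10 bp gap merges
  expect_false(opmap["b"] == opmap["c"])                 # strand switch splits
  expect_equal(unname(opmap["c"]), unname(opmap["d"]))
  # minus-strand operon order: 5'-most gene is the rightmost
  expect_equal(ops$gene_id[ops$operon_id == opmap["c"] & ops$position == 1],
               "d")
  # partition: every gene exactly once
  expect_setequal(ops$gene_id, genes$gene_id)
  expect_equal(anyDuplicated(ops$gene_id), 0L)
})

test_that("expression correlation can veto a gap-rule merge", {
  genome <- Biostrings::DNAStringSet(c(chr = rand_dna(3000, seed = 3)))
  genes <- data.frame(gene_id = c("a", "b"), contig = "chr",
                      start = c(101, 511), end = c(500, 900),
                      strand = "+", stringsAsFactors = FALSE)
  ann <- parse_annotation(genome, genes)
  expr <- rbind(a = c(10, 20, 30, 40), b = c(40, 30, 20, 10))
  ops <- call_operons(ann, expression = expr, gap_max = 100, corr_min = 0.7)
  expect_equal(length(unique(ops$operon_id)), 2)
  expr2 <- rbind(a = c(10, 20, 30, 40), b = c(11, 19, 33, 41))
  ops2 <- call_operons(ann, expression = expr2, gap_max = 100,
                       corr_min = 0.7)
  expect_equal(length(unique(ops2$operon_id)), 1)
})

test_that("operon recovery on simulated genomes matches the truth", {
  for (seed in c(5, 6)) {
    cfg <- sim_config(n_genes = 120, n_operons_regulon = 10, seed = seed)
    sim <- generate_genome(cfg)
    ann <- parse_annotation(sim$genome, sim$genes)
    ops <- call_operons(ann, gap_max = cfg$operon_gap_max)
    pairs <- function(o) {
      sp <- split(o$gene_id, o$operon_id)
      unlist(lapply(sp, function(g) if (length(g) > 1)
        utils::combn(sort(g), 2, paste, collapse = "|")), use.names = FALSE)
    }
    a <- pairs(ops); b <- pairs(sim$operons)
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_gte(jac, 0.9)
  }
})

test_that("promoter windows follow the 500+50 start-codon convention", {
  genome <- Biostrings::DNAStringSet(c(chr = rand_dna(4000, seed = 4)))
  genes <- data.frame(gene_id = c("plus", "edge", "minus"), contig = "chr",
                      start = c(1000, 10, 2000), end = c(1500, 300, 2600),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  ann <- parse_annotation(genome, genes)
  prom <- extract_promoters(ann)

  p <- prom[prom$gene_id == "plus", ]
  expect_equal(c(p$start, p$end), c(500, 1049))
  expect_equal(nchar(p$seq), 550)
  expect_equal(p$upstream_len, 500)
  expect_equal(p$downstream_len, 50)

  e <- prom[prom$gene_id == "edge", ]   # upstream truncated to 9 bases
  expect_equal(nchar(e$seq), 59)
  expect_equal(e$upstream_len, 9)

  m <- prom[prom$gene_id == "minus", ]
  raw <- substr(as.character(genome[[1]]), m$start, m$end)
  expect_equal(m$seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(raw))))
  expect_true(all(nchar(prom$seq) <= 550))
})

test_that("promoter extraction is mirror-symmetric under genome reversal", {
  cfg <- sim_config(n_genes = 30, n_operons_regulon = 3, seed = 10)
  sim <- generate_genome(cfg)
  L <- Biostrings::width(sim$genome)[1]
  mirrored_genome <- Biostrings::reverseComplement(sim$genome)
  names(mirrored_genome) <- names(sim$genome)
  mg <- sim$genes
  mg$start <- L - sim$genes$end + 1L
  mg$end <- L - sim$genes$start + 1L
  mg$strand <- ifelse(sim$genes$strand == "+", "-", "+")
  ann <- parse_annotation(sim$genome, sim$genes)
  ann_m <- parse_annotation(mirrored_genome, mg)
  p <- extract_promoters(ann); pm <- extract_promoters(ann_m)
  expect_equal(setNames(pm$seq, pm$gene_id)[p$gene_id],
               setNames(p$seq, p$gene_id))
})

test_that("sites propagate through operons exactly as brute force predicts", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = c("op1", "op1", "op1", "op2", "op3"),
    gene_id = c("a", "b", "c", "d", "e"),
    contig = "chr", strand = c("+", "+", "+", "-", "+"),
    position = c(1, 2, 3, 1, 1), stringsAsFactors = FALSE))

  sites <- data.frame(site_id = "s1", gene_id = "a",
                      stringsAsFactors = FALSE)
  got <- assign_sites_to_operons(sites, operons)
  expect_setequal(got$gene_sites$gene_id, c("a", "b", "c"))
  expect_false(any(got$gene_sites$internal))

  # internal gene: reported, flagged, not propagated
  internal <- data.frame(site_id = "s2", gene_id = "b",
                         stringsAsFactors = FALSE)
  got2 <- assign_sites_to_operons(internal, operons)
  expect_equal(got2$gene_sites$gene_id, "b")
  expect_true(all(got2$gene_sites$internal))

  empty <- assign_sites_to_operons(sites[0, ], operons)
  expect_equal(nrow(empty$gene_sites), 0)

  expect_error(assign_sites_to_operons(
    data.frame(site_id = "x", gene_id = "zz"), operons), "unknown gene")

  # randomized fixtures vs an independent brute-force re-derivation
  withr::with_seed(19, {
    for (rep in 1:5) {
      genes <- letters[1:10]
      opid <- paste0("op", sort(sample(1:4, 10, replace = TRUE)))
      ops <- do.call(rbind, lapply(split(genes, opid), function(g)
        data.frame(gene_id = g, position = seq_along(g))))
      ops$operon_id <- sub("\\..*", "", rownames(ops))
      ops$contig <- "chr"; ops$strand <- "+"
      ops <- regulonScout:::as_operon_set(ops)
      st <- data.frame(site_id = paste0("s", 1:3),
                       gene_id = sample(genes, 3))
      got <- assign_sites_to_operons(st, ops)
      # brute force: for each site, find operon; if its gene is listed
      # first, every member is regulated
      expected <- do.call(rbind, lapply(1:3, function(i) {
        op <- ops$operon_id[ops$gene_id == st$gene_id[i]]
        first <- ops$gene_id[ops$operon_id == op][1]
        if (first == st$gene_id[i])
          data.frame(gene_id = ops$gene_id[ops$operon_id == op],
                     site_id = st$site_id[i])
        else data.frame(gene_id = st$gene_id[i], site_id = st$site_id[i])
      }))
      got_keys <- sort(paste(got$gene_sites$gene_id, got$gene_sites$site_id))
      exp_keys <- sort(paste(expected$gene_id, expected$site_id))
      expect_identical(got_keys, exp_keys)
    }
  })
})

test_that("promoter FASTA and operon TSV writers round-trip", {
  ann <- tiny_annotation()
  prom <- extract_promoters(ann)
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoters_fasta(prom, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), sum(!prom$empty))
  expect_match(names(back)[1], "^gA\\|chr\\|\\d+-\\d+\\|\\+$")
  expect_equal(as.character(back[[1]]), prom$seq[1])

  ops <- call_operons(ann)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_operons_tsv(ops, tsv)
  back2 <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back2$gene_id, ops$gene_id)
})
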