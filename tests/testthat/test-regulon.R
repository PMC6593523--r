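mini_de <- function(genes, fc, q = rep(1e-4, length(genes))) {
  structure(data.frame(gene_id = genes, fold_change = fc,
                       q_value = q, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

test_that("operon mean fold change is the arithmetic mean of member genes", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = "op1", gene_id = c("a", "b", "c"), contig = "chr",
    strand = "+", position = 1:3, stringsAsFactors = FALSE))
  sites <- data.frame(site_id = "s1", gene_id = "a",
                      start = 10L, end = 23L, strand = "+", score = 15,
                      stringsAsFactors = FALSE)
  de <- mini_de(c("a", "b", "c"), c(2, 3, 4))
  rep_ <- build_regulon_report(sites, operons, de)
  expect_equal(rep_$operons$mean_fold_change, 3.0)
  expect_equal(rep_$n_genes, 3)
})

test_that("an empty consensus set yields an empty but writable report", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = "op1", gene_id = "a", contig = "chr", strand = "+",
    position = 1L, stringsAsFactors = FALSE))
  de <- mini_de("a", 1)
  rep_ <- build_regulon_report(NULL, operons, de)
  expect_equal(rep_$n_operons, 0)
  expect_equal(rep_$n_genes, 0)
  dir <- withr::local_tempdir()
  paths <- write_regulon_report(rep_, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$n_operons, 0)
})

test_that("genes with sites but missing from the DE table are flagged", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = "op1", gene_id = c("a", "b"), contig = "chr", strand = "+",
    position = 1:2, stringsAsFactors = FALSE))
  sites <- data.frame(site_id = "s1", gene_id = "a", start = 1L, end = 14L,
                      strand = "+", score = 10, stringsAsFactors = FALSE)
  de <- mini_de("a", 5)   # b absent
  expect_warning(build_regulon_report(sites, operons, de), "absent")
})

test_that("a planted regulon is reported operon-for-operon with dual support", {
  # sharp planted motif: sampled sites clear UGENE's 85% threshold nearly
  # always, so consensus support should be 'both' for >= 90% of sites
  # (pooled over the three runs; a single weakly-sampled site per run is
  # within expectation and is what the one-tool rescue rule is for)
  support <- character(0)
  for (seed in c(21, 22, 23)) {
    pwm <- default_planted_pwm(consensus_prob = 0.97)
    cfg <- sim_config(n_genes = 60, n_operons_regulon = 5,
                      planted_pwm = pwm, regulon_fold_change = 5,
                      seed = seed)
    sim <- generate_genome(cfg)
    ann <- parse_annotation(sim$genome, sim$genes)
    prom <- extract_promoters(ann)
    bg <- background_frequencies(prom$seq)
    ha <- scan_scheme_a(pwm, prom, background = bg)
    hb <- scan_scheme_b(pwm, prom, background = bg)
    ops <- call_operons(ann, gap_max = cfg$operon_gap_max)
    up_ops <- operons_with_genes(ops, sim$truth$regulon_gene_ids)
    cs <- consensus_sites(ha, hb, up_ops, ops)
    de <- mini_de(sim$genes$gene_id,
                  ifelse(sim$genes$gene_id %in% sim$truth$regulon_gene_ids,
                         5, 1))
    rep_ <- build_regulon_report(cs, ops, de)
    truth_ops <- unique(
      sim$operons$operon_id[sim$operons$gene_id %in%
                              sim$truth$regulon_gene_ids])
    # operon ids differ between generator and caller; compare gene sets
    got_genes <- sort(unique(rep_$genes$gene_id))
    expect_identical(got_genes, sort(sim$truth$regulon_gene_ids))
    expect_equal(rep_$n_operons, length(truth_ops))
    support <- c(support, cs$support)
  }
  expect_gte(mean(support == "both"), 0.9)
})

test_that("consensus sites project onto the planted genome coordinates", {
  pwm <- default_planted_pwm(consensus_prob = 0.97)
  cfg <- sim_config(n_genes = 40, n_operons_regulon = 4, planted_pwm = pwm,
                    seed = 31)
  sim <- generate_genome(cfg)
  ann <- parse_annotation(sim$genome, sim$genes)
  prom <- extract_promoters(ann)
  ha <- scan_scheme_a(pwm, prom)
  beds <- write_sites_bed(ha, prom)
  truth <- sim$truth$planted_sites
  found <- paste(beds$genome$chrom, beds$genome$start + 1L, beds$genome$end)
  planted <- paste(truth$contig, truth$start, truth$end)
  expect_true(all(planted %in% found))
  # promoter-relative BED is 0-based half-open with score = 100 x log-odds
  expect_equal(beds$promoter$end - beds$promoter$start,
               ha$end - ha$start + 1L)
  expect_equal(beds$promoter$score, as.integer(round(ha$score * 100)))
})

test_that("scanning and reporting are invariant under genome mirroring", {
  pwm <- default_planted_pwm(consensus_prob = 0.95)
  cfg <- sim_config(n_genes = 40, n_operons_regulon = 4, planted_pwm = pwm,
                    seed = 47)
  sim <- generate_genome(cfg)
  L <- Biostrings::width(sim$genome)[1]
  mirror_genome <- Biostrings::reverseComplement(sim$genome)
  names(mirror_genome) <- names(sim$genome)
  mg <- sim$genes
  mg$start <- L - sim$genes$end + 1L
  mg$end <- L - sim$genes$start + 1L
  mg$strand <- ifelse(sim$genes$strand == "+", "-", "+")

  run <- function(genome, genes) {
    ann <- parse_annotation(genome, genes)
    prom <- extract_promoters(ann)
    bg <- background_frequencies(prom$seq)
    ha <- scan_scheme_a(pwm, prom, background = bg)
    hb <- scan_scheme_b(pwm, prom, background = bg)
    ops <- call_operons(ann, gap_max = cfg$operon_gap_max)
    up <- operons_with_genes(ops, sim$truth$regulon_gene_ids)
    cs <- consensus_sites(ha, hb, up, ops)
    de <- mini_de(genes$gene_id,
                  ifelse(genes$gene_id %in% sim$truth$regulon_gene_ids,
                         5, 1))
    list(cs = cs, rep = build_regulon_report(cs, ops, de), prom = prom)
  }
  orig <- run(sim$genome, sim$genes)
  mirr <- run(mirror_genome, mg)

  # identical promoter-relative sites and identical regulated gene sets
  key <- function(cs) sort(paste(cs$gene_id, cs$start, cs$end, cs$strand,
                                 cs$support))
  expect_identical(key(orig$cs), key(mirr$cs))
  expect_identical(sort(unique(orig$rep$genes$gene_id)),
                   sort(unique(mirr$rep$genes$gene_id)))
  expect_equal(orig$rep$operons$mean_fold_change,
               mirr$rep$operons$mean_fold_change)
  # genome projections mirror each other: start' = L - end + 1
  bo <- write_sites_bed(orig$cs, orig$prom)$genome
  bm <- write_sites_bed(mirr$cs, mirr$prom)$genome
  expect_setequal(paste(bo$start, bo$end),
                  paste(L - bm$end, L - (bm$start + 1L) + 1L))
})

test_that("co-occurrence with a second TF's sites is tabulated per operon", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = c("op1", "op2"), gene_id = c("a", "b"), contig = "chr",
    strand = "+", position = 1L, stringsAsFactors = FALSE))
  sA <- data.frame(site_id = "s1", gene_id = "a", start = 1L, end = 14L,
                   strand = "+", score = 10, stringsAsFactors = FALSE)
  sK <- data.frame(site_id = "k1", gene_id = "a", start = 30L, end = 43L,
                   strand = "+", score = 9, stringsAsFactors = FALSE)
  de <- mini_de(c("a", "b"), c(5, 5))
  rep_ <- build_regulon_report(sA, operons, de,
                               other_tf_sites = list(KstR = sK),
                               tf_gene = "a")
  expect_true(rep_$co_occurrence["op1", "KstR"])
  expect_true(rep_$autoregulation)
})
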