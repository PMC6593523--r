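sharp_pwm <- function(w = 12, seed = 2) {
  cons <- rand_dna(w, seed = seed)
  cd <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  prob <- matrix(0.03 / 3, 4, w)
  prob[cbind(cd, seq_len(w))] <- 0.97
  new_pwm(prob, name = "sharp")
}

test_that("scheme A finds a planted consensus and nothing much else", {
  # with ~650k scored positions, a width-12 consensus (best possible
  # p = 4^-12) cannot clear the scan-wide BH cut at q <= 0.01; width 14
  # can, which is why 14-bp operators are detectable genome-wide
  p <- sharp_pwm(14)
  cons <- consensus_string(p)
  proms <- withr::with_seed(8, setNames(
    vapply(1:300, function(i) rand_dna(550), character(1)),
    sprintf("g%03d", 1:300)))
  substr(proms[37], 201, 214) <- cons
  hits <- scan_scheme_a(p, proms, background = rep(0.25, 4))
  expect_true(any(hits$gene_id == "g037" & hits$start == 201 &
                    hits$strand == "+"))
  planted_hit <- hits[hits$gene_id == "g037" & hits$start == 201, ]
  expect_identical(planted_hit$word[1], cons)
  expect_lte(nrow(hits), 3)   # FDR 0.01 admits at most a stray hit or two
})

test_that("a motif wider than the promoters yields zero hits without error", {
  p <- sharp_pwm(30)
  tiny <- c(a = "ACGTACGTAC", b = "TTTTCCCCGG")
  expect_equal(nrow(scan_scheme_a(p, tiny, background = rep(0.25, 4))), 0)
  expect_equal(nrow(scan_scheme_b(p, tiny, background = rep(0.25, 4))), 0)
})

test_that("scheme B follows the normalized fraction-of-maximum convention", {
  p <- sharp_pwm(10)
  cons <- consensus_string(p)
  proms <- c(x = paste0("AAAA", cons, "GGGG"))
  bg <- rep(0.25, 4)
  hits <- scan_scheme_b(p, proms, background = bg, f_min = 0.85)
  at_site <- hits[hits$start == 5 & hits$strand == "+", ]
  expect_equal(nrow(at_site), 1)
  expect_equal(at_site$score_fraction, 1, tolerance = 1e-9)

  # f_min = 0: every position on both strands is a hit (no overlap pruning)
  all_hits <- scan_scheme_b(p, proms, background = bg, f_min = 0)
  expect_equal(nrow(all_hits), unname(2 * (nchar(proms) - 10 + 1)))

  flat <- new_pwm(matrix(0.25, 4, 6))
  expect_error(scan_scheme_b(flat, proms, background = bg), "degenerate")
})

test_that("both schemes agree with a brute-force rescan", {
  p <- random_pwm(7, seed = 31, alpha = 0.3)
  proms <- withr::with_seed(32, setNames(
    vapply(1:15, function(i) rand_dna(60), character(1)),
    paste0("s", 1:15)))
  bg <- c(0.3, 0.2, 0.2, 0.3)
  got_b <- scan_scheme_b(p, proms, background = bg, f_min = 0.8)
  mx <- max_score(p, bg); mn <- min_score(p, bg)
  expected <- list()
  for (g in names(proms)) {
    for (s in 1:(60 - 7 + 1)) {
      word <- substr(proms[g], s, s + 6)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(word)))
      for (orient in c("+", "-")) {
        wrd <- if (orient == "+") word else rc
        sc <- score_word_brute(p$prob, wrd, bg)
        if ((sc - mn) / (mx - mn) >= 0.8)
          expected[[length(expected) + 1]] <-
            data.frame(gene_id = g, start = s, strand = orient, score = sc)
      }
    }
  }
  expected <- do.call(rbind, expected)
  key <- function(df) sort(paste(df$gene_id, df$start, df$strand))
  expect_identical(key(got_b), key(expected))

  # scheme A on the same fixture: every reported hit must satisfy the
  # q-threshold and sit where the brute-force scorer puts its score
  got_a <- scan_scheme_a(p, proms, background = bg, q_max = 0.5)
  if (nrow(got_a)) {
    for (i in seq_len(nrow(got_a))) {
      sc <- score_word_brute(p$prob, got_a$word[i], bg)
      expect_equal(sc, got_a$score[i], tolerance = 1e-9)
    }
    expect_true(all(got_a$q_value <= 0.5))
  }
})

test_that("scheme A false hits are rare on null promoters", {
  p <- default_planted_pwm()
  ok <- vapply(1:20, function(s) {
    proms <- withr::with_seed(1000 + s, setNames(
      vapply(1:300, function(i) rand_dna(550), character(1)),
      sprintf("g%03d", 1:300)))
    nrow(scan_scheme_a(p, proms)) <= 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("consensus sites implement the two-scheme merge rule", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = c("op1", "op2"), gene_id = c("gU", "gN"), contig = "chr",
    strand = "+", position = 1L, stringsAsFactors = FALSE))
  a <- data.frame(gene_id = c("gU", "gN"), start = c(100L, 50L),
                  end = c(113L, 63L), strand = "+", word = "x",
                  score = c(15, 14), p_value = 1e-8, q_value = 1e-4,
                  scheme = "A", stringsAsFactors = FALSE)
  b <- data.frame(gene_id = "gU", start = 101L, end = 114L, strand = "+",
                  word = "x", score = 15, score_fraction = 0.9,
                  scheme = "B", stringsAsFactors = FALSE)
  cs <- consensus_sites(a, b, upregulated_operons = character(0),
                        operons = operons)
  # overlap 13/14 pairs the gU hits; the gN singleton dies (not upstream of
  # an up-regulated operon)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$support, "both")
  expect_equal(cs$gene_id, "gU")

  cs2 <- consensus_sites(a, b, upregulated_operons = "op2",
                         operons = operons)
  expect_setequal(cs2$support, c("both", "A_only_upstream_upregulated"))
  # consensus is always a subset of A-union-B positions
  expect_true(all(paste(cs2$gene_id, cs2$start) %in%
                    paste(c(a$gene_id, b$gene_id), c(a$start, b$start))))
})

test_that("consensus merging matches a brute-force set-algebra oracle", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = paste0("op", 1:6), gene_id = paste0("g", 1:6),
    contig = "chr", strand = "+", position = 1L, stringsAsFactors = FALSE))
  withr::with_seed(44, for (rep in 1:10) {
    # at most one hit per gene per scheme: pairing then has no contention
    # and a set-algebra oracle is exact
    mk <- function(n, scheme) {
      df <- data.frame(gene_id = sample(paste0("g", 1:6), n),
                       start = sample(1:80, n), strand = sample(c("+", "-"), n,
                                                                replace = TRUE),
                       score = round(runif(n, 5, 20), 3),
                       stringsAsFactors = FALSE)
      df$end <- df$start + 9L
      df$word <- "x"
      if (scheme == "A") { df$p_value <- 1e-6; df$q_value <- 1e-3
      } else df$score_fraction <- 0.9
      df$scheme <- scheme
      df
    }
    a <- mk(6, "A"); b <- mk(6, "B")
    up <- sample(paste0("op", 1:6), 2)
    cs <- consensus_sites(a, b, up, operons)
    # oracle: a pair exists iff same gene, same strand, overlap >= 5 of 10
    paired_a <- logical(nrow(a))
    for (i in seq_len(nrow(a))) {
      ov <- b$gene_id == a$gene_id[i] & b$strand == a$strand[i] &
        pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) + 1L >= 5L
      paired_a[i] <- any(ov)
    }
    got_both <- cs[cs$support == "both", ]
    expect_setequal(paste(got_both$gene_id, got_both$start),
                    paste(a$gene_id[paired_a], a$start[paired_a]))
    # every singleton kept must be upstream of an up-regulated operon
    single <- cs[cs$support != "both", ]
    if (nrow(single)) {
      ops <- operons$operon_id[match(single$gene_id, operons$gene_id)]
      expect_true(all(ops %in% up))
    }
  })
})

test_that("autoregulation is flagged only for sites before the TF's operon", {
  operons <- regulonScout:::as_operon_set(data.frame(
    operon_id = c("op1", "op1", "op2"), gene_id = c("tfX", "g2", "g3"),
    contig = "chr", strand = "+", position = c(1L, 2L, 1L),
    stringsAsFactors = FALSE))
  sites_tf <- data.frame(gene_id = "tfX", start = 1L, end = 14L,
                         stringsAsFactors = FALSE)
  sites_other <- data.frame(gene_id = "g3", start = 1L, end = 14L,
                            stringsAsFactors = FALSE)
  expect_true(detect_autoregulation("tfX", sites_tf, operons))
  expect_true(detect_autoregulation("g2", sites_tf, operons))  # same operon
  expect_false(detect_autoregulation("tfX", sites_other, operons))
  expect_false(detect_autoregulation("tfX", sites_tf[0, ], operons))
  expect_error(detect_autoregulation("nope", sites_tf, operons),
               "not present")
})
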