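# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking.

# brute-force Benjamini-Hochberg step-up: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / rank(j), capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# per-position log-odds summation, independent of the pwm class internals
score_word_brute <- function(prob, word, bg) {
  letters <- strsplit(word, "")[[1]]
  idx <- match(letters, c("A", "C", "G", "T"))
  s <- 0
  for (i in seq_along(idx)) s <- s + log2(prob[idx[i], i] / bg[idx[i]])
  unname(s)
}

# exhaustive PWM score tail probability over all 4^w words
score_tail_brute <- function(prob, threshold, bg) {
  w <- ncol(prob)
  words <- expand.grid(rep(list(1:4), w))
  total <- 0
  for (r in seq_len(nrow(words))) {
    idx <- as.integer(words[r, ])
    s <- sum(log2(prob[cbind(idx, seq_len(w))] / bg[idx]))
    if (s >= threshold) total <- total + prod(bg[idx])
  }
  total
}

random_pwm <- function(w, seed = NULL, alpha = 1) {
  gen <- function() {
    m <- matrix(rgamma(4 * w, alpha), 4, w)
    new_pwm(sweep(m, 2, colSums(m), "/"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# a small annotated genome built by hand (not via the generator)
tiny_annotation <- function() {
  g <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb
  genome <- Biostrings::DNAStringSet(c(chr = g))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    contig = "chr",
    start = c(1001, 1501, 3001, 5001),
    end = c(1400, 1900, 3400, 5400),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  parse_annotation(genome, genes)
}
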