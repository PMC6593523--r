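DNA_BASES <- c("A", "C", "G", "T")

#' @useDynLib regulonScout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dnbinom lowess p.adjust quantile rbinom rlnorm rnbinom
#'   rnorm runif sd setNames approx pnorm var
#' @importFrom utils read.delim write.table head
NULL

# integer coding 1..4 = A,C,G,T; 0 = anything else (masked / ambiguous)
encode_dna <- function(x) {
  if (length(x) == 1L && !is.null(names(x))) names(x) <- NULL
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lapply(x, function(s) lut[utf8ToInt(s)])
}

decode_dna <- function(codes) {
  paste(c(DNA_BASES, "N")[ifelse(codes %in% 1:4, codes, 5L)], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a bounded child seed from a user seed and a stream label
# (double arithmetic: intermediates exceed 32-bit range)
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %%
               2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
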