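# Independent brute-force reference for the featurizer: materializes every
# prefix, recomputes its CGR endpoint from scratch, and groups endpoints by
# the k-letter suffix. Deliberately naive -- no streaming, no shared state
# with the package implementation.

oracle_cgr_endpoint <- function(prefix, corners) {
  p <- c(0.5, 0.5)
  for (ch in strsplit(prefix, "")[[1]]) {
    if (!ch %in% c("A", "C", "G", "T")) next
    p <- 0.5 * (p + corners[ch, ])
  }
  p
}

oracle_positions <- function(seq, k, corners = cgr_corners()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  words <- all_kmers(k)
  counts <- setNames(integer(length(words)), words)
  sx <- sy <- setNames(numeric(length(words)), words)
  for (i in k:L) {
    w <- paste(chars[(i - k + 1):i], collapse = "")
    if (!w %in% words) next                       # window touches ambiguity
    pt <- oracle_cgr_endpoint(substr(seq, 1, i), corners)
    counts[w] <- counts[w] + 1L
    sx[w] <- sx[w] + pt[1]
    sy[w] <- sy[w] + pt[2]
  }
  list(counts = counts,
       mean_x = ifelse(counts > 0, sx / pmax(counts, 1), 0),
       mean_y = ifelse(counts > 0, sy / pmax(counts, 1), 0))
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# The fully printed worked example: S = AGTCGTTACA, k = 2.
worked_seq <- "AGTCGTTACA"
worked_counts <- c(AA = 0L, AC = 1L, AG = 1L, AT = 0L,
                   CA = 1L, CC = 0L, CG = 1L, CT = 0L,
                   GA = 0L, GC = 0L, GG = 0L, GT = 2L,
                   TA = 1L, TC = 1L, TG = 0L, TT = 1L)
worked_mean_x <- c(AA = 0, AC = 0.2314453125, AG = 0.625, AT = 0,
                   CA = 0.11572265625, CC = 0, CG = 0.703125, CT = 0,
                   GA = 0, GC = 0, GG = 0, GT = 0.83203125,
                   TA = 0.462890625, TC = 0.40625, TG = 0, TT = 0.92578125)
worked_mean_y <- c(AA = 0, AC = 0.5517578125, AG = 0.625, AT = 0,
                   CA = 0.27587890625, CC = 0, CG = 0.828125, CT = 0,
                   GA = 0, GC = 0, GG = 0, GT = 0.36328125,
                   TA = 0.103515625, TC = 0.65625, TG = 0, TT = 0.20703125)
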