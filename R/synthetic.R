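# Seeded generator of class-conditioned phage-like sequences. Each host class
# is an order-m Markov chain over {A,C,G,T}; a separation dial interpolates
# between identical chains (no signal) and sharply class-specific chains,
# emulating the host-specific k-mer composition that alignment-free host
# prediction exploits. Only the compositional signal is simulated -- no genes,
# codon structure or prophages.

#' Markov specifications for synthetic host classes
#'
#' Builds one order-`m` transition table per class. A shared random base
#' table models composition common to all phages; each class additionally
#' gets a sharply preferential table (weight `pref_weight` on one preferred
#' base per context). The class table is the convex combination
#' `(1 - separation) * base + separation * class`, so `separation = 0`
#' yields identical classes and `separation = 1` near-disjoint preferred
#' k-mer sets.
#'
#' @param n_classes number of host classes (>= 2).
#' @param separation class separation in \[0, 1\].
#' @param seed integer seed; specs are reproducible and the caller's RNG
#'   stream is untouched.
#' @param order Markov order m (contexts are the 4^m m-mers).
#' @param pref_weight probability mass on the preferred base in the
#'   class-specific table.
#' @param length_mean,length_sd sequence length distribution carried on each
#'   spec (used by [sample_sequences()] when no explicit length is given).
#' @return A list of `host_class_spec` objects, each with `name`, `order`,
#'   `transition` (a 4^m x 4 stochastic matrix with context rownames),
#'   `length_mean`, `length_sd`, and the stationary `gc` content implied by
#'   the chain.
#' @export
make_class_specs <- function(n_classes, separation = 1, seed = 1L,
                             order = 2L, pref_weight = 0.85,
                             length_mean = 2000, length_sd = 0) {
  if (n_classes < 2) stop("`n_classes` must be at least 2")
  if (separation < 0 || separation > 1)
    stop("`separation` must lie in [0, 1]")
  order <- .check_k(order)
  nctx <- 4L^order
  .with_seed(seed, {
    base <- matrix(stats::rgamma(nctx * 4L, shape = 1), nrow = nctx)
    base <- base / rowSums(base)
    lapply(seq_len(n_classes), function(ci) {
      pref <- sample.int(4L, nctx, replace = TRUE)
      own <- matrix((1 - pref_weight) / 3, nrow = nctx, ncol = 4L)
      own[cbind(seq_len(nctx), pref)] <- pref_weight
      tr <- (1 - separation) * base + separation * own
      dimnames(tr) <- list(all_kmers(order), NUC)
      pairs <- stationary_kmer_probs(tr, order)
      gc <- sum(stationary_base_probs(tr, order)[c("C", "G")])
      structure(list(name = paste0("class_", ci), order = order,
                     transition = tr, length_mean = length_mean,
                     length_sd = length_sd, gc = gc,
                     stationary_pairs = pairs),
                class = "host_class_spec")
    })
  })
}

#' @export
print.host_class_spec <- function(x, ...) {
  cat(sprintf("Host class spec '%s': order-%d Markov chain, GC %.3f, length %g +/- %g\n",
              x$name, x$order, x$gc, x$length_mean, x$length_sd))
  invisible(x)
}

# Context-level transition matrix: context (a1..am) -> (a2..am, c) with
# probability transition[ctx, c].
.context_transition <- function(transition, order) {
  nctx <- nrow(transition)
  Tm <- matrix(0, nctx, nctx)
  for (ctx in seq_len(nctx)) {
    nxt <- ((ctx - 1L) %% 4L^(order - 1L)) * 4L + 1:4
    Tm[ctx, nxt] <- transition[ctx, ]
  }
  Tm
}

#' Stationary k-mer probabilities of a class chain
#'
#' The stationary distribution over length-m contexts of the chain (the
#' leading left eigenvector of the context transition matrix), i.e. the
#' long-run m-mer frequencies a sampled sequence converges to.
#'
#' @param transition a 4^m x 4 stochastic matrix (rows = contexts).
#' @param order the Markov order m.
#' @return Named numeric vector over [all_kmers()] of length m, summing
#'   to 1.
#' @export
stationary_kmer_probs <- function(transition, order) {
  Tm <- .context_transition(transition, order)
  e <- eigen(t(Tm))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), all_kmers(order))
}

#' @rdname stationary_kmer_probs
#' @return `stationary_base_probs()`: stationary single-base probabilities.
#' @export
stationary_base_probs <- function(transition, order) {
  p <- stationary_kmer_probs(transition, order)
  last <- substr(names(p), order, order)
  vapply(NUC, function(b) sum(p[last == b]), numeric(1))
}

# Sample one sequence of length L from an order-m chain.
.sample_chain <- function(transition, order, L) {
  cum <- transition %*% upper.tri(diag(4), diag = TRUE)  # row-wise cumsum
  # uniform random initial context
  ctx_codes <- sample.int(4L, order, replace = TRUE)
  out <- integer(L)
  n0 <- min(order, L)
  out[seq_len(n0)] <- ctx_codes[seq_len(n0)]
  if (L > order) {
    ctx <- sum((ctx_codes - 1L) * 4L^((order:1) - 1L)) + 1L
    u <- stats::runif(L - order)
    for (i in (order + 1L):L) {
      nb <- findInterval(u[i - order], cum[ctx, ]) + 1L
      out[i] <- nb
      ctx <- ((ctx - 1L) %% 4L^(order - 1L)) * 4L + nb
    }
  }
  paste(NUC[out], collapse = "")
}

#' Sample a labeled synthetic dataset
#'
#' Draws `n_per_class` sequences from each class's Markov chain. With
#' `length = NULL`, lengths are drawn per class from a normal with the
#' spec's `length_mean` / `length_sd` (truncated below at `min_length`).
#'
#' @param specs list of specs from [make_class_specs()].
#' @param n_per_class sequences per class.
#' @param length common sequence length, or `NULL` to use each spec's
#'   length distribution.
#' @param seed integer seed; generation is reproducible end to end.
#' @param min_length lower truncation for drawn lengths.
#' @return An object of class `synthetic_dataset`: a list with `sequences`
#'   (named character vector), `labels` (named class vector, aligned),
#'   `specs` and `seed`.
#' @export
sample_sequences <- function(specs, n_per_class = 50L, length = 2000L,
                             seed = 1L, min_length = 50L) {
  stopifnot(all(vapply(specs, inherits, logical(1), "host_class_spec")))
  if (n_per_class < 1) stop("`n_per_class` must be at least 1")
  .with_seed(seed, {
    seqs <- character(0); labs <- character(0)
    for (sp in specs) {
      for (j in seq_len(n_per_class)) {
        L <- if (is.null(length)) {
          max(min_length,
              round(stats::rnorm(1, sp$length_mean, sp$length_sd)))
        } else as.integer(length)
        id <- sprintf("%s_%03d", sp$name, j)
        seqs[id] <- .sample_chain(sp$transition, sp$order, L)
        labs[id] <- sp$name
      }
    }
    structure(list(sequences = seqs, labels = labs, specs = specs,
                   seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d sequences, %d classes, lengths %d-%d, seed %d\n",
              length(x$sequences), length(unique(x$labels)),
              min(nchar(x$sequences)), max(nchar(x$sequences)), x$seed))
  invisible(x)
}

#' Write a synthetic dataset as FASTA plus a label table
#'
#' Emits the exact input contract of the main pipeline: a multi-record FASTA
#' and a two-column tab-separated file mapping sequence ID to host taxon.
#'
#' @param dataset a [sample_sequences()] result.
#' @param fasta_path,labels_path output files.
#' @return The two paths, invisibly.
#' @export
write_dataset <- function(dataset, fasta_path, labels_path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  xs <- Biostrings::DNAStringSet(dataset$sequences)
  Biostrings::writeXStringSet(xs, fasta_path)
  utils::write.table(
    data.frame(id = names(dataset$labels), taxon = unname(dataset$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(c(fasta = fasta_path, labels = labels_path))
}
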