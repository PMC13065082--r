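# Featurization: k-mer counts, CGR trajectories, per-k-mer mean CGR positions,
# and the 3 x 2^k x 2^k feature tensor that the classifier and the distance
# module consume.

NUC <- c("A", "C", "G", "T")

# Integer codes 1..4 for A,C,G,T; NA for any other (IUPAC ambiguity) symbol.
# Ambiguous residues emit no CGR point and invalidate any k-window that
# contains them.
.encode_residues <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  s <- toupper(residues)
  if (!nzchar(s)) stop("sequence is empty")
  match(strsplit(s, "")[[1]], NUC)
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a single integer >= 1")
  as.integer(k)
}

#' All k-mers over \{A, C, G, T\}
#'
#' Lexicographic order (A < C < G < T), first letter most significant. This is
#' the canonical word order used for count tables and mean-position tables.
#'
#' @param k word length, integer >= 1.
#' @return Character vector of the 4^k words.
#' @export
all_kmers <- function(k) {
  k <- .check_k(k)
  w <- NUC
  if (k > 1) for (i in 2:k) w <- as.vector(t(outer(w, NUC, paste0)))
  w
}

# 1-based word index for each window end; NA where the window touches an
# ambiguous residue. Returns a vector aligned with window end positions
# k..L (indices 1..L-k+1).
.window_word_index <- function(codes, k) {
  L <- length(codes)
  v <- codes - 1L
  n <- L - k + 1L
  w <- v[seq_len(n)]
  if (k > 1) for (j in 2:k) w <- w * 4L + v[j:(n + j - 1L)]
  w + 1L
}

#' Count k-mer occurrences in a DNA sequence
#'
#' Counts every length-k window over \{A,C,G,T\}. Windows containing an
#' ambiguity code (N, R, Y, ...) contribute to no word, so on ambiguity-free
#' input the counts sum to L - k + 1.
#'
#' @param seq a single DNA string (case-insensitive).
#' @param k word length, integer >= 1; the sequence must be at least k long.
#' @return Named integer vector of length 4^k in [all_kmers()] order, with
#'   attribute `k`.
#' @examples
#' count_kmers("AGTCGTTACA", 2)[c("GT", "TA", "AA")]
#' @export
count_kmers <- function(seq, k) {
  k <- .check_k(k)
  codes <- .encode_residues(seq)
  if (length(codes) < k)
    stop(sprintf("sequence of length %d is shorter than k = %d",
                 length(codes), k))
  idx <- .window_word_index(codes, k)
  counts <- tabulate(idx, nbins = 4L^k)
  names(counts) <- all_kmers(k)
  attr(counts, "k") <- k
  counts
}

#' CGR trajectory of a DNA sequence
#'
#' Iterates the chaos-game map from the centre of the unit square: each
#' accepted nucleotide moves the point halfway toward its assigned corner,
#' `p_i = 0.5 * (p_{i-1} + corner(a_i))`. One point is emitted per A/C/G/T
#' residue, in order; ambiguity codes emit no point (the point stays put).
#' All points lie strictly inside the open unit square.
#'
#' @param seq a single non-empty DNA string.
#' @param corners a [cgr_corners()] assignment.
#' @return A matrix with columns `x`, `y`, one row per accepted residue, of
#'   class `cgr_trajectory`. Attribute `positions` maps each row to the
#'   1-based position of its residue in the original sequence.
#' @examples
#' cgr_trajectory("AG")     # (0.25, 0.25) then (0.625, 0.625)
#' @export
cgr_trajectory <- function(seq, corners = cgr_corners()) {
  stopifnot_corners(corners)
  codes <- .encode_residues(seq)
  keep <- which(!is.na(codes))
  cx <- corners[, "x"]; cy <- corners[, "y"]
  n <- length(keep)
  xs <- numeric(n); ys <- numeric(n)
  x <- 0.5; y <- 0.5
  ci <- codes[keep]
  for (i in seq_len(n)) {
    x <- 0.5 * (x + cx[ci[i]])
    y <- 0.5 * (y + cy[ci[i]])
    xs[i] <- x; ys[i] <- y
  }
  out <- cbind(x = xs, y = ys)
  attr(out, "positions") <- keep
  class(out) <- c("cgr_trajectory", class(out))
  out
}

#' Mean CGR position of each k-mer
#'
#' For every word w with count N_w > 0, averages the trajectory points at
#' which a window equal to w ends; words that never occur get (0, 0), the
#' convention under which absent cells of the positional channels are zero.
#' Every mean lies inside the word's 2^-k x 2^-k CGR cell (the suffix of the
#' trajectory determines the cell).
#'
#' @inheritParams count_kmers
#' @inheritParams cgr_trajectory
#' @return A list of class `kmer_positions` with elements `k`, `counts`,
#'   `mean_x`, `mean_y` (named vectors over [all_kmers()]), and `corners`.
#' @examples
#' p <- kmer_average_positions("AGTCGTTACA", 2)
#' p$mean_x["GT"]  # 0.83203125
#' @export
kmer_average_positions <- function(seq, k, corners = cgr_corners()) {
  k <- .check_k(k)
  stopifnot_corners(corners)
  codes <- .encode_residues(seq)
  L <- length(codes)
  if (L < k)
    stop(sprintf("sequence of length %d is shorter than k = %d", L, k))
  traj <- cgr_trajectory(seq, corners)
  # trajectory row for each original position (NA where residue ambiguous)
  row_of_pos <- rep(NA_integer_, L)
  row_of_pos[attr(traj, "positions")] <- seq_len(nrow(traj))
  idx <- .window_word_index(codes, k)          # NA for invalid windows
  ends <- seq.int(k, L)                        # window end positions
  ok <- !is.na(idx)
  widx <- idx[ok]
  trow <- row_of_pos[ends[ok]]
  nk <- 4L^k
  counts <- tabulate(widx, nbins = nk)
  sx <- numeric(nk); sy <- numeric(nk)
  if (length(widx)) {
    agg <- rowsum(traj[trow, , drop = FALSE], group = widx)
    at <- as.integer(rownames(agg))
    sx[at] <- agg[, "x"]; sy[at] <- agg[, "y"]
  }
  mean_x <- ifelse(counts > 0, sx / pmax(counts, 1L), 0)
  mean_y <- ifelse(counts > 0, sy / pmax(counts, 1L), 0)
  words <- all_kmers(k)
  names(counts) <- names(mean_x) <- names(mean_y) <- words
  structure(list(k = k, counts = counts, mean_x = mean_x, mean_y = mean_y,
                 corners = corners),
            class = "kmer_positions")
}

#' Grid cell of a k-mer in the 2^k x 2^k CGR partition
#'
#' Every trajectory point whose last k accepted residues equal `word` lies in
#' a unique 2^-k x 2^-k sub-square of the unit square; this returns that
#' cell's grid position. Indices are 0-based: row 0 is the top row (largest
#' y), column 0 the left column (smallest x).
#'
#' @param word one or more k-mer strings over A/C/G/T.
#' @param k word length; defaults to the length of the first word.
#' @inheritParams cgr_trajectory
#' @return For a single word, an integer vector `c(row, col)`; for several, a
#'   matrix with `row` and `col` columns.
#' @examples
#' kmer_cell_index("CC", 2)  # top-left: (0, 0)
#' @export
kmer_cell_index <- function(word, k = nchar(word[1]), corners = cgr_corners()) {
  k <- .check_k(k)
  stopifnot_corners(corners)
  word <- toupper(word)
  if (any(nchar(word) != k)) stop("each word must have exactly k characters")
  codes <- lapply(strsplit(word, ""), match, NUC)
  if (any(vapply(codes, anyNA, logical(1))))
    stop("words must contain only A, C, G or T")
  cx <- corners[, "x"]; cy <- corners[, "y"]
  one <- function(cd) {
    pw <- 2^(seq_len(k) - 1)                  # later letters dominate
    col <- sum(cx[cd] * pw)
    yix <- sum(cy[cd] * pw)
    c(row = 2^k - 1 - yix, col = col)
  }
  out <- t(vapply(codes, one, c(row = 0, col = 0)))
  storage.mode(out) <- "integer"
  if (length(word) == 1L) out[1, ] else `rownames<-`(out, word)
}

# (row, col) 0-based cell for every word of all_kmers(k), vectorized.
.cells_for_all_words <- function(k, corners) {
  nk <- 4L^k
  w0 <- 0:(nk - 1L)
  cx <- corners[, "x"]; cy <- corners[, "y"]
  col <- numeric(nk); yix <- numeric(nk)
  for (i in seq_len(k)) {                      # i-th letter of each word
    code <- (w0 %/% 4L^(k - i)) %% 4L + 1L
    col <- col + cx[code] * 2^(i - 1)
    yix <- yix + cy[code] * 2^(i - 1)
  }
  cbind(row = as.integer(2^k - 1 - yix), col = as.integer(col))
}

#' Build the 3-channel CGR feature tensor of a sequence
#'
#' Channel 1 holds the k-mer counts, channels 2 and 3 the mean x and mean y
#' CGR positions of each k-mer, each value placed at the k-mer's grid cell
#' (see [kmer_cell_index()]). With `normalize = TRUE` each channel is
#' independently min-max rescaled to \[0, 1\] (the classifier's input
#' convention).
#'
#' @inheritParams kmer_average_positions
#' @param normalize apply per-channel min-max normalization.
#' @param id optional sequence identifier stored on the tensor.
#' @return An array of dimension `c(2^k, 2^k, 3)` with channels named
#'   `freq`, `mean_x`, `mean_y`, of class `cgr_tensor`; attributes `k`,
#'   `corners`, `normalized`, `id`.
#' @examples
#' tz <- build_feature_tensor("AGTCGTTACA", 2, normalize = FALSE)
#' cell <- kmer_cell_index("GT", 2)
#' tz[cell["row"] + 1, cell["col"] + 1, ]  # count 2, means (0.832..., 0.363...)
#' @export
build_feature_tensor <- function(seq, k, corners = cgr_corners(),
                                 normalize = TRUE, id = NULL) {
  pos <- kmer_average_positions(seq, k, corners)
  k <- pos$k
  side <- 2L^k
  cells <- .cells_for_all_words(k, corners)
  lin <- cells[, "row"] + 1L + cells[, "col"] * side
  ch <- array(0, dim = c(side, side, 3L),
              dimnames = list(NULL, NULL, c("freq", "mean_x", "mean_y")))
  ch[lin] <- pos$counts
  ch[lin + side * side] <- pos$mean_x
  ch[lin + 2L * side * side] <- pos$mean_y
  out <- structure(ch, class = "cgr_tensor", k = k, corners = corners,
                   normalized = FALSE, id = id)
  if (normalize) out <- minmax_normalize(out) else out
}

#' Min-max normalize a feature tensor
#'
#' Rescales each channel independently to \[0, 1\]:
#' `(x - min) / (max - min)`. A constant channel (max equal to min) maps to
#' all zeros, which only arises for degenerate inputs.
#'
#' @param tensor an unnormalized `cgr_tensor`.
#' @return The tensor with `normalized = TRUE`.
#' @export
minmax_normalize <- function(tensor) {
  stopifnot(inherits(tensor, "cgr_tensor"))
  if (isTRUE(attr(tensor, "normalized")))
    stop("tensor is already normalized")
  for (c3 in 1:3) {
    v <- tensor[, , c3]
    rng <- range(v)
    tensor[, , c3] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
                      else 0
  }
  attr(tensor, "normalized") <- TRUE
  tensor
}

#' Featurize a set of sequences
#'
#' @param seqs a named character vector of DNA strings, or a
#'   `Biostrings::DNAStringSet`.
#' @inheritParams build_feature_tensor
#' @return A named list of `cgr_tensor` objects (one per sequence).
#' @export
featurize <- function(seqs, k = 7, corners = cgr_corners(), normalize = TRUE) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- stats::setNames(as.character(seqs), nm)
  }
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  out <- lapply(names(seqs), function(id)
    build_feature_tensor(seqs[[id]], k, corners, normalize, id = id))
  stats::setNames(out, names(seqs))
}

#' @export
print.cgr_tensor <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("CGR feature tensor%s: k = %d, 3 x %d x %d, %s\n",
              if (!is.null(attr(x, "id"))) paste0(" [", attr(x, "id"), "]") else "",
              k, 2^k, 2^k,
              if (attr(x, "normalized")) "normalized" else "raw counts/positions"))
  cat(sprintf("  nonzero cells: %d of %d\n",
              sum(x[, , 1] != 0), 4^k))
  invisible(x)
}
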