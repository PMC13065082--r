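# Cosine distances over flattened feature tensors, exported for external
# tree building (e.g. Neighbor-Joining in MEGA).

#' Flatten a feature tensor to a vector
#'
#' Fixed, documented ordering so vectors are comparable across runs: all
#' frequency cells, then all mean-x cells, then all mean-y cells, each
#' channel in row-major cell order (row 0 left-to-right, then row 1, ...).
#' The vector length is 3 * 4^k. Names are `<channel>:<row>,<col>` with
#' 0-based cell indices (see [kmer_cell_index()] for the word-to-cell map).
#'
#' @param tensor a `cgr_tensor`.
#' @return Named numeric vector of length `3 * 4^k`.
#' @export
flatten_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "cgr_tensor"))
  k <- attr(tensor, "k")
  side <- 2L^k
  cells <- paste0(rep(0:(side - 1L), each = side), ",",
                  rep(0:(side - 1L), times = side))
  out <- c(as.vector(t(tensor[, , 1])),
           as.vector(t(tensor[, , 2])),
           as.vector(t(tensor[, , 3])))
  names(out) <- paste0(rep(c("freq", "mean_x", "mean_y"),
                           each = side * side), ":", cells)
  out
}

#' Cosine similarity and distance between feature vectors
#'
#' `cosine_similarity(a, b)` is the dot product over the product of the
#' Euclidean norms; `cosine_distance` is one minus that. For the
#' non-negative vectors produced by [flatten_tensor()], similarity lies in
#' \[0, 1\] and distance in \[0, 1\]; for general vectors distance lies in
#' \[0, 2\].
#'
#' @param a,b equal-length numeric vectors with nonzero norm.
#' @return A single number.
#' @examples
#' cosine_distance(c(1, 1, 0), c(1, 0, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  sa <- sum(a * a); sb <- sum(b * b)
  if (sa == 0 || sb == 0)
    stop("cosine similarity is undefined for a zero vector")
  # single sqrt of the product, clamped: identical directions give exactly 1
  min(max(sum(a * b) / sqrt(sa * sb), -1), 1)
}

#' @rdname cosine_similarity
#' @export
cosine_distance <- function(a, b) 1 - cosine_similarity(a, b)

#' Pairwise cosine-distance matrix over feature tensors
#'
#' Flattens each tensor (see [flatten_tensor()]) and computes all pairwise
#' cosine distances. The result is symmetric with a zero diagonal and, for
#' tensor input, entries in \[0, 1\].
#'
#' @param tensors a named list of `cgr_tensor` objects sharing one k, or a
#'   numeric matrix of pre-flattened row vectors.
#' @param ids sequence identifiers; defaults to the tensor names.
#' @return An n x n numeric matrix with `ids` as dimnames.
#' @export
pairwise_distances <- function(tensors, ids = names(tensors)) {
  if (is.matrix(tensors)) {
    V <- tensors
    if (is.null(ids)) ids <- rownames(V)
  } else {
    if (length(tensors) < 2L) stop("need at least 2 sequences")
    ks <- vapply(tensors, function(t) attr(t, "k"), integer(1))
    if (length(unique(ks)) != 1L)
      stop("all tensors must share the same k")
    V <- do.call(rbind, lapply(tensors, flatten_tensor))
  }
  if (nrow(V) < 2L) stop("need at least 2 sequences")
  nrm <- sqrt(rowSums(V * V))
  if (any(nrm == 0)) stop("zero feature vector at: ",
                          paste(which(nrm == 0), collapse = ", "))
  Vn <- V / nrm
  D <- 1 - tcrossprod(Vn)
  D <- (D + t(D)) / 2        # enforce exact symmetry
  diag(D) <- 0
  D[D < 0] <- 0              # clip tiny negatives from rounding
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(D)))
  dimnames(D) <- list(ids, ids)
  D
}

#' Write a distance matrix for external tree building
#'
#' `write_phylip()` writes the relaxed square PHYLIP format (count line,
#' then one name plus its full distance row per line) accepted by
#' Neighbor-Joining tools; `write_distances_tsv()` writes the long
#' three-column form (id1, id2, distance) for each unordered pair.
#'
#' @param D a square distance matrix with identifiers as dimnames.
#' @param path output file.
#' @param digits significant digits written.
#' @return The path, invisibly.
#' @export
write_phylip <- function(D, path, digits = 10) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(D)))
  ids <- gsub("[[:space:]]+", "_", ids)
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste(c(formatC(ids[i], width = 10, flag = "-"),
                       formatC(D[i, ], digits = digits, format = "g")),
                     collapse = "  "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
write_distances_tsv <- function(D, path, digits = 10) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(D)))
  ids <- gsub("[[:space:]]+", "_", ids)
  pr <- which(upper.tri(D), arr.ind = TRUE)
  df <- data.frame(id1 = ids[pr[, 1]], id2 = ids[pr[, 2]],
                   distance = signif(D[pr], digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
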