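#' Random train/validation/test partition
#'
#' Randomly partitions items at a fixed ratio (8:1:1 by default) into
#' disjoint, exhaustive subsets. Sizes follow the largest-remainder rounding
#' rule, remainder ties going to the later subset, so e.g. 8595 items split
#' 8:1:1 gives sizes 6876 / 859 / 860.
#'
#' @param items a vector or list to partition.
#' @param ratios positive weights, one per subset.
#' @param seed integer seed; the same seed reproduces the same partition and
#'   the caller's RNG stream is left untouched.
#' @return A list of subsets of `items` (named `train`, `validation`, `test`
#'   when there are three); attribute `indices` holds the index vectors.
#' @examples
#' sp <- split_dataset(1:100, seed = 1)
#' lengths(sp)  # 80 10 10
#' @export
split_dataset <- function(items, ratios = c(8, 1, 1), seed = NULL) {
  n <- length(items)
  if (any(ratios <= 0)) stop("`ratios` must be positive")
  if (n < 10)
    stop(sprintf("cannot partition %d items; at least 10 are required", n))
  quota <- n * ratios / sum(ratios)
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    give <- order(-frac, -seq_along(frac))[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  if (any(sizes == 0))
    stop("too few items: a subset would be empty at this ratio")
  perm <- .with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  idx <- Map(function(s, e) sort(perm[s:e]), starts, ends)
  out <- lapply(idx, function(i) items[i])
  if (length(ratios) == 3L)
    names(out) <- names(idx) <- c("train", "validation", "test")
  attr(out, "indices") <- idx
  out
}
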