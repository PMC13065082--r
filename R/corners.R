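#' Corner assignment for the Chaos Game Representation
#'
#' The CGR embeds a DNA sequence in the unit square by pulling the current
#' point halfway toward the corner assigned to each successive nucleotide.
#' A corner assignment is a bijection from \{A, C, G, T\} to the four corners
#' \{(0,0), (0,1), (1,0), (1,1)\}.
#'
#' The default assignment is A=(0,0), C=(0,1), G=(1,1), T=(1,0): the
#' convention under which the package's worked-example fixtures hold exactly.
#' The choice of assignment permutes/reflects the feature grid but carries no
#' information; it is configurable for completeness.
#'
#' @param A,C,G,T length-2 numeric vectors, each one of (0,0), (0,1), (1,0),
#'   (1,1); together they must cover all four corners.
#' @return An object of class `cgr_corners`: a 4 x 2 numeric matrix with rows
#'   named A, C, G, T giving each nucleotide's (x, y) corner.
#' @examples
#' cgr_corners()                        # worked-example convention
#' cgr_corners(G = c(1, 0), T = c(1, 1)) # the alternative G/T placement
#' @export
cgr_corners <- function(A = c(0, 0), C = c(0, 1), G = c(1, 1), T = c(1, 0)) {
  m <- rbind(A = as.numeric(A), C = as.numeric(C),
             G = as.numeric(G), T = as.numeric(T))
  colnames(m) <- c("x", "y")
  if (!all(m %in% c(0, 1)) || any(dim(m) != c(4L, 2L)))
    stop("each corner must be one of (0,0), (0,1), (1,0), (1,1)")
  key <- m[, 1] * 2 + m[, 2]
  if (anyDuplicated(key))
    stop("corner assignment must be a bijection: two nucleotides share a corner")
  structure(m, class = "cgr_corners")
}

#' Corner assignment from a four-letter string
#'
#' Shorthand used by the command line: the string lists which nucleotide sits
#' at each corner, visiting the corners in the fixed order
#' (0,0), (0,1), (1,1), (1,0). The default `"ACGT"` therefore reads
#' A=(0,0), C=(0,1), G=(1,1), T=(1,0).
#'
#' @param s a string of the four letters A, C, G, T in some order.
#' @return A [cgr_corners()] object.
#' @export
corners_from_string <- function(s) {
  letters4 <- strsplit(toupper(s), "")[[1]]
  if (length(letters4) != 4L || !setequal(letters4, c("A", "C", "G", "T")))
    stop("corner string must be a permutation of the letters ACGT")
  pos <- list(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  args <- stats::setNames(pos, letters4)
  do.call(cgr_corners, args)
}

#' @export
print.cgr_corners <- function(x, ...) {
  cat("CGR corner assignment:\n")
  for (n in rownames(x))
    cat(sprintf("  %s -> (%g, %g)\n", n, x[n, 1], x[n, 2]))
  invisible(x)
}

stopifnot_corners <- function(corners) {
  if (!inherits(corners, "cgr_corners"))
    stop("`corners` must be created with cgr_corners()")
  corners
}
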