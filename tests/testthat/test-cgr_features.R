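# Featurization: k-mer counts, CGR trajectories, mean positions, cell
# binning, tensor assembly and normalization.

test_that("k-mer counting matches hand-enumerated fixtures", {
  cnt <- count_kmers(worked_seq, 2)
  expect_identical(as.integer(cnt), as.integer(worked_counts[names(cnt)]))

  cnt1 <- count_kmers("AAAA", 1)
  expect_identical(as.integer(cnt1), c(4L, 0L, 0L, 0L))

  cnt3 <- count_kmers("ACGTACGT", 3)
  expect_identical(unname(cnt3[c("ACG", "CGT", "GTA", "TAC")]),
                   c(2L, 2L, 1L, 1L))
  expect_identical(sum(cnt3), 6L)   # L - k + 1

  expect_error(count_kmers("AC", 3), "shorter than")
  expect_error(count_kmers("ACGT", 0), "k")
})

test_that("CGR trajectory follows the midpoint iteration from the centre", {
  expect_identical(unname(cgr_trajectory("A")[1, ]), c(0.25, 0.25))
  expect_identical(unname(cgr_trajectory("AG")[2, ]), c(0.625, 0.625))
  # T pulls toward (1, 0): four T's converge toward that corner
  expect_identical(unname(cgr_trajectory("TTTT")[4, ]), c(0.96875, 0.03125))
  expect_error(cgr_trajectory(""), "empty")
})

test_that("ambiguity codes emit no trajectory point and void their windows", {
  tr <- cgr_trajectory("ACNNGT")
  expect_identical(nrow(tr), 4L)
  expect_identical(attr(tr, "positions"), c(1L, 2L, 5L, 6L))

  cnt <- count_kmers("ACGTNACGT", 2)
  expect_identical(sum(cnt), 6L)    # TN and NA windows contribute nothing

  p <- kmer_average_positions("ACGTNACGT", 2)
  expect_identical(sum(p$counts), 6L)
  # every mean still sits inside its word's cell
  for (w in names(p$counts)[p$counts > 0]) {
    cell <- kmer_cell_index(w, 2)
    expect_gte(p$mean_x[[w]], cell["col"] / 4)
    expect_lte(p$mean_x[[w]], (cell["col"] + 1) / 4)
  }
})

test_that("mean k-mer positions reproduce the printed fixture exactly", {
  p <- kmer_average_positions(worked_seq, 2)
  expect_identical(unname(p$mean_x), unname(worked_mean_x[names(p$mean_x)]))
  expect_identical(unname(p$mean_y), unname(worked_mean_y[names(p$mean_y)]))
  # absent words sit exactly at (0, 0)
  expect_identical(unname(p$mean_x[worked_counts == 0]),
                   rep(0, sum(worked_counts == 0)))
})

test_that("cell indexing is geometric: suffix determines the 2^-k cell", {
  expect_identical(kmer_cell_index("CC", 2), c(row = 0L, col = 0L))
  expect_identical(kmer_cell_index("TT", 2), c(row = 3L, col = 3L))
  expect_identical(kmer_cell_index("GG", 2), c(row = 0L, col = 3L))
  expect_error(kmer_cell_index("NN", 2), "A, C, G or T")

  # a dedicated trajectory: points whose suffix is w land in w's cell
  set.seed(42)
  s <- random_dna(120)
  for (k in 1:3) {
    p <- kmer_average_positions(s, k)
    for (w in names(p$counts)[p$counts > 0]) {
      cell <- kmer_cell_index(w, k)
      lo_x <- cell[["col"]] / 2^k; lo_y <- (2^k - 1 - cell[["row"]]) / 2^k
      expect_true(p$mean_x[[w]] > lo_x && p$mean_x[[w]] < lo_x + 2^-k)
      expect_true(p$mean_y[[w]] > lo_y && p$mean_y[[w]] < lo_y + 2^-k)
    }
  }
})

test_that("feature tensor places counts and means at the right cells", {
  tz <- build_feature_tensor(worked_seq, 2, normalize = FALSE)
  gt <- kmer_cell_index("GT", 2)
  expect_identical(unname(tz[gt[["row"]] + 1, gt[["col"]] + 1, "freq"]), 2)
  expect_identical(unname(tz[gt[["row"]] + 1, gt[["col"]] + 1, "mean_x"]), 0.83203125)
  expect_identical(unname(tz[gt[["row"]] + 1, gt[["col"]] + 1, "mean_y"]), 0.36328125)
  expect_identical(sum(tz[, , "freq"]), 9)   # L - k + 1

  # two-step derivation: "AC" has a single window at (0.125, 0.625)
  t2 <- build_feature_tensor("AC", 2, normalize = FALSE)
  ac <- kmer_cell_index("AC", 2)
  expect_identical(sum(t2[, , "freq"] != 0), 1L)
  expect_identical(t2[ac[["row"]] + 1, ac[["col"]] + 1, ],
                   c(freq = 1, mean_x = 0.125, mean_y = 0.625))

  # k = 7 gives the full-size 128 x 128 grid
  t7 <- build_feature_tensor(random_dna(64), 7, normalize = FALSE)
  expect_identical(dim(t7), c(128L, 128L, 3L))
})

test_that("positional channels are zero exactly where the count is zero", {
  set.seed(7)
  for (rep in 1:5) {
    k <- sample(1:4, 1)
    tz <- build_feature_tensor(random_dna(sample(20:200, 1)), k,
                               normalize = FALSE)
    zero <- tz[, , "freq"] == 0
    expect_true(all(tz[, , "mean_x"][zero] == 0))
    expect_true(all(tz[, , "mean_y"][zero] == 0))
    expect_true(all(tz[, , "mean_x"][!zero] > 0))
    expect_true(all(tz[, , "mean_y"][!zero] > 0))
  }
})

test_that("min-max normalization rescales channels to [0,1]", {
  tz <- build_feature_tensor(worked_seq, 2, normalize = FALSE)
  nz <- minmax_normalize(tz)
  expect_true(all(nz >= 0 & nz <= 1))
  gt <- kmer_cell_index("GT", 2)
  expect_identical(unname(nz[gt[["row"]] + 1, gt[["col"]] + 1, "freq"]), 1)  # max count
  expect_error(minmax_normalize(nz), "already normalized")

  # degenerate constant channel maps to zeros
  t1 <- build_feature_tensor("AAAA", 1, normalize = FALSE)
  n1 <- minmax_normalize(t1)
  expect_true(all(n1[, , "mean_x"] %in% c(0, 1)))  # single nonzero cell
  expect_identical(sum(n1[, , "freq"]), 1)

  # {0,1,2} -> {0,0.5,1} per channel, via the worked counts
  expect_identical(sort(unique(as.vector(nz[, , "freq"]))), c(0, 0.5, 1))
})

test_that("relabeling corners reflects the geometry without losing structure", {
  # y-reflection of the default assignment: A<->C and G<->T swap rows
  refl <- cgr_corners(A = c(0, 1), C = c(0, 0), G = c(1, 0), T = c(1, 1))
  set.seed(11)
  for (rep in 1:3) {
    s <- random_dna(80)
    k <- sample(1:3, 1)
    a <- kmer_average_positions(s, k)
    b <- kmer_average_positions(s, k, corners = refl)
    expect_identical(a$counts, b$counts)
    occ <- a$counts > 0
    expect_equal(b$mean_x[occ], a$mean_x[occ], tolerance = 1e-12)
    expect_equal(unname(b$mean_y[occ]), unname(1 - a$mean_y[occ]),
                 tolerance = 1e-12)
  }
})

test_that("corner assignments are validated as bijections", {
  expect_error(cgr_corners(A = c(0, 0), C = c(0, 0)), "bijection")
  expect_error(cgr_corners(A = c(0.5, 0)), "corner")
  expect_identical(corners_from_string("ACGT"), cgr_corners())
  expect_error(corners_from_string("ACGG"), "permutation")
})
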