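# Flattening, cosine similarity/distance and the pairwise matrix export.

test_that("flattening is 3*4^k long, channel-major, row-major per channel", {
  tz <- build_feature_tensor(worked_seq, 2, normalize = FALSE)
  v <- flatten_tensor(tz)
  expect_length(v, 48)

  gt <- kmer_cell_index("GT", 2)
  offset <- gt[["row"]] * 4 + gt[["col"]] + 1   # row-major within channel 1
  expect_identical(unname(v[offset]), 2)        # the worked-example GT count
  expect_identical(unname(v[16 + offset]), 0.83203125)
  expect_identical(unname(v[32 + offset]), 0.36328125)

  t7 <- build_feature_tensor(random_dna(300), 7)
  expect_length(flatten_tensor(t7), 3 * 128 * 128)
})

test_that("cosine similarity and distance match closed forms", {
  expect_identical(cosine_similarity(c(2, 3, 4), c(2, 3, 4)), 1)
  expect_identical(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_identical(cosine_distance(c(5, 5), c(5, 5)), 0)
  expect_identical(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("pairwise matrix is symmetric, zero-diagonal, scale-invariant and
           matches a naive double loop", {
  set.seed(61)
  seqs <- setNames(replicate(8, random_dna(150)), paste0("s", 1:8))
  tensors <- featurize(seqs, k = 2)
  D <- pairwise_distances(tensors)
  expect_identical(D, t(D))
  expect_identical(unname(diag(D)), rep(0, 8))
  expect_true(all(D >= 0 & D <= 2))

  vecs <- lapply(tensors, flatten_tensor)
  for (i in 1:8) for (j in 1:8) if (i != j)
    expect_equal(D[i, j], cosine_distance(vecs[[i]], vecs[[j]]),
                 tolerance = 1e-12)

  # scaling a vector leaves its cosine distances unchanged
  V <- do.call(rbind, vecs)
  V2 <- V; V2[1, ] <- 3.7 * V2[1, ]
  expect_equal(pairwise_distances(V2), pairwise_distances(V),
               tolerance = 1e-12)

  # a duplicated sequence sits at distance zero off the diagonal
  dup <- featurize(c(a = seqs[[1]], b = seqs[[1]]), k = 2)
  expect_equal(pairwise_distances(dup)["a", "b"], 0, tolerance = 1e-12)
})

test_that("mixed-k and degenerate inputs are rejected", {
  t2 <- build_feature_tensor(random_dna(50), 2)
  t3 <- build_feature_tensor(random_dna(50), 3)
  expect_error(pairwise_distances(list(a = t2, b = t3)), "same k")
  expect_error(pairwise_distances(list(a = t2)), "at least 2")
})

test_that("separated classes are farther apart than within-class pairs", {
  specs <- make_class_specs(2, separation = 1, seed = 71)
  ds <- sample_sequences(specs, n_per_class = 5, length = 1000, seed = 71)
  tensors <- featurize(ds$sequences, k = 3)
  D <- pairwise_distances(tensors)
  same <- outer(ds$labels, ds$labels, "==") & upper.tri(D)
  diff_ <- outer(ds$labels, ds$labels, "!=") & upper.tri(D)
  expect_gt(mean(D[diff_]), mean(D[same]))
})

test_that("PHYLIP and long-form exports are well-formed", {
  set.seed(81)
  tensors <- featurize(setNames(replicate(3, random_dna(100)),
                                c("phage one", "phage_2", "phage_3")), k = 2)
  D <- pairwise_distances(tensors)
  f <- tempfile(fileext = ".phy")
  write_phylip(D, f)
  lines <- readLines(f)
  expect_length(lines, 4)
  expect_identical(as.integer(trimws(lines[1])), 3L)
  row1 <- strsplit(trimws(lines[2]), "[[:space:]]+")[[1]]
  expect_identical(row1[1], "phage_one")          # whitespace relaxed away
  expect_equal(as.numeric(row1[-1]), unname(D[1, ]), tolerance = 1e-8)

  g <- tempfile(fileext = ".tsv")
  write_distances_tsv(D, g)
  df <- read.delim(g)
  expect_identical(nrow(df), 3L)                   # the 3 unordered pairs
  expect_equal(df$distance[df$id1 == "phage_one" & df$id2 == "phage_2"],
               D["phage one", "phage_2"], tolerance = 1e-8)
})
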