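test_that("build_matrix matches a brute-force double loop per metric", {
  set.seed(31)
  s <- random_sequence(6, 10, 8)
  emb <- embed_flatten(s)
  for (metric in c("cosine", "l1", "psnr", "ssim")) {
    M <- build_matrix(s, detector_params(metric))
    expect_s3_class(M, "pairwise_matrix")
    for (i in 0:4) for (j in (i + 1):5) {
      expected <- if (metric == "cosine")
        cosine_similarity(emb[i + 1, ], emb[j + 1, ])
      else compare_frames(s, i, j, metric)
      expect_equal(M$values[i + 1, j + 1], expected, tolerance = 1e-12)
      expect_equal(M$values[j + 1, i + 1], M$values[i + 1, j + 1])
    }
  }
})

test_that("identical frames give the identity similarity/difference matrices", {
  s <- frame_sequence(replicate(3, matrix(9, 5, 5), simplify = FALSE))
  expect_equal(build_matrix(s, detector_params("cosine"))$values,
               matrix(1, 3, 3))
  expect_equal(build_matrix(s, detector_params("l1"))$values,
               matrix(0, 3, 3))
  ssim_m <- build_matrix(s, detector_params("ssim"))$values
  expect_equal(ssim_m, matrix(1, 3, 3), tolerance = 1e-12)
})

test_that("the psnr diagonal is stored finite, above every other cell", {
  set.seed(32)
  s <- random_sequence(5, 8, 8)
  v <- build_matrix(s, detector_params("psnr"))$values
  expect_true(all(is.finite(v)))
  off <- v[row(v) != col(v)]
  expect_true(all(diag(v) > max(off)))
  expect_equal(diag(v), rep(max(off) + 1, 5))
})

test_that("find_local_extrema isolates a single planted minimum", {
  v <- matrix(0.9, 5, 5)
  diag(v) <- 1
  v[2, 5] <- v[5, 2] <- 0.2
  M <- pairwise_matrix(v, "similarity", "cosine")
  cands <- find_local_extrema(M, 2, 2, border = "clip")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$i, 1L)
  expect_equal(cands$j, 4L)
  expect_equal(cands$value, 0.2)
  # negation duality: maxima of -M are the same cells
  Mn <- pairwise_matrix(-v, "difference", "neg")
  expect_equal(find_local_extrema(Mn, 2, 2, border = "clip")[, c("i", "j")],
               cands[, c("i", "j")])
  # constant matrices have no strict extrema
  Mc <- pairwise_matrix(matrix(1, 5, 5), "similarity", "const")
  expect_equal(nrow(find_local_extrema(Mc, 2, 2)), 0L)
})

test_that("find_local_extrema matches the exhaustive oracle on random matrices", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(6:25, 1)
    v <- random_symmetric_matrix(n)
    orient <- sample(c("similarity", "difference"), 1)
    border <- sample(c("clip", "interior"), 1)
    w <- sample(1:3, 1)
    M <- pairwise_matrix(v, orient, "random")
    got <- find_local_extrema(M, w, 2, border = border)
    want <- brute_extrema(v, orient, w, 2, border = border)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$value, want$value)
  }
})

test_that("wider windows never produce more candidates", {
  set.seed(34)
  for (rep in 1:20) {
    v <- random_symmetric_matrix(sample(8:20, 1))
    M <- pairwise_matrix(v, "similarity", "random")
    counts <- vapply(1:3, function(w)
      nrow(find_local_extrema(M, w, 2, border = "clip")), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("suppression implements the greedy distance rule", {
  # a frame 1 step from an accepted keyframe is suppressed,
  # one 3 steps away is retained (min_separation 2)
  cands <- data.frame(i = c(0L, 1L), j = c(5L, 8L), value = c(0.1, 0.2))
  res <- suppress_candidates(cands, "similarity", 2)
  expect_true(all(c(0L, 5L, 8L) %in% res$keyframes))
  expect_false(1L %in% res$keyframes)

  cands <- data.frame(i = c(0L, 3L), j = c(5L, 8L), value = c(0.1, 0.2))
  res <- suppress_candidates(cands, "similarity", 2)
  expect_equal(res$keyframes, c(0L, 3L, 5L, 8L))

  # worked step-through: frame 3 suppressed by 2, repeat of 9 deduplicated
  cands <- data.frame(i = c(2L, 3L, 6L), j = c(9L, 9L, 12L),
                      value = c(0.1, 0.15, 0.2))
  res <- suppress_candidates(cands, "similarity", 2)
  expect_equal(res$keyframes, c(2L, 6L, 9L, 12L))
  # every keyframe appears as an endpoint of a provenance pair
  prov_frames <- unique(c(res$provenance$i, res$provenance$j))
  expect_true(all(res$keyframes %in% prov_frames))
})

test_that("suppression matches the step-through oracle on random lists", {
  set.seed(35)
  for (rep in 1:50) {
    cands <- random_candidates(n_frames = 30, k = sample(3:12, 1))
    orient <- sample(c("similarity", "difference"), 1)
    res <- suppress_candidates(cands, orient, 2)
    expect_equal(res$keyframes, brute_suppress(cands, orient, 2))
    # safety: all pairwise keyframe distances >= min_separation
    if (length(res$keyframes) > 1)
      expect_gte(min(dist(res$keyframes)), 2)
  }
  empty <- suppress_candidates(
    data.frame(i = integer(0), j = integer(0), value = numeric(0)),
    "similarity", 2)
  expect_length(empty$keyframes, 0L)
})

test_that("detect recovers phantom extremes and is deterministic", {
  ph <- generate_phantom(phantom_config(n_frames = 30, period = 10))
  res <- detect_keyframes(ph$sequence, detector_params("cosine", "flatten"))
  truth <- which(ph$labels == 1) - 1L
  # every detection within +-1 of a true extreme, at most one extreme missed
  expect_true(all(vapply(res$keyframes, function(k)
    min(abs(truth - k)) <= 1, logical(1))))
  expect_gte(length(res$keyframes), 5L)
  res2 <- detect_keyframes(ph$sequence, detector_params("cosine", "flatten"))
  expect_identical(res$keyframes, res2$keyframes)

  const <- frame_sequence(replicate(6, matrix(3, 8, 8), simplify = FALSE))
  expect_length(detect_keyframes(const, detector_params("l1"))$keyframes, 0L)
})

test_that("similarity detection on M equals difference detection on -M", {
  set.seed(36)
  v <- random_symmetric_matrix(15)
  for (border in c("clip", "interior")) {
    a <- find_local_extrema(pairwise_matrix(v, "similarity", "m"),
                            2, 2, border = border)
    b <- find_local_extrema(pairwise_matrix(-v, "difference", "m"),
                            2, 2, border = border)
    expect_equal(a[, c("i", "j")], b[, c("i", "j")])
    ra <- suppress_candidates(a, "similarity", 2)
    rb <- suppress_candidates(b, "difference", 2)
    expect_identical(ra$keyframes, rb$keyframes)
  }
})

test_that("matrix CSV export round-trips and rejects asymmetry", {
  set.seed(37)
  v <- random_symmetric_matrix(6)
  M <- pairwise_matrix(v, "similarity", "cosine")
  path <- withr::local_tempfile(fileext = ".csv")
  export_matrix(M, path)
  M2 <- import_matrix(path)
  expect_lt(max(abs(M2$values - v)), 1e-9)
  # header row and column carry 0-based frame indices
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_equal(hdr, c("frame", as.character(0:5)))

  bad <- v
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(pairwise_matrix(bad, "similarity"),
               class = "cdkd_invariant_error")
})
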