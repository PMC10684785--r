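toy_D <- function() {
  D <- rbind(c(0, 0.2, 0.6), c(0.2, 0, 0.4), c(0.6, 0.4, 0))
  dimnames(D) <- list(c("A", "B", "C"), c("A", "B", "C"))
  D
}

test_that("detection uses a strict threshold", {
  x <- c(MAG1 = 0.5, MAG2 = 0.0009, MAG3 = 0.4991)
  det <- detect_mags(x, 0.001)
  expect_identical(det$mags, c("MAG1", "MAG3"))
  expect_identical(det$n, 2L)

  x <- c(MAG1 = 0.999, MAG2 = 0.001)
  expect_identical(detect_mags(x, 0.001)$mags, "MAG1")  # boundary excluded

  x <- c(MAG1 = 0.7, MAG2 = 0.3, MAG3 = 0)
  expect_identical(detect_mags(x, 0)$mags, c("MAG1", "MAG2"))
})

test_that("overall-mean overlap matches hand-derived values and bounds", {
  D <- toy_D()
  # pairwise distances 0.2, 0.4, 0.6; mean over 6 ordered pairs = 0.4
  expect_equal(overlap_overall_mean(D, c("A", "B", "C")), 0.6)
  Did <- matrix(0, 3, 3, dimnames = dimnames(D))
  expect_equal(overlap_overall_mean(Did, c("A", "B", "C")), 1)
  Ddisj <- 1 - diag(3); dimnames(Ddisj) <- dimnames(D)
  expect_equal(overlap_overall_mean(Ddisj, c("A", "B", "C")), 0)
  expect_true(is.na(overlap_overall_mean(D, "A")))
})

test_that("nearest-neighbor overlap matches hand-derived values", {
  D <- toy_D()
  # minima: A -> 0.2, B -> 0.2, C -> 0.4
  expect_equal(overlap_nearest_mean(D, c("A", "B", "C")), 1 - 0.8 / 3)
  D2 <- rbind(c(0, 0), c(0, 0)); dimnames(D2) <- list(c("A", "B"), c("A", "B"))
  expect_equal(overlap_nearest_mean(D2, c("A", "B")), 1)
  expect_true(is.na(overlap_nearest_mean(D, "A")))
})

test_that("weighted overlap matches the hand dot product and its limits", {
  D <- toy_D()
  det <- structure(list(mags = c("A", "B", "C"), n = 3L,
                        p = c(A = 0.5, B = 0.3, C = 0.2)),
                   class = "detected_set")
  expect_equal(overlap_weighted_nearest_mean(D, det), 0.76)
  # uniform weights reduce to the unweighted nearest mean
  unif <- structure(list(mags = c("A", "B", "C"), n = 3L,
                         p = c(A = 1, B = 1, C = 1) / 3),
                    class = "detected_set")
  expect_equal(overlap_weighted_nearest_mean(D, unif),
               overlap_nearest_mean(D, c("A", "B", "C")))
  # a dominant MAG drives the score to 1 minus its nearest-neighbor distance
  dom <- structure(list(mags = c("A", "B", "C"), n = 3L,
                        p = c(A = 1 - 2e-9, B = 1e-9, C = 1e-9)),
                   class = "detected_set")
  expect_equal(overlap_weighted_nearest_mean(D, dom), 1 - 0.2,
               tolerance = 1e-6)
})

test_that("overlap series handles constant tables, dropouts, and id mismatch", {
  D <- toy_D()
  a <- make_abundance(list(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)))
  colnames(a) <- c("A", "B", "C")
  ov <- overlap_series(D, a)
  expect_equal(length(unique(ov$overall_mean)), 1L)
  expect_equal(length(unique(ov$weighted_nearest_mean)), 1L)

  a2 <- make_abundance(list(c(0.5, 0.3, 0.2), c(0.9995, 0.0003, 0.0002)))
  colnames(a2) <- c("A", "B", "C")
  ov2 <- overlap_series(D, a2)
  expect_equal(ov2$n_detected, c(3L, 1L))
  expect_true(all(is.na(ov2[2, c("overall_mean", "nearest_mean",
                                 "weighted_nearest_mean")])))

  colnames(a2) <- c("A", "B", "Z")
  expect_error(overlap_series(D, a2), "Z")
})

test_that("scores are bounded, ordered, and threshold-invariant on random communities", {
  set.seed(31)
  for (k in 1:200) {
    n <- sample(3:8, 1)
    m <- random_gene_matrix(n, 40)
    D <- pairwise_jaccard(m)
    p <- random_composition(n)
    names(p) <- rownames(m)
    det <- detect_mags(p, 0)
    ov <- overlap_overall_mean(D, det)
    nn <- overlap_nearest_mean(D, det)
    wn <- overlap_weighted_nearest_mean(D, det)
    for (s in c(ov, nn, wn)) { expect_gte(s, 0); expect_lte(s, 1) }
    expect_gte(nn, ov)  # a MAG's nearest distance <= its mean distance
  }
})

test_that("MAGs below the detection threshold do not affect the scores", {
  set.seed(32)
  m <- random_gene_matrix(6, 40)
  D <- pairwise_jaccard(m)
  p <- c(0.4, 0.3, 0.2995, 0.0002, 0.0002, 0.0001)
  names(p) <- rownames(m)
  det_all <- detect_mags(p, 0.001)
  expect_identical(det_all$mags, rownames(m)[1:3])
  sub <- p[1:3] / sum(p[1:3])
  det_sub <- detect_mags(sub, 0.001)
  expect_equal(overlap_overall_mean(D, det_all), overlap_overall_mean(D, det_sub))
  expect_equal(overlap_nearest_mean(D, det_all), overlap_nearest_mean(D, det_sub))
  # weighted index: renormalization over T makes the undetected tail irrelevant
  expect_equal(overlap_weighted_nearest_mean(D, det_all),
               overlap_weighted_nearest_mean(D, det_sub), tolerance = 1e-3)
})

test_that("all three indices agree with brute-force enumeration", {
  set.seed(33)
  for (k in 1:100) {
    n <- sample(3:7, 1)
    m <- random_gene_matrix(n, 30)
    D <- pairwise_jaccard(m)
    ids <- rownames(m)
    p <- random_composition(n); names(p) <- ids
    det <- detect_mags(p, 0)
    expect_equal(overlap_overall_mean(D, det), oracle_overall(D, ids))
    expect_equal(overlap_nearest_mean(D, det), oracle_nearest(D, ids))
    expect_equal(overlap_weighted_nearest_mean(D, det), oracle_weighted(D, ids, p))
  }
})

test_that("global weight normalization is available and differs when T is a strict subset", {
  set.seed(34)
  m <- random_gene_matrix(4, 30)
  D <- pairwise_jaccard(m)
  p <- c(0.5, 0.3, 0.1995, 0.0005)
  names(p) <- rownames(m)
  det <- detect_mags(p, 0.001)
  g <- overlap_weighted_nearest_mean(D, det, weight_normalization = "global")
  d <- overlap_weighted_nearest_mean(D, det, weight_normalization = "detected_set")
  expect_gte(g, d)  # global weights sum below 1, shrinking the penalty
})
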