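daily_table <- function(rows) make_abundance(rows, days = seq_along(rows))

test_that("RPKM normalization matches the worked example", {
  cov <- data.frame(day = c(1, 1), mag_id = c("A", "B"),
                    mapped_reads = c(100, 200),
                    genome_length_bp = c(1e6, 2e6),
                    total_mapped = c(1e6, 1e6))
  a <- relative_abundance_from_coverage(cov)
  # equal per-base coverage: RPKM (0.1, 0.1) -> abundances (0.5, 0.5)
  expect_equal(unname(a[1, ]), c(0.5, 0.5))
})

test_that("coverage normalization is scale invariant and closes to the simplex", {
  cov <- data.frame(day = rep(c(1, 2), each = 3),
                    mag_id = rep(c("A", "B", "C"), 2),
                    mapped_reads = c(120, 40, 300, 10, 80, 7),
                    genome_length_bp = rep(c(3e6, 1e6, 5e6), 2),
                    total_mapped = rep(c(2e6, 3e6), each = 3))
  a <- relative_abundance_from_coverage(cov)
  expect_equal(unname(rowSums(a)), c(1, 1))
  cov2 <- cov
  cov2$mapped_reads <- cov2$mapped_reads * 7
  cov2$total_mapped <- cov2$total_mapped * 7
  expect_equal(relative_abundance_from_coverage(cov2), a)

  single <- data.frame(day = 1, mag_id = "A", mapped_reads = 5,
                       genome_length_bp = 1e6, total_mapped = 1e6)
  expect_equal(unname(relative_abundance_from_coverage(single)[1, ]), 1)
})

test_that("abruptness matches hand-derived window examples", {
  const <- daily_table(rep(list(c(0.6, 0.4)), 10))
  expect_equal(abruptness(const, 5), 0)

  turnover <- daily_table(c(rep(list(c(1, 0)), 5), rep(list(c(0, 1)), 5)))
  expect_equal(abruptness(turnover, 5), 1)

  # window means (1, 0) vs (0.5, 0.5) -> Bray-Curtis 0.5
  half <- daily_table(c(rep(list(c(1, 0)), 5), rep(list(c(0.5, 0.5)), 5)))
  expect_equal(abruptness(half, 5), 0.5)
})

test_that("abruptness is undefined for incomplete windows", {
  a <- daily_table(rep(list(c(0.5, 0.5)), 12))
  ab <- abruptness_series(a, w = 5)
  expect_true(all(is.na(ab[1:4])))        # first w - 1 days
  expect_true(all(is.na(ab[8:12])))       # last w days
  expect_true(all(!is.na(ab[5:7])))
})

test_that("abruptness agrees with a brute-force window oracle", {
  set.seed(41)
  for (k in 1:100) {
    a <- daily_table(lapply(1:14, function(i) random_composition(5)))
    t <- sample(5:9, 1)
    expect_equal(abruptness(a, t), oracle_abruptness(a, t))
  }
})

test_that("consecutive beta-diversity honors the count contract and oracle", {
  a <- make_abundance(lapply(1:13, function(i) random_composition(6)),
                      days = c(1, 10, 20, 24, 30, 40, 50, 60, 70, 80, 90, 100, 110))
  b <- consecutive_beta(a)
  expect_length(b, 13L)
  expect_true(is.na(b[13]))
  expect_equal(sum(!is.na(b)), 12L)
  for (k in 1:12) expect_equal(b[k], oracle_bray(a[k, ], a[k + 1, ]))

  same <- daily_table(rep(list(c(0.3, 0.7)), 4))
  expect_equal(consecutive_beta(same)[1:3], rep(0, 3))
})

test_that("Shannon diversity matches hand-derived values and the uniform maximum", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon(rep(0.25, 4), base = 2), 2)
  set.seed(42)
  for (k in 1:50) {
    n <- sample(3:10, 1)
    expect_lte(shannon(random_composition(n)), log(n))
  }
})

test_that("rescale01 maps endpoints exactly and preserves NA", {
  expect_equal(rescale01(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(2, NA, 6, 4)
  r <- rescale01(v)
  expect_true(is.na(r[2]))
  expect_equal(r[c(1, 3, 4)], c(0, 1, 0.5))
  expect_equal(min(r, na.rm = TRUE), 0)
  expect_equal(max(r, na.rm = TRUE), 1)
  expect_error(rescale01(c(3, 3, 3)), "constant")
  expect_error(rescale01(c(NA, 1)), "2 defined values")
})

test_that("dynamics series assembles all statistics with rescaled copies", {
  set.seed(43)
  a <- daily_table(lapply(1:15, function(i) random_composition(4)))
  d <- dynamics_series(a)
  expect_s3_class(d, "dynamics_series")
  expect_identical(colnames(d),
                   c("day", "beta_next", "abruptness", "alpha",
                     "beta_next_rescaled", "abruptness_rescaled", "alpha_rescaled"))
  expect_equal(min(d$alpha_rescaled, na.rm = TRUE), 0)
  expect_equal(max(d$beta_next_rescaled, na.rm = TRUE), 1)
  expect_true(all(d$beta_next >= 0 & d$beta_next <= 1, na.rm = TRUE))
  expect_true(all(d$abruptness >= 0 & d$abruptness <= 1, na.rm = TRUE))
  expect_true(all(d$alpha >= 0))
})

test_that("an engineered single-day turnover exceeds 0.5 only near the flip", {
  flip <- daily_table(c(rep(list(c(0.98, 0.02)), 10), rep(list(c(0.02, 0.98)), 10)))
  ab <- abruptness_series(flip)
  over <- which(!is.na(ab) & ab > 0.5)
  expect_true(all(over >= 7 & over <= 14))
  expect_gt(max(ab, na.rm = TRUE), 0.9)
  far <- c(5, 6, 15)
  expect_true(all(ab[far] <= 0.5, na.rm = TRUE))
})
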