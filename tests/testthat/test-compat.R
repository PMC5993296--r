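test_that("fragment strand-bias follows the sup definition", {
  w <- "ACGGTCAT"
  # single-strand donor: every informative fragment has bias 1
  d1 <- planted_donor(60000, w, seq(100, 59000, by = 400), rep(1, 148),
                      seed = 27)
  fb <- fragment_bias(d1, w, n_fragments = 300, frag_bp = 10000, seed = 4)
  expect_equal(fb$mean_bias, 1.0)
  expect_equal(fb$n_informative, 300)
  # deterministic under the same seed
  fb2 <- fragment_bias(d1, w, n_fragments = 300, frag_bp = 10000, seed = 4)
  expect_identical(fb$mean_bias, fb2$mean_bias)
  # bias bounded in [0.5, 1] for mixed-strand donors
  set.seed(28)
  d2 <- planted_donor(60000, w, seq(100, 59000, by = 400),
                      sample(c(1, -1), 148, TRUE), seed = 29)
  fb3 <- fragment_bias(d2, w, n_fragments = 500, frag_bp = 10000, seed = 5)
  expect_gte(fb3$mean_bias, 0.5)
  expect_lte(fb3$mean_bias, 1)
  expect_error(fragment_bias(genome("s", random_seq(100, seed = 1)), w),
               "shorter than one fragment")
})

test_that("random-fragment means agree with the exhaustive-fragment oracle", {
  w <- "ACGGTCAT"
  set.seed(30)
  d <- planted_donor(30000, w, seq(50, 29000, by = 400),
                     sample(c(1, -1), 73, TRUE), seed = 31)
  s <- as.character(d$sequence)
  hits <- naive_motif_scan(s, w, circular = TRUE)
  pw <- sort(hits$pos[hits$strand == 1]); pc <- sort(hits$pos[hits$strand == -1])
  L <- 30000
  sbs <- vapply(0:(L - 1), function(a) {
    hi <- a + 10000 - 8
    cnt <- function(p) sum(p >= a & p <= hi) +
      (if (hi >= L) sum(p <= hi - L) else 0)
    nw <- cnt(pw); nc <- cnt(pc)
    if (nw + nc == 0) NA_real_ else max(nw, nc) / (nw + nc)
  }, numeric(1))
  exact <- mean(sbs, na.rm = TRUE)
  mc <- fragment_bias(d, w, n_fragments = 2000, frag_bp = 10000, seed = 6)
  se <- sd(sbs, na.rm = TRUE) / sqrt(2000)
  expect_lt(abs(mc$mean_bias - exact), 3 * se + 1e-9)
})

test_that("compatibility is the abundance-weighted mean of fragment biases", {
  expect_identical(compat_weighted_mean(c(0.8, 0.6), c(100, 300)), 0.65)
  # duplicate listing with coherent weights leaves the score unchanged
  expect_equal(compat_weighted_mean(c(0.8, 0.6, 0.6), c(100, 150, 150)),
               0.65)
  w <- "ACGGTCAT"
  d <- planted_donor(50000, w, seq(100, 49000, by = 400), rep(1, 123),
                     seed = 33)
  cs <- compatibility(data.frame(octamer = w, n_i = 100), d,
                      n_fragments = 200, seed = 7)
  expect_equal(cs$c_xy, 1.0)
  cs2 <- compatibility(data.frame(octamer = w, n_i = 100), d,
                       n_fragments = 200, seed = 7)
  expect_identical(cs$c_xy, cs2$c_xy)
})

test_that("compatibility is directionally asymmetric when AIMS sharing is", {
  # genome 1's AIMS (X) planted strand-pure in genome 1, random in
  # genome 3; genome 3's AIMS (Y) planted strand-pure in genome 1.
  X <- "ACGGTCAT"; Y <- "TGCAACGG"
  set.seed(34)
  posX <- seq(100, 79000, by = 600)
  posY <- seq(400, 79200, by = 600)
  g1 <- planted_donor(80000, X, posX, rep(1, length(posX)), seed = 35)
  v <- strsplit(as.character(g1$sequence), "")[[1]]
  for (x in posY) v[(x + 1):(x + 8)] <- strsplit(Y, "")[[1]]
  g1 <- genome("g1", paste(v, collapse = ""))
  g3 <- planted_donor(80000, X, posX, sample(c(1, -1), length(posX), TRUE),
                      seed = 36)
  c_1from3 <- compatibility(data.frame(octamer = X, n_i = 100), g3,
                            n_fragments = 400, seed = 8)$c_xy
  c_3from1 <- compatibility(data.frame(octamer = Y, n_i = 100), g1,
                            n_fragments = 400, seed = 9)$c_xy
  expect_gt(c_3from1, 0.95)             # transfer 1 -> 3 unimpeded
  expect_lt(c_1from3, 0.75)             # transfer 3 -> 1 reduced
  expect_gt(c_3from1 - c_1from3, 0.2)
})

test_that("group summaries report per-group means, deltas and regressions", {
  df <- data.frame(donor_id = sprintf("d%d", 1:6),
                   c_xy = c(0.9, 0.85, 0.7, 0.72, 0.6, 0.62))
  groups <- setNames(c("same_family", "same_family",
                       "same_division_different_family",
                       "same_division_different_family",
                       "different_division", "different_division"),
                     df$donor_id)
  gs <- group_summary(df, groups)
  expect_equal(gs$table$mean_c, c(0.875, 0.71, 0.61))
  expect_equal(unname(gs$deltas["family"]), 0.875 - 0.71)
  expect_equal(unname(gs$deltas["division"]),
               mean(c(0.9, 0.85, 0.7, 0.72)) - 0.61)
  # all donors in one group: other groups blank, not zero
  g2 <- setNames(rep("same_family", 6), df$donor_id)
  gs2 <- group_summary(df, g2)
  expect_true(is.na(gs2$table$mean_c[3]))
  expect_error(group_summary(df, groups[1:3]), "labelled")
  idn <- setNames(seq(0.99, 0.80, length.out = 6), df$donor_id)
  gs3 <- group_summary(df, groups, identity = idn)
  expect_s3_class(gs3$regression, "lm")
  expect_gt(coef(gs3$regression)[2], 0)
})
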