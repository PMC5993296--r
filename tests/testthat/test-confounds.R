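test_that("codon metrics behave at their known reference points", {
  gc <- Biostrings::GENETIC_CODE
  one_per_aa <- vapply(unique(gc[gc != "*"]), function(a)
    names(gc)[gc == a][1], character(1))
  gene <- paste(rep(one_per_aa, 6), collapse = "")
  expect_equal(aimsarch:::enc_wright(aimsarch:::split_codons(gene)), 20)
  # uniform usage across many codons approaches the 61-codon ceiling
  set.seed(54)
  sense <- names(gc)[gc != "*"]
  big <- paste(sample(sense, 6000, replace = TRUE), collapse = "")
  expect_gt(aimsarch:::enc_wright(aimsarch:::split_codons(big)), 55)
})

test_that("codon-bias regressions are null on gradient-free genes", {
  fix <- generate_genome(plant_spec(length = 3e5), seed = 55)
  cb <- codon_bias_gradient(fix$features, fix$genome, fix$map)
  # position-independent usage: no metric should show a strong gradient
  ps <- vapply(c("enc", "deviation", "gc3", "rscu"),
               function(m) cb[[m]]$p, numeric(1))
  expect_gte(sum(ps > 0.05), 3)
})

test_that("a planted origin-proximal codon bias is recovered with its sign", {
  # genes near the origin biased toward a codon subset
  set.seed(56)
  L <- 3e5
  m <- replichore_map(0, L / 2, L)
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[gcode != "*"]
  starts <- seq(100, L - 1000, by = 1200)
  d <- distance_from_terminus(starts + 450, m)
  seqs <- vapply(seq_along(starts), function(i) {
    w <- rep(1, length(sense))
    # bias strength grows toward the origin (d -> 50)
    w[seq(1, length(sense), by = 2)] <- 1 + 3 * d[i] / 50
    paste(sample(sense, 300, TRUE, prob = w / sum(w)), collapse = "")
  }, character(1))
  v <- strsplit(random_seq(L, seed = 57), "")[[1]]
  for (i in seq_along(starts))
    v[(starts[i] + 1):(starts[i] + 900)] <- strsplit(seqs[i], "")[[1]]
  g <- genome("cb", paste(v, collapse = ""))
  ft <- gene_features(sprintf("g%d", seq_along(starts)), starts,
                      starts + 900L, rep(1L, length(starts)))
  cb <- codon_bias_gradient(ft, g, m, metrics = "enc")
  expect_lt(cb$enc$p, 0.05)
  # stronger codon bias near the origin: effective codon number falls
  # as distance from the terminus grows
  expect_lt(cb$enc$slope, 0)
})

test_that("inverted-repeat pairing handles the worked and palindromic cases", {
  # one k-mer and its reverse complement, nothing else matching
  L <- 120000
  v <- rep("A", L)
  w <- "CCGTC"; rc <- revcomp_chr(w)
  v[101:105] <- strsplit(w, "")[[1]]
  v[401:405] <- strsplit(rc, "")[[1]]
  g <- genome("ir", paste(v, collapse = ""))
  m <- replichore_map(0, L / 2, L)
  ir <- inverted_repeat_spacing(g, m, k = 5, window_bp = 10000)
  expect_equal(ir$n_pairs, 1L)
  expect_equal(ir$windows$spacing[1], 300)
  # palindromic k-mers pair with themselves
  v2 <- rep("A", L)
  p <- "CCGCGG"   # own reverse complement
  for (x in c(200, 900, 5000)) v2[(x + 1):(x + 6)] <- strsplit(p, "")[[1]]
  g2 <- genome("ir2", paste(v2, collapse = ""))
  ir2 <- inverted_repeat_spacing(g2, m, k = 6, window_bp = 10000)
  expect_equal(ir2$n_pairs, 2L)        # both consecutive pairs count
  # i.i.d. genome: no significant spacing gradient expected
  g3 <- genome("ir3", random_seq(2e5, seed = 58))
  m3 <- replichore_map(0, 1e5, 2e5)
  ir3 <- inverted_repeat_spacing(g3, m3, k = 5)
  expect_gt(ir3$regression$p, 0.01)
})

test_that("operon gradients detect planted trends and degenerate inputs", {
  m <- replichore_map(0, 5e5, 1e6)
  ops_same <- data.frame(start = seq(1e3, 4.9e5, by = 5e3))
  ops_same$end <- ops_same$start + 3000
  ops_same$n_genes <- 3
  og <- operon_gradient(map = m, operons = ops_same)
  expect_equal(og$length_regression$slope, 0)
  # planted length gradient: longer operons near the terminus
  set.seed(59)
  d <- runif(300, 0, 50)
  starts <- (m$ter + d / 100 * 1e6) %% 1e6
  lens <- pmax(500, 6000 - 100 * d + rnorm(300, 0, 200))
  ops <- data.frame(start = starts, end = starts + lens,
                    n_genes = pmax(1, round(lens / 1000)))
  og2 <- operon_gradient(map = m, operons = ops)
  expect_lt(og2$length_regression$p, 0.05)
  expect_lt(og2$length_regression$slope, 0)
  expect_error(operon_gradient(map = m, operons = ops[0, ]), "empty")
  # derivation from same-strand gene runs
  ft <- gene_features(sprintf("g%d", 1:6),
                      c(0L, 940L, 1880L, 5000L, 5945L, 9000L),
                      c(900L, 1840L, 2780L, 5900L, 6850L, 9900L),
                      c(1L, 1L, 1L, -1L, -1L, 1L))
  og3 <- operon_gradient(ft, m, max_gap_bp = 50)
  expect_equal(nrow(og3$operons), 3L)
  expect_equal(og3$operons$n_genes, c(3, 2, 1))
})

test_that("NG86 synonymous distance matches hand-worked site counts", {
  expect_equal(ks_ng86("ATGAAA", "ATGAAA")$ks, 0)
  # TTA vs TTG: single synonymous third-position difference; each codon
  # has 2/3 synonymous sites (pos 1: 1/3 via CTA/CTG; pos 3: 1/3;
  # stop-avoiding pathways only), so pS = 1 / (2/3) saturates
  r <- ks_ng86("TTA", "TTG")
  expect_equal(r$syn_sites, 2 / 3, tolerance = 1e-12)
  expect_equal(r$syn_diffs, 1)
  expect_true(r$ps >= 0.75)
  expect_true(is.na(r$ks))
  # diluted with invariant codons the Jukes-Cantor correction applies:
  # GGG has 1 synonymous site (4-fold third position)
  a <- paste0("TTA", strrep("GGG", 9))
  b <- paste0("TTG", strrep("GGG", 9))
  r2 <- ks_ng86(a, b)
  S <- 2 / 3 + 9 * 1
  ps <- 1 / S
  expect_equal(r2$syn_sites, S, tolerance = 1e-12)
  expect_equal(r2$ps, ps, tolerance = 1e-12)
  expect_equal(r2$ks, -0.75 * log(1 - 4 * ps / 3), tolerance = 1e-12)
  expect_false(r2$saturated)
  # symmetry
  r3 <- ks_ng86(b, a)
  expect_equal(r2$ks, r3$ks, tolerance = 1e-15)
  # gap codons are skipped
  r4 <- ks_ng86(paste0("T-A", strrep("GGG", 3)), paste0("TTG", strrep("GGG", 3)))
  expect_equal(r4$syn_sites, 3)
})

test_that("regression helper holds its nominal type-I error on null data", {
  set.seed(60)
  hits <- 0; reps <- 400
  for (i in seq_len(reps)) {
    x <- runif(30); y <- rnorm(30)
    if (aimsarch:::regression_summary(x, y)$p < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
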