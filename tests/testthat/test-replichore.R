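test_that("pentamer profiles match brute-force enumeration and normalize", {
  g <- genome("t", paste0(strrep("A", 7), random_seq(200, seed = 2)),
              circular = FALSE)
  ft <- gene_features(c("g1", "g2"), c(0L, 10L), c(7L, 100L), c(1L, 1L))
  pr <- pentamer_profile(ft, g, pseudocount = 0)
  # raw counts: oracle over both genes pooled
  oracle <- naive_pentamer_counts(substr(as.character(g$sequence), 1, 7))
  o2 <- naive_pentamer_counts(substr(as.character(g$sequence), 11, 100))
  for (k in names(o2)) oracle[[k]] <- (oracle[[k]] %||% 0) + o2[[k]]
  cnt <- pr$counts$all
  # check a handful of keys incl. the AAAAA runs
  for (key in names(oracle)) {
    fr <- as.integer(substr(key, 1, 1))
    pent <- substr(key, 3, 7)
    code <- sum((match(strsplit(pent, "")[[1]], c("A", "C", "G", "T")) - 1) *
                  4^(4:0))
    expect_equal(unname(cnt[fr * 1024 + code + 1]), oracle[[key]],
                 info = key)
  }
  # single gene AAAAAAA: P(A|AAAA) = 1 at every frame before smoothing
  pr1 <- pentamer_profile(ft[1, ], g, pseudocount = 0)
  f <- pr1$f$all
  expect_equal(f[1, 1, 1], 1)  # base A given tetramer AAAA, frame 0
  # with smoothing each conditional sums to 1 over bases
  prs <- pentamer_profile(ft, g, pseudocount = 1)
  sums <- apply(prs$f$all, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("genes shorter than a pentamer warn and contribute nothing", {
  g <- genome("t", random_seq(100, seed = 3), circular = FALSE)
  ft <- gene_features(c("s", "n"), c(0L, 10L), c(4L, 60L), c(1L, 1L))
  expect_warning(pr <- pentamer_profile(ft, g, pseudocount = 0),
                 "shorter than 5")
  pr2 <- suppressWarnings(pentamer_profile(ft, g, pseudocount = 0))
  pr3 <- pentamer_profile(ft[2, , drop = FALSE], g, pseudocount = 0)
  expect_equal(pr2$counts$all, pr3$counts$all)
})

test_that("delta is nonnegative, zero iff identical, and label-symmetric", {
  g <- genome("t", random_seq(4000, seed = 4), circular = FALSE)
  ft <- gene_features(sprintf("g%d", 1:8), (0:7) * 500L,
                      (0:7) * 500L + 450L, rep(1L, 8))
  lead <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  pr <- pentamer_profile(ft, g, leading = lead)
  expect_gte(delta_score(pr), 0)
  prsw <- pentamer_profile(ft, g, leading = !lead)
  expect_equal(delta_score(pr), delta_score(prsw), tolerance = 1e-12)
  # identical gene sets in both classes: delta 0 via equal counts
  ft2 <- rbind(ft, ft)
  ft2$gene_id <- sprintf("g%d", 1:16)
  pr0 <- pentamer_profile(ft2, g, leading = rep(c(TRUE, FALSE), each = 8))
  expect_equal(delta_score(pr0), 0, tolerance = 1e-12)
  expect_error(pentamer_profile(ft, g, leading = rep(TRUE, 8)),
               "strand class")
})

test_that("planted composition switch is recovered within 1% of genome length", {
  spec <- plant_spec(length = 4e5, ori = 1e5, ter = 3e5)
  fix <- generate_genome(spec, seed = 31)
  map <- find_breakpoints(fix$genome, fix$features)
  L <- fix$genome$length
  err <- function(a, b) min((a - b) %% L, (b - a) %% L) / L * 100
  expect_lt(err(map$ori, spec$ori), 1)
  expect_lt(err(map$ter, spec$ter), 1)
  expect_equal(map$confidence, "ok")
  expect_gte(map$delta, 0)
})

test_that("a genome with no replichore signal is flagged low-confidence", {
  spec <- plant_spec(length = 4e5, pentamer_effect = 0,
                     leading_fraction = 0.5)
  fix <- generate_genome(spec, seed = 32)
  map <- find_breakpoints(fix$genome, fix$features)
  expect_equal(map$confidence, "low")
})

test_that("origin labelling maximizes genes transcribed away from it", {
  # all genes on each arm pointing away from position 0
  L <- 10000L
  starts <- seq(200L, 9000L, by = 1000L)
  strand <- ifelse(starts + 400 < 5000, 1L, -1L)  # away from 0, ter at 5000
  ft <- gene_features(sprintf("g%d", seq_along(starts)), starts,
                      starts + 800L, strand)
  m <- replichore_map(5000, 0, L)  # deliberately mislabelled
  m2 <- classify_ori_ter(m, ft)
  expect_equal(m2$ori, 0)
  expect_equal(m2$ter, 5000)
  # 60/40 majority
  strand2 <- strand
  strand2[c(1, 3)] <- -strand2[c(1, 3)]
  ft2 <- gene_features(ft$gene_id, ft$start, ft$end, strand2)
  expect_equal(classify_ori_ter(m, ft2)$ori, 0)
  # forced exact tie: half away from each breakpoint
  ft3 <- gene_features(sprintf("h%d", 1:8),
                       c(seq(200, 3200, 1000), seq(5200, 8200, 1000)),
                       c(seq(200, 3200, 1000), seq(5200, 8200, 1000)) + 800L,
                       c(1L, 1L, -1L, -1L, 1L, 1L, -1L, -1L))
  m3 <- classify_ori_ter(replichore_map(0, 5000, L), ft3)
  expect_equal(m3$confidence, "ambiguous")
})

test_that("IUPAC motif scan matches a naive oracle and finds dif instances", {
  inst <- "ACTTCGCATAATGTATATTATGTTAAAT"   # R->A, N->C, K->T
  g <- genome("d", paste0(random_seq(300, seed = 5), inst,
                          random_seq(200, seed = 6)))
  h <- find_motif(g, DIF_CONSENSUS)
  expect_true(any(h$pos == 300 & h$strand == 1))
  grc <- genome("drc", paste0(random_seq(100, seed = 7), revcomp_chr(inst),
                              random_seq(50, seed = 8)))
  hrc <- find_motif(grc, DIF_CONSENSUS)
  expect_true(any(hrc$pos == 100 & hrc$strand == -1))
  # random-sequence scan equals the brute-force oracle
  s <- random_seq(3000, seed = 9)
  gg <- genome("r", s)
  for (pat in c("ACGT", "RNTK", "AGNATGTT")) {
    got <- find_motif(gg, pat)
    want <- naive_motif_scan(s, pat, circular = TRUE)
    got_k <- sort(paste(got$pos, got$strand))
    want_k <- sort(paste(want$pos, want$strand))
    expect_identical(got_k, want_k, label = pat)
  }
  # mismatch tolerance agrees with the oracle too
  got1 <- find_motif(gg, "ACGTACGT", max_mismatch = 1)
  want1 <- naive_motif_scan(s, "ACGTACGT", max_mismatch = 1, circular = TRUE)
  expect_identical(sort(paste(got1$pos, got1$strand)),
                   sort(paste(want1$pos, want1$strand)))
  # longer consensus than the genome is an empty result with warning
  expect_warning(h0 <- find_motif(genome("s", "ACGT"), strrep("A", 10)),
                 "longer than genome")
  expect_equal(nrow(h0), 0L)
})

test_that("terminus validation reports the nearest dif hit", {
  m <- replichore_map(0, 2e6, 4e6)
  expect_equal(validate_terminus(m, data.frame(pos = 2e6))$offset_bp, 0)
  r <- validate_terminus(m, data.frame(pos = 2e6 + 40000))
  expect_equal(r$offset_pct, 1.0)
  hits <- data.frame(pos = c(100, 1.99e6, 2.5e6, 3.9e6))
  r2 <- validate_terminus(m, hits)
  L <- 4e6
  dists <- pmin((hits$pos - 2e6) %% L, (2e6 - hits$pos) %% L)
  expect_equal(r2$offset_bp, min(dists))
  expect_equal(r2$nearest, hits$pos[which.min(dists)])
  expect_equal(validate_terminus(m, NULL)$status, "no dif found")
})

test_that("GC-skew diagnostic locates a planted skew switch approximately", {
  set.seed(10)
  half <- 2e5
  s1 <- paste(sample(c("A", "T", "G", "C"), half, TRUE,
                     prob = c(0.25, 0.25, 0.3, 0.2)), collapse = "")
  s2 <- paste(sample(c("A", "T", "G", "C"), half, TRUE,
                     prob = c(0.25, 0.25, 0.2, 0.3)), collapse = "")
  g <- genome("sk", paste0(s1, s2))
  sk <- gc_skew(g, window = 10000)
  # cumulative skew peaks near the composition switch at `half`
  expect_lt(abs(sk$ter - half) / (2 * half), 0.1)
})
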