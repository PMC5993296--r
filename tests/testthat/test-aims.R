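test_that("backbone excision removes and merges insertion spans", {
  g <- genome("b", random_seq(10000, seed = 14), circular = FALSE)
  none <- backbone_genome(g, NULL)
  expect_equal(as.character(none$genome$sequence), as.character(g$sequence))
  one <- backbone_genome(g, data.frame(start = 4000, end = 5000))
  expect_equal(one$genome$length, 9000)
  expect_equal(one$removed_bp, 1000)
  s <- as.character(g$sequence)
  expect_equal(as.character(one$genome$sequence),
               paste0(substr(s, 1, 4000), substr(s, 5001, 10000)))
  adj <- backbone_genome(g, data.frame(start = c(100, 200),
                                       end = c(200, 300)))
  expect_equal(adj$genome$length, 9800)
  expect_equal(adj$removed_bp, 200)
  expect_warning(backbone_genome(g, data.frame(start = c(100, 150),
                                               end = c(250, 400))),
                 "overlapping")
})

test_that("arm shuffling is seed-reproducible and count-preserving", {
  tm <- tiny_map_genome(160000, seed = 15)
  g1 <- shuffle_arms(tm$genome, tm$map, segment_bp = 10000, seed = 99)
  g2 <- shuffle_arms(tm$genome, tm$map, segment_bp = 10000, seed = 99)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_false(identical(as.character(g1$sequence),
                         as.character(tm$genome$sequence)))
  expect_equal(g1$length, tm$genome$length)
  # per-strand counts preserved up to <= 7 windows per segment junction
  n_junctions <- 2 * (160000 / 2 / 10000)
  for (w in c("ACGTAC", "GGCC", "ACGTACGT")) {
    before <- count_octamer(tm$genome, tm$map, w)
    after <- count_octamer(g1, tm$map, w)
    expect_lte(abs(before$n_leading - after$n_leading), n_junctions * 7)
    expect_lte(abs(before$n_lagging - after$n_lagging), n_junctions * 7)
  }
  w <- testthat::capture_warnings(
    shuffle_arms(tm$genome, tm$map, segment_bp = 100000))
  expect_true(all(grepl("left intact", w)))   # one warning per short arm
  expect_length(w, 2L)
})

test_that("planted gradient octamers are identified and stringency is monotone", {
  plants <- gradient_aims_plants(n = 6, a_ori = 0.9, a_ter = 3.6, seed = 8)
  fix <- generate_genome(plant_spec(length = 8e5, aims_plants = plants),
                         seed = 16)
  tab <- aims_count_tables(fix$genome, fix$map)
  aims <- identify_aims(fix$genome, fix$map, n_null = 2, seed = 3,
                        tables = tab)
  expect_gte(sum(plants$octamer %in% aims$octamers$octamer), 5)
  expect_true(all(aims$octamers$bias >= 0.70))
  expect_true(all(aims$octamers$n_i >= 96))
  expect_true(all(aims$octamers$ter_increase >= 0.5 - 1e-9))
  expect_true(all(aims$octamers$ter_bias > aims$octamers$ori_bias))
  expect_true(all(nchar(aims$octamers$octamer) == 8))
  # monotone stringency on each threshold
  base <- aimsarch:::aims_default_params()
  n0 <- aimsarch:::scan_degenerate_space(tab, base, collect = FALSE)
  for (chg in list(list(min_bias = 0.8), list(min_copies = 200),
                   list(min_ter_increase = 1.5))) {
    p <- utils::modifyList(base, chg)
    expect_lte(aimsarch:::scan_degenerate_space(tab, p, collect = FALSE), n0)
  }
  # degeneracy restriction yields a subset
  pn <- utils::modifyList(base, list(alphabet = "N"))
  expect_lte(aimsarch:::scan_degenerate_space(tab, pn, collect = FALSE), n0)
})

test_that("threshold calibration selects a qualifying operating point", {
  plants <- gradient_aims_plants(n = 6, a_ori = 0.9, a_ter = 3.6, seed = 9)
  fix <- generate_genome(plant_spec(length = 8e5, aims_plants = plants),
                         seed = 17)
  cal <- calibrate_thresholds(fix$genome, fix$map,
                              ter_increase_grid = c(0.5, 1),
                              bias_grid = 0.70, min_genuine = 50,
                              n_null = 2, seed = 5)
  expect_false(is.null(cal$chosen))
  expect_gte(cal$chosen$fold, 10)
  # genuine count non-increasing with stringency
  tabm <- cal$table[order(cal$table$min_ter_increase), ]
  expect_true(all(diff(tabm$genuine) <= 0))
  # a gradient-free genome yields no qualifying point
  flat <- generate_genome(plant_spec(length = 6e5), seed = 18)
  cal0 <- calibrate_thresholds(flat$genome, flat$map,
                               ter_increase_grid = 0.5, bias_grid = 0.70,
                               min_genuine = 10, n_null = 2, seed = 6)
  expect_null(cal0$chosen)
})

test_that("AIMS clustering groups overlapping octamers order-independently", {
  expect_equal(cluster_aims(c("GGGCAGGG", "GGCAGGGN", "TTTTAAAA")),
               c(1, 1, 2))
  expect_equal(max(cluster_aims(c("ACGTACGT", "GGGGGGGG"))), 2)
  set.seed(19)
  octs <- c("ACGTACGT", "CGTACGTN", "NACGTACG", "TTGGCCAA", "TGGCCAAN")
  base <- cluster_aims(octs)
  for (i in 1:5) {
    p <- sample(length(octs))
    permuted <- cluster_aims(octs[p])
    # same partition under permutation
    expect_equal(outer(permuted, permuted, "=="),
                 outer(base[p], base[p], "=="))
  }
  # equivalence with the pairwise linkage oracle on small sets
  pairs_oracle <- function(octs) {
    n <- length(octs)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      aimsarch:::aims_linked(octs[i], octs[j])))
    # transitive closure
    reach <- adj | diag(n)
    for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
    apply(reach, 1, function(r) min(which(r)))
  }
  for (seedi in 20:23) {
    oct_rand <- withr_seed(seedi, replicate(6, paste(
      sample(c("A", "C", "G", "T", "N", "R"), 8, TRUE), collapse = "")))
    got <- cluster_aims(oct_rand)
    want <- pairs_oracle(oct_rand)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="),
                 info = paste(oct_rand, collapse = " "))
  }
})

test_that("family representatives pick the most abundant member", {
  fake <- structure(list(octamers = data.frame(
    octamer = c("ACGTACGT", "ACGTACGN", "GGGGCCCC"),
    n_i = c(100, 150, 120), bias = c(0.8, 0.75, 0.9),
    ter_increase = 1, ter_bias = 0.9, ori_bias = 0.7, n_deg = c(0, 1, 0)),
    genome_id = "x", params = list(), null_counts = integer(0),
    fold = NA), class = "aims_set")
  reps <- aims_representatives(fake)
  expect_equal(nrow(reps), 2)
  expect_true("ACGTACGN" %in% reps$octamer)  # larger N_i in its family
  expect_true("GGGGCCCC" %in% reps$octamer)
})

test_that("AIMS sets round-trip through JSON", {
  fake <- structure(list(octamers = data.frame(
    octamer = c("ACGTACGT", "NNGGCCTT"), n_i = c(120, 98),
    bias = c(0.81, 0.72), ter_increase = c(1.2, 0.9),
    ter_bias = c(0.9, 0.8), ori_bias = c(0.7, 0.72), n_deg = c(0L, 2L)),
    params = aimsarch:::aims_default_params(), genome_id = "gX",
    null_counts = c(1L, 0L, 2L), null_mean = 1, fold = 2,
    zero_null_flag = FALSE), class = "aims_set")
  p <- tempfile(fileext = ".json")
  write_aims_set(fake, p)
  back <- read_aims_set(p)
  expect_equal(back$octamers$octamer, fake$octamers$octamer)
  expect_equal(back$octamers$n_i, fake$octamers$n_i)
  expect_equal(back$genome_id, "gX")
  expect_equal(back$null_counts, c(1L, 0L, 2L))
  unlink(p)
})
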