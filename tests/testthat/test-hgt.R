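mk_homology <- function(query, subject_genome, subject_gene, sim, rb = TRUE)
  data.frame(query_gene = query, subject_genome = subject_genome,
             subject_gene = subject_gene, similarity = sim, coverage = 95,
             reciprocal_best = rb, stringsAsFactors = FALSE)

test_that("the foreign-gene filter applies absence and similarity rules", {
  ft <- gene_features(c("g1", "g2", "g3", "g4", "g5"),
                      (0:4) * 1000L, (0:4) * 1000L + 900L, rep(1L, 5))
  m <- replichore_map(9000, 4500, 10000)
  hom <- rbind(
    # g1 native everywhere
    mk_homology("g1", c("sis", "s1", "s2", "s3"), "o1", 95),
    # g2 absent in sister, but present in one of three strains: native
    mk_homology("g2", "sis", NA, 0, FALSE),
    mk_homology("g2", "s1", "o2", 90),
    mk_homology("g2", c("s2", "s3"), NA, 0, FALSE),
    # g3 absent everywhere, best conspecific similarity 30: foreign
    mk_homology("g3", "sis", NA, 0, FALSE),
    mk_homology("g3", "s1", "w1", 30, FALSE),
    mk_homology("g3", c("s2", "s3"), NA, 0, FALSE),
    # g4 absent everywhere, no conspecific hit at all: foreign
    mk_homology("g4", c("sis", "s1", "s2", "s3"), NA, 0, FALSE),
    # g5 absent everywhere but conspecific homologue at 55%: native
    mk_homology("g5", "sis", NA, 0, FALSE),
    mk_homology("g5", "s1", "w2", 55, FALSE),
    mk_homology("g5", c("s2", "s3"), NA, 0, FALSE))
  ins <- call_insertions(ft, hom, "sis", c("s1", "s2", "s3"), m)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$genes, "g3,g4")     # consecutive foreigners merge
  expect_equal(ins$n_genes, 2L)
  expect_equal(ins$start, 2000)
  expect_equal(ins$end, 3900)
  expect_error(call_insertions(ft, hom, "missing_sp", c("s1", "s2"), m),
               "absent from homology")
})

test_that("three consecutive foreign genes merge into one insertion", {
  ft <- gene_features(sprintf("g%d", 1:5), (0:4) * 1000L,
                      (0:4) * 1000L + 900L, rep(1L, 5))
  m <- replichore_map(9000, 4500, 10000)
  hom <- rbind(
    mk_homology(c("g1", "g5"), "sis", "x", 95),
    mk_homology(c("g1", "g5"), "s1", "x", 95),
    mk_homology(c("g1", "g5"), "s2", "x", 95),
    mk_homology(c("g2", "g3", "g4"), "sis", NA, 0, FALSE),
    mk_homology(c("g2", "g3", "g4"), "s1", NA, 0, FALSE),
    mk_homology(c("g2", "g3", "g4"), "s2", NA, 0, FALSE))
  ins <- call_insertions(ft, hom, "sis", c("s1", "s2"), m)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$n_genes, 3L)
  expect_equal(ins$length_bp, 2900)
})

test_that("permissive fractions match a naive per-occurrence enumeration", {
  tm <- tiny_map_genome(20000, seed = 21)
  s <- as.character(tm$genome$sequence)
  aims <- c("ACGTACGT", "GGNACCTT")
  span <- c(3000, 9000)
  got <- span_permissive_fraction(tm$genome, tm$map, aims, span)
  want_l <- 0; want_g <- 0
  for (w in aims) {
    o <- naive_octamer_count(s, tm$map, w, region = span)
    want_l <- want_l + o$n_leading; want_g <- want_g + o$n_lagging
  }
  expect_equal(got$n_permissive, want_l)
  expect_equal(got$n_nonpermissive, want_g)
  if (want_l + want_g > 0)
    expect_equal(got$value, want_l / (want_l + want_g))
  # simple arithmetic checks
  expect_equal(permissive_fraction(4, 1)$value, 0.8)
  expect_equal(permissive_fraction(7, 0)$value, 1.0)
})

test_that("permissive fraction is invariant under full reverse complement", {
  plants <- gradient_aims_plants(n = 3, a_ori = 2, a_ter = 4, seed = 22)
  fix <- generate_genome(plant_spec(length = 1e5, aims_plants = plants),
                         seed = 23)
  span <- c(10000, 30000)
  f1 <- span_permissive_fraction(fix$genome, fix$map, plants$octamer, span)
  # reverse complement the genome; the map flips coherently
  L <- fix$genome$length
  grc <- genome("rc", revcomp_chr(as.character(fix$genome$sequence)))
  mrc <- replichore_map((L - fix$map$ori) %% L, (L - fix$map$ter) %% L, L)
  span_rc <- c(L - span[2], L - span[1])
  f2 <- span_permissive_fraction(grc, mrc, plants$octamer, span_rc)
  expect_equal(f1$n_permissive, f2$n_permissive)
  expect_equal(f1$value, f2$value)
})

test_that("the exponential bias curve recovers exact and noisy parameters", {
  mkins <- function(d, pf, len = 1000)
    data.frame(start = 0, end = len, genes = "x", n_genes = 1,
               length_bp = len, midpoint_pct = d, permissive_fraction = pf)
  # exact model evaluated at bin midpoints: near-exact recovery
  d <- seq(1, 49, by = 2)
  ins <- mkins(d, 0.3 * exp(-d / 10) + 0.55)
  bc <- bias_curve(ins)
  expect_equal(bc$a, 0.3, tolerance = 1e-6)
  expect_equal(bc$b, 10, tolerance = 1e-5)
  expect_equal(bc$c, 0.55, tolerance = 1e-6)
  expect_gt(bc$r_squared, 0.999999)
  # binomial sampling noise: recovery within 3 SE-scale tolerance
  set.seed(24)
  d2 <- runif(2000, 0, 50)
  p2 <- 0.3 * exp(-d2 / 10) + 0.55
  obs <- rbinom(2000, 50, p2) / 50
  bc2 <- bias_curve(mkins(d2, obs))
  expect_equal(bc2$a, 0.3, tolerance = 0.1)
  expect_equal(bc2$c, 0.55, tolerance = 0.03)
  expect_gt(bc2$b, 5); expect_lt(bc2$b, 20)
  # constant input: flat curve, no spurious decay
  bc3 <- bias_curve(mkins(d, rep(0.7, length(d))))
  expect_equal(bc3$c + bc3$a * mean(exp(-d / bc3$b)), 0.7, tolerance = 0.02)
  expect_true(is.na(bc3$r_squared) || bc3$r_squared < 1)
  # minimum-span filter drops short insertions
  ins4 <- rbind(mkins(10, 0.9, len = 500), mkins(30, 0.6, len = 5000))
  bc4 <- bias_curve(ins4, min_span_bp = 1000)
  expect_equal(sum(bc4$bins$n), 1L)
})

test_that("loss estimator matches hand-worked and closed-form cases", {
  mkins <- function(d, pf, len)
    data.frame(start = 0, end = len, genes = "x", n_genes = 1,
               length_bp = len, midpoint_pct = d, permissive_fraction = pf)
  # identical windows: zero loss
  same <- rbind(mkins(3, c(0.6, 0.9), 100), mkins(45, c(0.6, 0.9), 100))
  expect_equal(loss_fraction(same)$loss, 0)
  # hand example: origin {0.5, 1.0} equal lengths, terminus {1.0}
  ex <- rbind(mkins(45, 0.5, 100), mkins(45, 1.0, 100), mkins(3, 1.0, 50))
  expect_equal(loss_fraction(ex)$loss, 0.25)
  # antisymmetry under swapping windows
  lf <- loss_fraction(ex)
  lr <- loss_fraction(ex, ter_window = c(42, 48), ori_window = c(0, 6))
  expect_equal(lf$loss, -lr$loss)
  expect_error(loss_fraction(ex[ex$midpoint_pct > 40, ]), "empty window")
  # loss equals the area difference of the cumulative-length curves
  set.seed(25)
  pop_t <- mkins(rep(3, 60), runif(60, 0.4, 1), sample(500:2000, 60, TRUE))
  pop_o <- mkins(rep(45, 80), runif(80, 0.3, 1), sample(500:2000, 80, TRUE))
  both <- rbind(pop_t, pop_o)
  lf2 <- loss_fraction(both)
  s <- seq(0, 1, by = 1e-3)
  Ft <- cumulative_length_curve(pop_t, s)
  Fo <- cumulative_length_curve(pop_o, s)
  area_diff <- sum(Fo$F - Ft$F) * 1e-3
  expect_equal(lf2$loss, area_diff, tolerance = 2e-3)
})

test_that("planted-deletion experiment reproduces the truncation closed form", {
  set.seed(26)
  n <- 10000
  q <- 0.8
  pf <- runif(n, 0.3, 1)
  len <- sample(500:2000, n, replace = TRUE)
  keep <- runif(n) >= (1 - pf) * q       # terminus-window survival
  mk <- function(d, pfv, lenv)
    data.frame(start = 0, end = lenv, genes = "x", n_genes = 1,
               length_bp = lenv, midpoint_pct = d,
               permissive_fraction = pfv)
  ins <- rbind(mk(45, pf, len), mk(3, pf[keep], len[keep]))
  got <- loss_fraction(ins)$loss
  # closed form: E[w p (1-(1-p)q)] / E[w (1-(1-p)q)] - E[w p] / E[w]
  # with p, w independent; evaluate by population averages
  surv <- 1 - (1 - pf) * q
  want <- sum(len * pf * surv) / sum(len * surv) - sum(len * pf) / sum(len)
  expect_lt(abs(got - want), 0.01)
  expect_lt(loss_fraction(ins)$ks_p, 1e-6)
})
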