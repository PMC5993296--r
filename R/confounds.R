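# Alternative-hypothesis controls: codon-usage-bias gradients,
# inverted-repeat spacing gradients, operon-length gradients, and a
# synonymous-divergence (Ks) age proxy.

split_codons <- function(seq_chr) {
  n <- nchar(seq_chr) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq_chr, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

GENETIC_CODE_TABLE <- function() Biostrings::GENETIC_CODE

# --- codon usage metrics ----------------------------------------------------

# Wright's effective number of codons (ENC); genes using one codon per
# amino acid give 20, uniform usage gives 61.
enc_wright <- function(codons) {
  gc <- GENETIC_CODE_TABLE()
  codons <- codons[codons %in% names(gc) & gc[codons] != "*"]
  aa <- gc[codons]
  fam <- split(codons, aa)
  # F per amino-acid family with >1 observation
  degs <- vapply(names(fam), function(a) sum(gc == a & gc != "*"), numeric(1))
  Fhat <- vapply(seq_along(fam), function(i) {
    x <- table(fam[[i]]); n <- sum(x)
    if (n < 2L) return(NA_real_)
    (n * sum((x / n)^2) - 1) / (n - 1)
  }, numeric(1))
  names(Fhat) <- names(fam)
  avg <- function(d) {
    f <- Fhat[degs == d & !is.na(Fhat) & Fhat > 0]
    if (length(f) == 0L) NA_real_ else mean(f)
  }
  F2 <- avg(2); F3 <- avg(3); F4 <- avg(4); F6 <- avg(6)
  if (is.na(F3)) F3 <- if (!is.na(F2) && !is.na(F4)) (F2 + F4) / 2 else F2
  if (any(is.na(c(F2, F4, F6)))) {
    miss <- c(F2 = F2, F4 = F4, F6 = F6)
    repl <- mean(miss, na.rm = TRUE)
    if (is.na(F2)) F2 <- repl; if (is.na(F4)) F4 <- repl
    if (is.na(F6)) F6 <- repl
  }
  enc <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(enc, 61)
}

# sum of absolute deviations of a gene's synonymous codon frequencies
# from genome-wide synonymous frequencies
codon_deviation <- function(codons, genome_freq) {
  gc <- GENETIC_CODE_TABLE()
  codons <- codons[codons %in% names(gc) & gc[codons] != "*"]
  if (length(codons) == 0L) return(NA_real_)
  aa <- gc[codons]
  dev <- 0; used <- 0
  for (a in unique(aa)) {
    syn <- names(gc)[gc == a]
    if (length(syn) < 2L) next
    cnt <- table(factor(codons[aa == a], levels = syn))
    p <- cnt / sum(cnt)
    q <- genome_freq[syn]; q <- q / sum(q)
    dev <- dev + sum(abs(p - q)); used <- used + 1
  }
  if (used == 0L) NA_real_ else dev / used
}

gc3_skew <- function(codons) {
  third <- substr(codons, 3, 3)
  g <- sum(third == "G" | third == "C")
  length3 <- length(third)
  if (length3 == 0L) return(NA_real_)
  g / length3
}

# Euclidean distance between gene and genome relative synonymous codon
# usage vectors
rscu_distance <- function(codons, genome_rscu) {
  r <- rscu_vector(codons)
  ok <- !is.na(r) & !is.na(genome_rscu)
  if (!any(ok)) return(NA_real_)
  sqrt(sum((r[ok] - genome_rscu[ok])^2))
}

rscu_vector <- function(codons) {
  gc <- GENETIC_CODE_TABLE()
  sense <- names(gc)[gc != "*"]
  codons <- codons[codons %in% sense]
  cnt <- table(factor(codons, levels = sense))
  out <- rep(NA_real_, length(sense)); names(out) <- sense
  for (a in unique(gc[sense])) {
    syn <- sense[gc[sense] == a]
    tot <- sum(cnt[syn])
    if (tot == 0) next
    out[syn] <- as.numeric(cnt[syn]) * length(syn) / tot
  }
  out
}

#' Codon-usage-bias gradients along the chromosome
#'
#' Computes per-gene codon bias under four standard metrics (effective
#' number of codons; mean absolute deviation of synonymous codon
#' frequencies from the genome-wide frequencies; GC3 content; Euclidean
#' RSCU distance from the genome profile) and regresses each against
#' the gene's distance from the replication terminus. Genes with
#' internal stop codons are excluded with a warning. Significance is
#' reported, never asserted.
#'
#' @param features CDS [gene_features].
#' @param genome A [genome].
#' @param map A [replichore_map].
#' @param metrics Subset of `c("enc", "deviation", "gc3", "rscu")`.
#' @return List per metric with `slope`, `intercept`, `r`, `p`,
#'   `n_genes`, plus the per-gene table.
#' @export
codon_bias_gradient <- function(features, genome, map,
                                metrics = c("enc", "deviation", "gc3",
                                            "rscu")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  features <- features[features$kind == "CDS", , drop = FALSE]
  gc <- GENETIC_CODE_TABLE()
  seqs <- lapply(seq_len(nrow(features)), function(i)
    coding_seq(genome, features$start[i], features$end[i],
               features$strand[i]))
  codlist <- lapply(seqs, split_codons)
  internal_stop <- vapply(codlist, function(cd) {
    cd2 <- cd[cd %in% names(gc)]
    body <- head(cd2, -1L)
    any(gc[body] == "*")
  }, logical(1))
  if (any(internal_stop))
    warning(sum(internal_stop), " gene(s) with internal stops excluded")
  keep <- !internal_stop
  codlist <- lapply(codlist[keep], function(cd) {
    cd <- cd[cd %in% names(gc)]
    if (length(cd) && gc[cd[length(cd)]] == "*") cd <- head(cd, -1L)
    cd
  })
  f <- features[keep, , drop = FALSE]
  dist <- distance_from_terminus(((f$start + f$end) / 2) %% map$length, map)
  allcod <- unlist(codlist)
  sense <- names(gc)[gc != "*"]
  gfreq <- table(factor(allcod[allcod %in% sense], levels = sense))
  gfreq <- as.numeric(gfreq); names(gfreq) <- sense
  grscu <- rscu_vector(allcod)
  compute <- list(
    enc = function(cd) enc_wright(cd),
    deviation = function(cd) codon_deviation(cd, gfreq),
    gc3 = function(cd) gc3_skew(cd),
    rscu = function(cd) rscu_distance(cd, grscu))
  pergene <- data.frame(gene_id = f$gene_id, dist_pct = dist)
  out <- list()
  for (m in metrics) {
    v <- vapply(codlist, compute[[m]], numeric(1))
    pergene[[m]] <- v
    ok <- !is.na(v)
    out[[m]] <- regression_summary(dist[ok], v[ok])
  }
  out$per_gene <- pergene
  out
}

regression_summary <- function(x, y) {
  if (length(x) >= 3L && stats::sd(x) > 0 && stats::sd(y) == 0)
    return(list(slope = 0, intercept = y[1], r = NA_real_,
                p = NA_real_, n = length(x)))
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  ct <- suppressWarnings(stats::cor.test(x, y))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Inverted-repeat spacing gradient
#'
#' For each k-mer, occurrences of the k-mer and its reverse complement
#' on an arm's Watson strand are merged in positional order; each
#' consecutive pair in opposite orientations forms an "inverted pair"
#' whose spacing is their separation. (A palindromic k-mer is its own
#' reverse complement, so all of its consecutive occurrence pairs
#' count.) Mean spacing per window is regressed against the window's
#' distance from the terminus.
#'
#' @param genome A [genome].
#' @param map A [replichore_map].
#' @param k K-mer size (5, 6 or 7).
#' @param window_bp Window size (default 10000).
#' @return List with the regression summary and the per-window table.
#' @export
inverted_repeat_spacing <- function(genome, map, k = 5, window_bp = 10000) {
  stopifnot(k %in% 5:7)
  arms <- arm_intervals(map)
  rows <- list()
  for (an in c("arm1", "arm2")) {
    iv <- arms[[an]]
    s <- as.character(genome_subseq(genome, iv[1] %% map$length, iv[2]))
    n <- nchar(s)
    if (n < 3L * window_bp) next
    b <- base_codes(s)
    np <- n - k + 1L
    code <- b[1:np]
    for (j in 2:k) code <- code * 4L + b[j:(np + j - 1L)]
    valid <- !is.na(code)
    pos <- which(valid); code <- code[valid]
    # canonical pair id and orientation
    rccode <- revcomp_code(code, k)
    canon <- pmin(code, rccode)
    orient <- code <= rccode             # TRUE = "forward" member
    o <- order(canon, pos)
    cs <- canon[o]; ps <- pos[o]; os <- orient[o]
    samegrp <- c(FALSE, cs[-1] == cs[-length(cs)])
    inv_pair <- samegrp & (os != c(FALSE, os[-length(os)]) |
                             cs == rccode[o])  # palindromes: all pairs
    spacing <- ps - c(0L, ps[-length(ps)])
    midpt <- (ps + c(0L, ps[-length(ps)])) / 2
    sel <- which(inv_pair)
    if (length(sel) == 0L) next
    # distance of the pair midpoint from the terminus
    gpos <- (iv[1] + midpt[sel] - 1) %% map$length
    rows[[an]] <- data.frame(spacing = spacing[sel],
                             dist_pct = distance_from_terminus(gpos, map))
  }
  if (length(rows) == 0L) stop("arms too short for windowed regression")
  dat <- do.call(rbind, rows)
  wpct <- 100 * window_bp / map$length
  dat$win <- floor(dat$dist_pct / wpct)
  agg <- stats::aggregate(spacing ~ win, data = dat, FUN = mean)
  agg$dist_pct <- (agg$win + 0.5) * wpct
  list(regression = regression_summary(agg$dist_pct, agg$spacing),
       windows = agg[, c("dist_pct", "spacing")],
       n_pairs = nrow(dat))
}

# reverse-complement of k-mer integer codes (base-4, A=0..T=3, first
# character most significant)
revcomp_code <- function(code, k) {
  out <- integer(length(code)); out[] <- 0L
  x <- code
  for (j in seq_len(k)) {
    digit <- x %% 4L
    out <- out * 4L + (3L - digit)
    x <- x %/% 4L
  }
  out
}

#' Operon-length gradients
#'
#' Regresses operon length (bp) and genes per operon against the
#' operon's distance from the terminus. Operons may be supplied
#' (data.frame `start`, `end`, `n_genes`) or derived as runs of
#' same-strand genes with intergenic gaps below `max_gap_bp`.
#'
#' @param features CDS [gene_features] (used when `operons` is NULL).
#' @param map A [replichore_map].
#' @param operons Optional data.frame with `start`, `end`, `n_genes`.
#' @param max_gap_bp Gap threshold for operon derivation (default 50).
#' @return List with `length_regression`, `genes_regression`, and the
#'   operon table.
#' @export
operon_gradient <- function(features = NULL, map, operons = NULL,
                            max_gap_bp = 50) {
  if (is.null(operons)) {
    if (is.null(features) || nrow(features) == 0L)
      stop("no operons and no features supplied")
    o <- order(features$start)
    f <- features[o, , drop = FALSE]
    n <- nrow(f)
    newrun <- c(TRUE, f$strand[-1] != f$strand[-n] |
                  (f$start[-1] - f$end[-n]) >= max_gap_bp)
    grp <- cumsum(newrun)
    operons <- do.call(rbind, lapply(split(seq_len(n), grp), function(i)
      data.frame(start = min(f$start[i]), end = max(f$end[i]),
                 n_genes = length(i))))
  }
  if (NROW(operons) == 0L) stop("empty operon list")
  mid <- ((operons$start + operons$end) / 2) %% map$length
  d <- distance_from_terminus(mid, map)
  len <- operons$end - operons$start
  list(length_regression = regression_summary(d, len),
       genes_regression = regression_summary(d, operons$n_genes),
       operons = data.frame(operons, dist_pct = d))
}

# --- NG86 synonymous distance ----------------------------------------------

ng86_site_tables <- function() {
  if (!is.null(.aimsarch_cache$ng86)) return(.aimsarch_cache$ng86)
  gc <- GENETIC_CODE_TABLE()
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[cd] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      ref <- substr(cd, p, p)
      alts <- setdiff(bases, ref)
      nsyn <- 0; nvalid <- 0
      for (a in alts) {
        mut <- cd; substr(mut, p, p) <- a
        if (gc[mut] == "*") next         # changes to stops excluded
        nvalid <- nvalid + 1
        if (gc[mut] == gc[cd]) nsyn <- nsyn + 1
      }
      if (nvalid > 0) s <- s + nsyn / nvalid
    }
    syn_sites[cd] <- s
  }
  .aimsarch_cache$ng86 <- list(syn_sites = syn_sites, gc = gc)
  .aimsarch_cache$ng86
}

# synonymous/nonsynonymous difference counts between two codons,
# averaged over all mutational pathways that avoid stop codons
ng86_pair_diffs <- function(c1, c2) {
  tab <- ng86_site_tables(); gc <- tab$gc
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else perms_of(pos)
  acc <- c(0, 0); nvalid <- 0
  for (p in paths) {
    cur <- c1; sdd <- 0; ndd <- 0; okpath <- TRUE
    for (site in p) {
      nxt <- cur
      substr(nxt, site, site) <- substr(c2, site, site)
      if (gc[nxt] == "*") { okpath <- FALSE; break }
      if (gc[cur] == gc[nxt]) sdd <- sdd + 1 else ndd <- ndd + 1
      cur <- nxt
    }
    if (okpath) { acc <- acc + c(sdd, ndd); nvalid <- nvalid + 1 }
  }
  if (nvalid == 0L) {
    # all pathways pass through stops; fall back to counting all
    return(c(sd = 0, nd = nd))
  }
  c(sd = acc[1] / nvalid, nd = acc[2] / nvalid)
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- perms_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Synonymous divergence (Ks) by the Nei-Gojobori method
#'
#' Counts synonymous sites and synonymous differences over an in-frame
#' codon alignment (pathway-averaged for multi-site codon differences,
#' pathways through stop codons excluded) and applies the Jukes-Cantor
#' correction `Ks = -3/4 * ln(1 - 4/3 * pS)`. Codons containing gaps,
#' ambiguity characters or stops are skipped. Symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b Equal-length, in-frame aligned nucleotide strings.
#' @return List `ks`, `ps` (proportion of synonymous differences),
#'   `syn_sites`, `syn_diffs`, and `saturated` (`TRUE` with `ks = NA`
#'   when `pS >= 3/4`, outside the Jukes-Cantor domain).
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  tab <- ng86_site_tables()
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  ok <- ca %in% names(tab$syn_sites) & cb %in% names(tab$syn_sites) &
    !is.na(tab$syn_sites[ca]) & !is.na(tab$syn_sites[cb])
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L)
    return(list(ks = NA_real_, ps = NA_real_, syn_sites = 0,
                syn_diffs = 0, saturated = FALSE))
  S <- sum((tab$syn_sites[ca] + tab$syn_sites[cb]) / 2)
  sd_tot <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) sd_tot <- sd_tot + ng86_pair_diffs(ca[i], cb[i])[["sd"]]
  }
  if (S == 0)
    return(list(ks = NA_real_, ps = NA_real_, syn_sites = 0,
                syn_diffs = sd_tot, saturated = FALSE))
  ps <- sd_tot / S
  if (ps >= 0.75)
    return(list(ks = NA_real_, ps = ps, syn_sites = S, syn_diffs = sd_tot,
                saturated = TRUE))
  list(ks = -0.75 * log(1 - 4 * ps / 3), ps = ps, syn_sites = S,
       syn_diffs = sd_tot, saturated = FALSE)
}
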