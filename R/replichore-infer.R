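# Replication-breakpoint inference from frame-specific pentamer
# composition of protein-coding genes.
#
# For every candidate breakpoint pair the genes are split into two
# strand classes (co-oriented with vs. against the putative fork), a
# conditional pentamer profile P(B_m | T_ijkl) is built per reading
# frame for each class, and the squared-difference score
#   Delta = sum_r sum_T sum_B (f_lead - f_lag)^2
# is maximized over candidates.

PENT_BASES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# integer base codes for a character sequence; non-ACGT -> NA
base_codes <- function(seq_chr) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(seq_chr)]
}

# Frame-specific pentamer counts of one coding sequence (read in coding
# orientation). Returns integer vector of length 3072 indexed
# frame*1024 + tetramer*4 + base + 1, frame = start offset mod 3.
pentamer_counts_one <- function(seq_chr) {
  n <- nchar(seq_chr)
  out <- integer(3072L)
  if (n < 5L) return(out)
  b <- base_codes(seq_chr)
  np <- n - 4L
  code <- b[1:np] * 256L + b[2:(np + 1L)] * 64L + b[3:(np + 2L)] * 16L +
    b[4:(np + 3L)] * 4L + b[5:(np + 4L)]
  frame <- (seq_len(np) - 1L) %% 3L
  idx <- frame * 1024L + code + 1L
  tabulate(idx[!is.na(idx)], nbins = 3072L)
}

# coding sequence of a feature (strand-aware, wrap-aware)
coding_seq <- function(genome, start, end, strand) {
  s <- genome_subseq(genome, start, end)
  if (strand < 0) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# n_genes x 3072 matrix of frame-specific pentamer counts
gene_pentamer_matrix <- function(genome, features) {
  short <- (features$end - features$start) < 5L
  if (any(short))
    warning(sprintf("%d gene(s) shorter than 5 bp contribute no pentamers",
                    sum(short)))
  t(vapply(seq_len(nrow(features)), function(i)
    pentamer_counts_one(coding_seq(genome, features$start[i],
                                   features$end[i], features$strand[i])),
    integer(3072L)))
}

# counts (length 3072) -> smoothed conditional frequencies P(B|T) per
# frame; pseudocount 1 per pentamer per frame.
pentamer_conditionals <- function(counts, pseudocount = 1) {
  a <- array(counts + pseudocount, dim = c(4L, 256L, 3L))
  tot <- colSums(a)                       # 256 x 3 tetramer-frame margins
  sweep(a, c(2L, 3L), tot, "/")
}

#' Frame-specific conditional pentamer profile
#'
#' Builds the conditional pentamer frequencies `P(B_m | T_ijkl)` for each
#' of the three reading frames, pooled over a set of protein-coding
#' genes read in their own coding orientation. A pseudocount of 1 per
#' pentamer per frame keeps the conditionals defined for unseen
#' tetramers.
#'
#' @param features [gene_features] (CDS only are used).
#' @param genome A [genome].
#' @param leading Logical vector per gene: does the gene belong to the
#'   leading-strand class? If `NULL` a single pooled profile is returned.
#' @param pseudocount Additive smoothing per pentamer per frame.
#' @return A list of class `pentamer_profile` with arrays
#'   `f` (4 bases x 256 tetramers x 3 frames) per strand class, raw
#'   `counts`, and the gene tallies per class.
#' @export
pentamer_profile <- function(features, genome, leading = NULL,
                             pseudocount = 1) {
  features <- features[features$kind == "CDS", , drop = FALSE]
  if (nrow(features) == 0L) stop("no CDS features")
  M <- gene_pentamer_matrix(genome, features)
  if (is.null(leading)) {
    cnt <- colSums(M)
    return(structure(list(f = list(all = pentamer_conditionals(cnt, pseudocount)),
                          counts = list(all = cnt),
                          n_genes = c(all = nrow(features))),
                     class = "pentamer_profile"))
  }
  stopifnot(length(leading) == nrow(features))
  if (!any(leading) || all(leading))
    stop("empty gene set for one strand class; Delta undefined")
  cl <- colSums(M[leading, , drop = FALSE])
  cg <- colSums(M[!leading, , drop = FALSE])
  structure(list(f = list(leading = pentamer_conditionals(cl, pseudocount),
                          lagging = pentamer_conditionals(cg, pseudocount)),
                 counts = list(leading = cl, lagging = cg),
                 n_genes = c(leading = sum(leading), lagging = sum(!leading))),
            class = "pentamer_profile")
}

#' Pentamer-difference score between two strand classes
#'
#' @param profile A two-class [pentamer_profile].
#' @return The sum over frames, tetramers and bases of the squared
#'   difference of conditional frequencies; `>= 0`, and `0` iff the two
#'   profiles are identical.
#' @export
delta_score <- function(profile) {
  stopifnot(all(c("leading", "lagging") %in% names(profile$f)))
  sum((profile$f$leading - profile$f$lagging)^2)
}

# Delta for class-count vectors (pre-smoothed conditional comparison)
delta_from_counts <- function(c1, c2, pseudocount = 1) {
  sum((pentamer_conditionals(c1, pseudocount) -
         pentamer_conditionals(c2, pseudocount))^2)
}

# intergenic midpoints of a circularly ordered feature set
intergenic_midpoints <- function(features, L) {
  o <- order((features$start + features$end) / 2)
  f <- features[o, , drop = FALSE]
  n <- nrow(f)
  nxt <- c(2:n, 1L)
  gap_start <- f$end
  gap_end <- f$start[nxt] + ifelse(f$start[nxt] < f$end, L, 0)
  ((gap_start + gap_end) / 2) %% L
}

#' Infer replication breakpoints
#'
#' Searches pairs of intergenic candidate positions for the partition of
#' genes into putative leading/lagging strand classes that maximizes the
#' frame-specific pentamer difference score. A two-stage search
#' (coarse grid over every `grid`-th intergenic gap, then refinement
#' over all gaps within +/- 5% of genome length of the coarse optimum)
#' returns the optimum at intergenic-gap resolution. Genes are assigned
#' to arms by their midpoints.
#'
#' @param genome A [genome].
#' @param features [gene_features]; only CDS rows are used.
#' @param grid Coarse-stage spacing over intergenic gaps (default 10).
#' @param flat_ratio If the maximal Delta is less than `flat_ratio`
#'   times the median Delta the result is flagged low-confidence.
#' @param refine_pct Half-width of the refinement window, percent of
#'   genome length.
#' @return A [replichore_map] whose `ori`/`ter` labels are assigned by
#'   [classify_ori_ter]; `delta_profile` holds every evaluated pair.
#' @export
find_breakpoints <- function(genome, features, grid = 10,
                             flat_ratio = 2, refine_pct = 5) {
  features <- features[features$kind == "CDS", , drop = FALSE]
  L <- genome$length
  mid <- ((features$start + features$end) / 2) %% L
  o <- order(mid)
  features <- features[o, , drop = FALSE]
  mid <- mid[o]
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 CDS features")
  cand <- sort(intergenic_midpoints(features, L))
  if (length(cand) < 2L) stop("need >= 2 intergenic candidate positions")

  M <- gene_pentamer_matrix(genome, features)
  plus <- features$strand > 0
  Mp <- M; Mp[!plus, ] <- 0L
  Mm <- M; Mm[plus, ] <- 0L
  # prefix sums over gene order: row i = sum of first i genes
  Pp <- rbind(0, apply(Mp, 2L, cumsum))
  Pm <- rbind(0, apply(Mm, 2L, cumsum))
  totp <- Pp[n + 1L, ]; totm <- Pm[n + 1L, ]
  # first gene index with midpoint >= candidate position
  gidx <- findInterval(cand, mid) + 1L   # genes i..j-1 are in [cand_i, cand_j)

  tPp <- t(Pp); tPm <- t(Pm)
  eval_pairs <- function(ii, jj) {
    # arm I = genes with midpoint in [cand_i, cand_j)
    delta_pairs_cpp(tPp, tPm, totp, totm, gidx[ii] - 1L, gidx[jj] - 1L)
  }

  nc <- length(cand)
  coarse <- unique(c(seq(1L, nc, by = max(1L, as.integer(grid))), nc))
  pairs <- t(utils::combn(coarse, 2L))
  dvals <- eval_pairs(pairs[, 1L], pairs[, 2L])
  best <- which.max(dvals)
  b1 <- pairs[best, 1L]; b2 <- pairs[best, 2L]
  # flat-profile diagnostic from the coarse (global) stage only
  conf <- if (max(dvals, na.rm = TRUE) /
              stats::median(dvals, na.rm = TRUE) < flat_ratio) "low" else "ok"

  # refinement: all gaps within refine_pct% of each coarse breakpoint
  win <- L * refine_pct / 100
  near <- function(ci) which(pmin((cand - cand[ci]) %% L,
                                  (cand[ci] - cand) %% L) <= win)
  set1 <- near(b1); set2 <- near(b2)
  rp <- expand.grid(i = set1, j = set2)
  rp <- rp[rp$i != rp$j, , drop = FALSE]
  ij <- unique(cbind(pmin(rp$i, rp$j), pmax(rp$i, rp$j)))
  rvals <- eval_pairs(ij[, 1L], ij[, 2L])
  allpairs <- rbind(pairs, ij)
  allvals <- c(dvals, rvals)
  keep <- !is.na(allvals)
  allpairs <- allpairs[keep, , drop = FALSE]; allvals <- allvals[keep]
  best <- which.max(allvals)
  bp1 <- cand[allpairs[best, 1L]]; bp2 <- cand[allpairs[best, 2L]]
  dmax <- allvals[best]
  prof <- data.frame(b1 = cand[allpairs[, 1L]], b2 = cand[allpairs[, 2L]],
                     delta = allvals)
  map <- replichore_map(ori = bp1, ter = bp2, length = L, delta = dmax,
                        delta_profile = prof, confidence = conf)
  classify_ori_ter(map, features)
}

#' Assign origin/terminus labels to a breakpoint pair
#'
#' The breakpoint labelled as the origin is the one maximizing the
#' number of genes transcribed away from it (equivalently, the
#' leading-strand gene count under that labelling). Ties fall back to
#' the leading-strand CDS fraction and then the lower coordinate; an
#' exact tie is flagged `"ambiguous"`.
#'
#' @param map A [replichore_map] (labels provisional).
#' @param features [gene_features].
#' @return The map with `ori`/`ter` fixed and `confidence` updated.
#' @export
classify_ori_ter <- function(map, features) {
  features <- features[features$kind == "CDS", , drop = FALSE]
  mid <- ((features$start + features$end) / 2) %% map$length
  away1 <- sum(is_leading(mid, features$strand, map))           # ori = map$ori
  map2 <- replichore_map(map$ter, map$ori, map$length, map$delta,
                         map$delta_profile, map$confidence)
  away2 <- sum(is_leading(mid, features$strand, map2))          # ori = map$ter
  if (away1 > away2) return(map)
  if (away2 > away1) return(map2)
  # exact tie after count and fraction (same denominator): lower coord
  out <- if (map$ori <= map$ter) map else map2
  out$confidence <- "ambiguous"
  out
}

#' Cumulative GC-skew diagnostic
#'
#' Provided for comparison output only; the breakpoint caller does not
#' use GC skew. Windowed skew `(G - C) / (G + C)` and the positions of
#' the cumulative-skew extrema (conventional ori/ter estimates).
#'
#' @param genome A [genome].
#' @param window Window size in bp.
#' @return List with per-window skew, cumulative skew, and `ori`/`ter`
#'   estimates (bp of the cumulative minimum / maximum).
#' @export
gc_skew <- function(genome, window = 10000) {
  s <- as.character(genome$sequence)
  L <- genome$length
  starts <- seq(1L, L - window + 1L, by = window)
  g <- vapply(starts, function(a) {
    sub <- substr(s, a, a + window - 1L)
    nG <- lengths(regmatches(sub, gregexpr("G", sub, fixed = TRUE)))
    nC <- lengths(regmatches(sub, gregexpr("C", sub, fixed = TRUE)))
    if (nG + nC == 0) 0 else (nG - nC) / (nG + nC)
  }, numeric(1))
  cum <- cumsum(g)
  list(window_start = starts - 1L, skew = g, cumulative = cum,
       ori = starts[which.min(cum)] - 1L, ter = starts[which.max(cum)] - 1L)
}

#' Scan a genome for an IUPAC consensus motif
#'
#' @param genome A [genome].
#' @param consensus IUPAC consensus string.
#' @param max_mismatch Maximum allowed mismatches (default 0).
#' @param both_strands Also report reverse-complement matches (strand
#'   `-1`, position = 0-based Watson start of the match)? Default `TRUE`.
#' @return data.frame with `pos` (0-based), `strand`, `mismatches`.
#' @export
find_motif <- function(genome, consensus, max_mismatch = 0,
                       both_strands = TRUE) {
  k <- nchar(consensus)
  if (k > genome$length) {
    warning("consensus longer than genome; no hits possible")
    return(data.frame(pos = integer(), strand = integer(),
                      mismatches = integer()))
  }
  subject <- if (genome$circular && genome$length > k)
    genome_subseq(genome, 0L, genome$length + k - 1L) else genome$sequence
  scan1 <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatch,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    if (length(m) == 0L)
      return(data.frame(pos = integer(), strand = integer(),
                        mismatches = integer()))
    pos0 <- Biostrings::start(m) - 1L
    mm <- vapply(seq_along(m), function(i)
      Biostrings::neditAt(Biostrings::DNAString(pat), subject,
                          at = Biostrings::start(m)[i],
                          fixed = c(pattern = FALSE, subject = TRUE)),
      integer(1))
    keep <- pos0 < genome$length
    data.frame(pos = pos0[keep] %% genome$length,
               strand = rep(strand, sum(keep)), mismatches = mm[keep])
  }
  out <- scan1(consensus, 1L)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(consensus)))
    out <- rbind(out, scan1(rc, -1L))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' dif-site consensus (gamma-proteobacteria)
#' @export
DIF_CONSENSUS <- "RNTKCGCATAATGTATATTATGTTAAAT"

#' Ter-site consensus (E. coli)
#' @export
TER_CONSENSUS <- "AGNATGTTGTAACTAA"

#' Validate a predicted terminus against dif-site hits
#'
#' @param map A [replichore_map].
#' @param dif_hits data.frame from [find_motif] (columns `pos`, ...).
#' @return List with the nearest hit, the circular offset in bp and as a
#'   percentage of genome length; or `status = "no dif found"`.
#' @export
validate_terminus <- function(map, dif_hits) {
  if (is.null(dif_hits) || nrow(dif_hits) == 0L)
    return(list(status = "no dif found", offset_bp = NA_real_,
                offset_pct = NA_real_, nearest = NA_real_))
  L <- map$length
  d <- pmin((dif_hits$pos - map$ter) %% L, (map$ter - dif_hits$pos) %% L)
  i <- which.min(d)
  list(status = "ok", offset_bp = d[i], offset_pct = 100 * d[i] / L,
       nearest = dif_hits$pos[i])
}
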