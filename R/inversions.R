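# Arm-restricted inversion detection from signed ortholog orders.
#
# Two closely related genomes are compared as signed circular
# permutations over their shared single-copy orthologs (sign = coding
# strand). An inversion is a maximal block whose gene order is reversed
# and strand-flipped relative to at least `flank_k` syntenic genes on
# each side.

# Core detector on signed permutations.
# a, b: data.frames with columns gene (character) and sign (+1/-1), in
# chromosomal order. Returns a list of integer vectors (indices into
# a's order) for each detected block.
find_inverted_blocks <- function(a, b, flank_k = 2, circular = TRUE) {
  shared <- intersect(a$gene, b$gene)
  a <- a[a$gene %in% shared, , drop = FALSE]
  b <- b[b$gene %in% shared, , drop = FALSE]
  n <- nrow(a)
  if (n < 2L * flank_k + 1L) {
    warning("too few shared orthologs for inversion detection")
    return(list())
  }
  posB <- match(a$gene, b$gene)          # position of a's i-th gene in b
  relsign <- a$sign * b$sign[posB]
  stepfwd <- function(i) if (i == n) 1L else i + 1L
  modn <- function(x) ((x - 1L) %% n) + 1L
  # consecutive-in-b helpers on the circle
  succ_dec <- function(i, j) modn(posB[j]) == modn(posB[i] - 1L)  # q_j = q_i - 1
  succ_inc <- function(i, j) modn(posB[j]) == modn(posB[i] + 1L)

  idx_range <- if (circular) seq_len(n) else seq_len(n)
  blocks <- list()
  used <- rep(FALSE, n)
  for (s in idx_range) {
    if (used[s] || relsign[s] != -1L) next
    # extend a maximal run of relsign -1 with q decreasing by 1
    e <- s
    repeat {
      nx <- if (circular) modn(e + 1L) else e + 1L
      if (!circular && nx > n) break
      if (nx == s) break
      if (relsign[nx] == -1L && succ_dec(e, nx)) e <- nx else break
    }
    # also extend backwards (runs can start before s in circular order)
    st <- s
    repeat {
      pv <- if (circular) modn(st - 1L) else st - 1L
      if (!circular && pv < 1L) break
      if (pv == e) break
      if (relsign[pv] == -1L && succ_inc(st, pv)) st <- pv else break
    }
    block <- if (st <= e) st:e else c(st:n, 1:e)
    if (!circular && (st > e)) next
    used[block] <- TRUE
    # flank synteny: flank_k genes on each side with relsign +1 and
    # q consecutive increasing, bridging the reversed block:
    # q(left flank neighbour) must equal q(last block gene) - 1 and
    # q(right flank neighbour) must equal q(first block gene) + 1.
    lf <- modn(st - seq_len(flank_k))
    rf <- modn(e + seq_len(flank_k))
    if (!circular && (st - flank_k < 1L || e + flank_k > n)) next
    if (length(intersect(c(lf, rf), block))) next
    ok <- all(relsign[lf] == 1L) && all(relsign[rf] == 1L)
    if (ok) {
      first <- block[1L]; last <- block[length(block)]
      ok <- modn(posB[lf[1L]]) == modn(posB[last] - 1L) &&
        modn(posB[rf[1L]]) == modn(posB[first] + 1L)
      # flank runs must themselves be consecutive in b
      if (ok && flank_k > 1L) {
        for (k in seq_len(flank_k - 1L)) {
          if (!succ_dec(lf[k], lf[k + 1L])) ok <- FALSE   # moving left, q decreases
          if (!succ_inc(rf[k], rf[k + 1L])) ok <- FALSE
        }
      }
    }
    if (ok) blocks <- c(blocks, list(block))
  }
  blocks
}

# span (bp) of a set of features on a circular genome: the smallest
# circular interval covering all of them; returned c(start, end) with
# end possibly > L
feature_span <- function(starts, ends, L) {
  if (any(ends > L)) ends <- pmin(ends, L)  # wrapping features clipped
  n <- length(starts)
  if (n == 1L) return(c(starts, ends))
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  gaps <- c(s[-1L], s[1L] + L) - e       # gap after each feature
  gi <- which.max(gaps)
  if (gaps[gi] <= 0) return(c(min(s), max(e)))
  st <- if (gi == n) s[1L] else s[gi + 1L]
  en <- e[gi] + if (e[gi] < st) L else 0
  if (en <= st) en <- en + L
  c(st, en)
}

span_contains <- function(span, pos, L) {
  ((pos - span[1]) %% L) < (span[2] - span[1])
}

#' Detect arm-restricted inversions between a genome pair
#'
#' @param featA,featB [gene_features] of the two genomes (shared
#'   single-copy orthologs carry the same `gene_id`; genes present in
#'   one genome only are skipped as transparent).
#' @param mapA,mapB [replichore_map]s of the two genomes.
#' @param flank_k Required syntenic genes on each side (default 2).
#' @param pair_id Identifier recorded on each record.
#' @return data.frame of class `inversion_records`: one row per
#'   inversion with member genes, spans, lengths, and midpoint
#'   distance-from-terminus percentages in each genome and their mean.
#'   Candidates whose span contains the origin or terminus of either
#'   genome are discarded.
#' @export
detect_inversions <- function(featA, featB, mapA, mapB, flank_k = 2,
                              pair_id = "pair") {
  ordA <- order((featA$start + featA$end) / 2)
  ordB <- order((featB$start + featB$end) / 2)
  a <- data.frame(gene = featA$gene_id[ordA], sign = featA$strand[ordA],
                  start = featA$start[ordA], end = featA$end[ordA],
                  stringsAsFactors = FALSE)
  b <- data.frame(gene = featB$gene_id[ordB], sign = featB$strand[ordB],
                  start = featB$start[ordB], end = featB$end[ordB],
                  stringsAsFactors = FALSE)
  shared <- intersect(a$gene, b$gene)
  a2 <- a[a$gene %in% shared, , drop = FALSE]
  b2 <- b[b$gene %in% shared, , drop = FALSE]
  blocks <- find_inverted_blocks(a2, b2, flank_k = flank_k)
  if (length(blocks) == 0L)
    return(empty_inversion_records())
  LA <- mapA$length; LB <- mapB$length
  rows <- lapply(blocks, function(bl) {
    genes <- a2$gene[bl]
    ia <- match(genes, a2$gene); ib <- match(genes, b2$gene)
    spanA <- feature_span(a2$start[ia], a2$end[ia], LA)
    spanB <- feature_span(b2$start[ib], b2$end[ib], LB)
    # discard if either genome's span contains either replication site
    if (span_contains(spanA, mapA$ori, LA) ||
        span_contains(spanA, mapA$ter, LA) ||
        span_contains(spanB, mapB$ori, LB) ||
        span_contains(spanB, mapB$ter, LB)) return(NULL)
    midA <- ((spanA[1] + spanA[2]) / 2) %% LA
    midB <- ((spanB[1] + spanB[2]) / 2) %% LB
    dA <- distance_from_terminus(midA, mapA)
    dB <- distance_from_terminus(midB, mapB)
    data.frame(pair_id = pair_id,
               genes = paste(sort(genes), collapse = ","),
               n_genes = length(genes),
               startA = spanA[1] %% LA, endA = spanA[2],
               startB = spanB[1] %% LB, endB = spanB[2],
               length_bp = ((spanA[2] - spanA[1]) + (spanB[2] - spanB[1])) / 2,
               midpoint_pctA = dA, midpoint_pctB = dB,
               midpoint_pct = (dA + dB) / 2,
               provenance = pair_id,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_inversion_records())
  out <- do.call(rbind, rows)
  class(out) <- c("inversion_records", "data.frame")
  out
}

empty_inversion_records <- function() {
  out <- data.frame(pair_id = character(), genes = character(),
                    n_genes = integer(), startA = numeric(),
                    endA = numeric(), startB = numeric(), endB = numeric(),
                    length_bp = numeric(), midpoint_pctA = numeric(),
                    midpoint_pctB = numeric(), midpoint_pct = numeric(),
                    provenance = character(), stringsAsFactors = FALSE)
  class(out) <- c("inversion_records", "data.frame")
  out
}

#' Collapse inversions observed in multiple pairwise comparisons
#'
#' Records with identical ortholog content are counted once; the
#' provenance column accumulates the contributing pair ids. Idempotent.
#'
#' @param records An `inversion_records` data.frame (rows from one or
#'   more comparisons).
#' @return Deduplicated `inversion_records`.
#' @export
dedupe_inversions <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- records$genes
  keep <- !duplicated(key)
  out <- records[keep, , drop = FALSE]
  out$provenance <- vapply(out$genes, function(g)
    paste(sort(unique(unlist(strsplit(records$provenance[key == g], ";")))),
          collapse = ";"), character(1))
  rownames(out) <- NULL
  class(out) <- c("inversion_records", "data.frame")
  out
}

#' Positional summary of inversions
#'
#' Bins inversion midpoints over distance-from-terminus and reports the
#' inversion count, total inverted bp, and mean inversion size per bin,
#' together with the Pearson correlation of each series against the
#' bin midpoint.
#'
#' @param records `inversion_records`.
#' @param bin_pct Bin width, percent of genome length (default 5).
#' @return List with `bins` (data.frame) and `correlations`.
#' @export
positional_summary <- function(records, bin_pct = 5) {
  edges <- seq(0, 50, by = bin_pct)
  mids <- head(edges, -1) + bin_pct / 2
  nb <- length(mids)
  count <- integer(nb); total_bp <- numeric(nb); mean_size <- rep(NA_real_, nb)
  if (nrow(records) > 0L) {
    bin <- pmin(findInterval(records$midpoint_pct, edges,
                             rightmost.closed = TRUE), nb)
    for (i in seq_len(nb)) {
      sel <- bin == i
      count[i] <- sum(sel)
      total_bp[i] <- sum(records$length_bp[sel])
      if (count[i] > 0) mean_size[i] <- mean(records$length_bp[sel])
    }
  }
  bins <- data.frame(bin_mid_pct = mids, count = count,
                     total_bp = total_bp, mean_size = mean_size)
  corr <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(mids[ok], y[ok])
  }
  list(bins = bins,
       correlations = c(count = corr(count), total_bp = corr(total_bp),
                        mean_size = corr(mean_size)))
}
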