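# Octamer counting on replichores.
#
# Concrete 8-mer counts come from Biostrings; degenerate octamers
# (IUPAC, up to 2 ambiguous positions) are aggregated from the 4^8
# concrete count table by tensor contraction with the IUPAC membership
# matrix, so the full degenerate candidate space can be scored without
# per-pattern scans.

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                   "V", "H", "D", "B", "N")
DEGENERATE_SYMBOLS <- IUPAC_SYMBOLS[5:15]

# 0/1 membership matrix rows = symbols, cols = A,C,G,T
iupac_membership <- function(symbols) {
  map <- Biostrings::IUPAC_CODE_MAP
  t(vapply(symbols, function(s) {
    as.numeric(c("A", "C", "G", "T") %in% strsplit(map[[s]], "")[[1]])
  }, numeric(4)))
}

.aimsarch_cache <- new.env(parent = emptyenv())

# permutation such that counts[rc8_perm()] reindexes an 8-mer count
# vector by reverse complement
rc8_perm <- function() {
  if (!is.null(.aimsarch_cache$rc8)) return(.aimsarch_cache$rc8)
  idx <- 0:(4^8 - 1)
  digits <- matrix(0L, length(idx), 8L)
  x <- idx
  for (k in 8:1) { digits[, k] <- x %% 4L; x <- x %/% 4L }
  comp <- 3L - digits                    # A<->T, C<->G in ACGT order
  rcidx <- comp[, 8:1, drop = FALSE] %*% 4^(7:0)
  .aimsarch_cache$rc8 <- as.integer(rcidx) + 1L
  .aimsarch_cache$rc8
}

octamer_index_to_string <- function(i0) {
  # i0: 0-based lexicographic index over ACGT, first character most
  # significant
  bases <- c("A", "C", "G", "T")
  out <- character(length(i0))
  m <- matrix("", length(i0), 8L)
  x <- i0
  for (k in 8:1) { m[, k] <- bases[x %% 4L + 1L]; x <- x %/% 4L }
  apply(m, 1L, paste0, collapse = "")
}

# split a circular interval [s, e) (0 <= s < L, e may exceed L) into
# linear pieces within [0, L)
circ_pieces <- function(s, e, L) {
  s <- s %% L
  len <- e - (e - (e %% L)) + 0  # unused; compute via length below
  len <- (e - s)
  if (len <= 0) return(list())
  if (s + len <= L) return(list(c(s, s + len)))
  list(c(s, L), c(0, s + len - L))
}

# intersection of two linear intervals
lin_intersect <- function(a, b) {
  s <- max(a[1], b[1]); e <- min(a[2], b[2])
  if (e > s) c(s, e) else NULL
}

# intersect a circular interval with each arm; returns list with
# per-arm lists of linear [s,e) pieces
region_by_arm <- function(interval, map) {
  arms <- arm_intervals(map)
  L <- map$length
  rp <- circ_pieces(interval[1], interval[2], L)
  out <- list(arm1 = list(), arm2 = list())
  for (an in c("arm1", "arm2")) {
    for (ap in circ_pieces(arms[[an]][1], arms[[an]][2], L)) {
      for (r in rp) {
        x <- lin_intersect(ap, r)
        if (!is.null(x)) out[[an]] <- c(out[[an]], list(x))
      }
    }
  }
  out
}

# leading/lagging concrete 8-mer count vectors for a region
# (circular interval or NULL for genome-wide), plus region bp length
octamer_region_counts <- function(genome, map, interval = NULL, width = 8L) {
  L <- map$length
  if (is.null(interval)) interval <- c(map$ori, map$ori + L)
  ra <- region_by_arm(interval, map)
  lead <- numeric(4^width); lag <- numeric(4^width)
  bp <- 0
  rc <- rc8_perm()
  for (an in c("arm1", "arm2")) {
    for (p in ra[[an]]) {
      if (p[2] - p[1] < width) { bp <- bp + (p[2] - p[1]); next }
      w <- Biostrings::oligonucleotideFrequency(
        genome_subseq(genome, p[1], p[2]), width = width)
      bp <- bp + (p[2] - p[1])
      if (an == "arm1") { lead <- lead + w; lag <- lag + w[rc] }
      else { lead <- lead + w[rc]; lag <- lag + w }
    }
  }
  list(leading = lead, lagging = lag, bp = bp)
}

#' Count a (possibly degenerate) octamer on the two strand classes
#'
#' Counts all occurrences of `octamer` on both strands of a genome
#' within a region, classifying each occurrence as leading or lagging
#' via the replichore map (an occurrence on the Watson strand of arm 1,
#' or the Crick strand of arm 2, is leading). Degenerate IUPAC symbols
#' match their expansion sets; overlapping occurrences all count;
#' windows wrapping the circular coordinate origin count.
#'
#' @param genome A [genome].
#' @param map A [replichore_map].
#' @param octamer IUPAC string (any length, typically 8).
#' @param region Optional circular interval `c(start, end)` in bp
#'   (0-based half-open, `end` may exceed the length to wrap); default
#'   whole genome.
#' @return List `n_leading`, `n_lagging`.
#' @export
count_octamer <- function(genome, map, octamer, region = NULL) {
  L <- genome$length
  k <- nchar(octamer)
  subject <- if (genome$circular && L > k)
    genome_subseq(genome, 0L, L + k - 1L) else genome$sequence
  hits <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    p <- Biostrings::start(m) - 1L
    p[p < L]
  }
  pw <- hits(octamer)                                   # strand +1
  pc <- hits(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(octamer))))                   # strand -1
  in_region <- function(p) {
    if (is.null(region)) return(rep(TRUE, length(p)))
    s <- region[1] %% L; len <- region[2] - region[1]
    ((p - s) %% L) < len
  }
  pw <- pw[in_region(pw)]; pc <- pc[in_region(pc)]
  lw <- is_leading(pw, rep(1L, length(pw)), map)
  lc <- is_leading(pc, rep(-1L, length(pc)), map)
  list(n_leading = sum(lw) + sum(lc),
       n_lagging = sum(!lw) + sum(!lc))
}

# ---- degenerate aggregation ------------------------------------------------

# contract an 8-mer count vector over octamer positions `pos` (length 1
# or 2) with membership matrix D. Returns matrix n_sym^k x 4^(8-k);
# row index decodes symbols (first position fastest), column index
# decodes the remaining concrete positions (see decode_rest).
contract_counts <- function(v, pos, D) {
  k <- length(pos)
  dims <- 9L - pos                       # array dim of each octamer position
  arr <- array(v, dim = rep(4L, 8L))
  other <- setdiff(1:8, dims)
  arr <- aperm(arr, c(dims, other))
  m <- matrix(arr, nrow = 4^k)
  M <- if (k == 1L) D else kronecker(D, D)
  M %*% m
}

# decode column index (1-based) of contract_counts output into the
# concrete bases at the remaining positions; returns character matrix
# with one column per remaining octamer position, ordered by octamer
# position ascending.
decode_rest <- function(cols, pos) {
  dims <- 9L - pos
  other <- setdiff(1:8, dims)            # ascending array dims, fastest first
  oct_pos <- 9L - other                  # corresponding octamer positions
  bases <- c("A", "C", "G", "T")
  x <- cols - 1L
  out <- matrix("", length(cols), length(other))
  for (j in seq_along(other)) { out[, j] <- bases[x %% 4L + 1L]; x <- x %/% 4L }
  colnames(out) <- as.character(oct_pos)
  out[, order(oct_pos), drop = FALSE]
}

decode_symbols <- function(rows, k, symbols) {
  x <- rows - 1L
  ns <- length(symbols)
  out <- matrix("", length(rows), k)
  for (j in seq_len(k)) { out[, j] <- symbols[x %% ns + 1L]; x <- x %/% ns }
  out
}

# assemble octamer strings for qualifying candidates
assemble_octamers <- function(rows, cols, pos, symbols) {
  k <- length(pos)
  sym <- decode_symbols(rows, k, symbols)
  rest <- decode_rest(cols, pos)
  other <- sort(9L - setdiff(1:8, 9L - pos))
  m <- matrix("", length(rows), 8L)
  for (j in seq_len(k)) m[, pos[j]] <- sym[, j]
  restpos <- sort(setdiff(1:8, pos))
  for (j in seq_along(restpos)) m[, restpos[j]] <- rest[, j]
  apply(m, 1L, paste0, collapse = "")
}
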