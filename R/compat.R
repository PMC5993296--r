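# Inter-genome AIMS compatibility: the strand-bias of a recipient's
# AIMS measured in random fragments of a candidate donor genome.

#' Mean fragment strand-bias of one AIMS in a donor genome
#'
#' Samples `n_fragments` fragments of `frag_bp` bp uniformly (with
#' replacement, wrap-around permitted) from the donor and, in each
#' fragment with at least one occurrence, computes the sup strand-bias
#' `max(N_W, N_C) / (N_W + N_C)` of the octamer over the fragment's two
#' strands. The mean over informative fragments is returned. Because
#' only the larger of the two per-strand fractions is taken, the
#' statistic carries a small-count upward bias: its expectation exceeds
#' 0.5 even in a donor with no true strand preference.
#'
#' @param donor A [genome].
#' @param octamer IUPAC octamer string.
#' @param n_fragments Number of fragments (default 1000).
#' @param frag_bp Fragment length (default 10000).
#' @param seed Optional seed.
#' @return List `mean_bias` (`NA` when no fragment is informative),
#'   `n_informative`, `n_fragments`.
#' @export
fragment_bias <- function(donor, octamer, n_fragments = 1000,
                          frag_bp = 10000, seed = NULL) {
  L <- donor$length
  if (L < frag_bp) stop("donor shorter than one fragment")
  k <- nchar(octamer)
  subject <- if (donor$circular) genome_subseq(donor, 0L, L + k - 1L)
  else donor$sequence
  pos_of <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    p <- Biostrings::start(m) - 1L
    sort(p[p < L])
  }
  pw <- pos_of(octamer)
  pc <- pos_of(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(octamer))))
  starts <- with_seed(seed, sample.int(L, n_fragments, replace = TRUE) - 1L)
  count_in <- function(p, a) {
    # occurrences with start in [a, a+frag_bp-k] (window fully inside)
    if (length(p) == 0L) return(integer(length(a)))
    hi <- a + frag_bp - k
    n1 <- findInterval(hi, p) - findInterval(a - 1L, p)
    # wrapped part for fragments running past L
    over <- hi - (L - 1L)
    n2 <- ifelse(over > 0,
                 findInterval(pmin(over, L) - 1L + 0.5, p), 0L)
    n1 + n2
  }
  nw <- count_in(pw, starts)
  nc <- count_in(pc, starts)
  tot <- nw + nc
  inf <- tot > 0
  sb <- pmax(nw[inf], nc[inf]) / tot[inf]
  list(mean_bias = if (any(inf)) mean(sb) else NA_real_,
       n_informative = sum(inf), n_fragments = n_fragments)
}

#' Abundance-weighted mean strand-bias (the compatibility aggregation)
#'
#' `C = sum_i SBbar_i * N_i / sum_i N_i`. Duplicate listings of an AIMS
#' leave the result unchanged when their `N_i` sum coherently.
#'
#' @param mean_bias Per-AIMS mean fragment strand-biases.
#' @param n_i Per-AIMS recipient abundances (weights).
#' @return The weighted mean, a scalar in `[0.5, 1]` for sup biases.
#' @export
compat_weighted_mean <- function(mean_bias, n_i) {
  stopifnot(length(mean_bias) == length(n_i), all(n_i >= 0))
  sum(mean_bias * n_i) / sum(n_i)
}

#' AIMS compatibility between a recipient and a donor genome
#'
#' The compatibility `C_XY` is the abundance-weighted mean of the
#' per-AIMS mean fragment strand-biases: `sum_i SBbar_i * N_i / sum_i
#' N_i`, where `N_i` is the abundance of AIMS `i` in the recipient and
#' `SBbar_i` its mean fragment bias in the donor. AIMS with no
#' informative fragment are dropped from the sum with a warning.
#' Contributions are not weighted by the AIMS's bias in the recipient.
#'
#' @param recipient_aims `aims_set` of the recipient (octamers with
#'   abundances `n_i`), or a data.frame with `octamer` and `n_i`.
#' @param donor A [genome].
#' @param n_fragments,frag_bp,seed Passed to [fragment_bias].
#' @return Object of class `compatibility_score` with `c_xy`, per-AIMS
#'   contributions, and identifiers.
#' @export
compatibility <- function(recipient_aims, donor, n_fragments = 1000,
                          frag_bp = 10000, seed = NULL) {
  tab <- if (inherits(recipient_aims, "aims_set")) recipient_aims$octamers
  else recipient_aims
  stopifnot(nrow(tab) > 0L, all(c("octamer", "n_i") %in% names(tab)))
  seeds <- if (is.null(seed)) vector("list", nrow(tab))
  else as.list(seed + seq_len(nrow(tab)))
  per <- lapply(seq_len(nrow(tab)), function(i)
    fragment_bias(donor, tab$octamer[i], n_fragments = n_fragments,
                  frag_bp = frag_bp, seed = seeds[[i]]))
  sb <- vapply(per, function(x) x$mean_bias, numeric(1))
  ni <- tab$n_i
  ok <- !is.na(sb)
  if (!any(ok)) stop("no informative AIMS in donor ", donor$id)
  if (any(!ok))
    warning(sum(!ok), " AIMS with no informative fragment dropped")
  cxy <- compat_weighted_mean(sb[ok], ni[ok])
  structure(list(recipient_id = if (inherits(recipient_aims, "aims_set"))
    recipient_aims$genome_id else NA_character_,
    donor_id = donor$id, c_xy = cxy,
    per_aims = data.frame(octamer = tab$octamer, n_i = ni,
                          mean_bias = sb,
                          n_informative = vapply(per, function(x)
                            x$n_informative, numeric(1))),
    n_informative_aims = sum(ok)),
    class = "compatibility_score")
}

#' @export
print.compatibility_score <- function(x, ...) {
  cat(sprintf("<compatibility> %s <- %s: C = %.4f (%d informative AIMS)\n",
              x$recipient_id, x$donor_id, x$c_xy, x$n_informative_aims))
  invisible(x)
}

#' Summarize compatibility scores by donor group
#'
#' Groups follow the conventional taxonomic contrast: donors in the
#' same family as the recipient, donors in the same division but a
#' different family, and donors in a different division. Reports
#' per-group N and mean compatibility plus the same/different deltas,
#' and optionally a least-squares regression of compatibility against
#' a supplied donor-recipient identity covariate.
#'
#' @param scores List of `compatibility_score` objects or data.frame
#'   with `donor_id` and `c_xy`.
#' @param groups Named character vector mapping donor id to one of
#'   `"same_family"`, `"same_division_different_family"`,
#'   `"different_division"`.
#' @param identity Optional named numeric vector (donor id ->
#'   donor-recipient identity, e.g. 16S) for the regression.
#' @return List `table` (per-group N/mean, blank cells as `NA`),
#'   `deltas`, and `regression` (or `NULL`).
#' @export
group_summary <- function(scores, groups, identity = NULL) {
  df <- if (is.data.frame(scores)) scores
  else data.frame(donor_id = vapply(scores, function(x) x$donor_id,
                                    character(1)),
                  c_xy = vapply(scores, function(x) x$c_xy, numeric(1)),
                  stringsAsFactors = FALSE)
  if (!all(df$donor_id %in% names(groups)))
    stop("every donor must be labelled")
  df$group <- unname(groups[df$donor_id])
  lv <- c("same_family", "same_division_different_family",
          "different_division")
  tab <- data.frame(group = lv,
                    n = vapply(lv, function(g) sum(df$group == g), numeric(1)),
                    mean_c = vapply(lv, function(g) {
                      v <- df$c_xy[df$group == g]
                      if (length(v)) mean(v) else NA_real_
                    }, numeric(1)))
  same_div <- df$c_xy[df$group %in% lv[1:2]]
  diff_div <- df$c_xy[df$group == lv[3]]
  deltas <- c(
    division = (if (length(same_div)) mean(same_div) else NA_real_) -
      (if (length(diff_div)) mean(diff_div) else NA_real_),
    family = tab$mean_c[1] - tab$mean_c[2])
  reg <- NULL
  if (!is.null(identity)) {
    df$identity <- unname(identity[df$donor_id])
    ok <- !is.na(df$identity)
    if (sum(ok) >= 3L) reg <- stats::lm(c_xy ~ identity, data = df[ok, ])
  }
  list(table = tab, deltas = deltas, regression = reg, data = df)
}
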