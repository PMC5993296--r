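# Horizontally acquired insertions and the permissive-orientation bias
# of recipient AIMS within them.

#' Call horizontally acquired insertions from a homology table
#'
#' A gene is called foreign when it lacks an orthologue in every sister
#' species and in every conspecific strain, and its best homologue in a
#' conspecific strain is below `sim_threshold` percent similarity
#' (requiring absence in multiple strains guards against scoring a
#' parallel loss as an acquisition). Runs of consecutive foreign genes
#' merge into a single insertion spanning from the start of the first
#' to the end of the last gene, including intervening intergenic DNA.
#'
#' @param features [gene_features] of the focal (recipient) genome, in
#'   any order.
#' @param homology Homology table (see [read_homology]) with the focal
#'   genes as queries.
#' @param sister_species Character vector of sister-species genome ids.
#' @param conspecific_strains Character vector (length >= 2 recommended)
#'   of conspecific strain genome ids.
#' @param map [replichore_map] of the focal genome (for midpoint
#'   coordinates).
#' @param sim_threshold Percent-similarity cutoff (default 40).
#' @return data.frame of class `insertion_records`: span, member genes,
#'   midpoint distance-from-terminus percent, and length.
#' @export
call_insertions <- function(features, homology, sister_species,
                            conspecific_strains, map, sim_threshold = 40) {
  stopifnot(length(sister_species) >= 1L)
  known <- unique(homology$subject_genome)
  missing <- setdiff(c(sister_species, conspecific_strains), known)
  if (length(missing))
    stop("genomes absent from homology table: ",
         paste(missing, collapse = ", "))
  o <- order((features$start + features$end) / 2)
  f <- features[o, , drop = FALSE]
  has_orth <- function(gene, genomes) {
    h <- homology[homology$query_gene == gene &
                    homology$subject_genome %in% genomes &
                    !is.na(homology$subject_gene) &
                    homology$reciprocal_best, , drop = FALSE]
    nrow(h) > 0L
  }
  best_consp_sim <- function(gene) {
    h <- homology[homology$query_gene == gene &
                    homology$subject_genome %in% conspecific_strains &
                    !is.na(homology$subject_gene), , drop = FALSE]
    if (nrow(h) == 0L) -Inf else max(h$similarity)
  }
  foreign <- vapply(f$gene_id, function(g)
    !has_orth(g, sister_species) && !has_orth(g, conspecific_strains) &&
      best_consp_sim(g) < sim_threshold, logical(1))
  if (!any(foreign)) return(empty_insertion_records())
  runs <- rle(foreign)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- lapply(which(runs$values), function(k) {
    i <- starts[k]:ends[k]
    span <- c(min(f$start[i]), max(f$end[i]))
    mid <- (span[1] + span[2]) / 2
    data.frame(genome_id = map$length,   # placeholder replaced below
               start = span[1], end = span[2],
               genes = paste(f$gene_id[i], collapse = ","),
               n_genes = length(i),
               length_bp = span[2] - span[1],
               midpoint_pct = distance_from_terminus(mid %% map$length, map,
                                                     clamp = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$genome_id <- NULL
  class(out) <- c("insertion_records", "data.frame")
  out
}

empty_insertion_records <- function() {
  out <- data.frame(start = numeric(), end = numeric(), genes = character(),
                    n_genes = integer(), length_bp = numeric(),
                    midpoint_pct = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("insertion_records", "data.frame")
  out
}

#' Permissive-orientation fraction of AIMS within a span
#'
#' Enumerates every occurrence of every AIMS of the recipient within a
#' genomic span and returns the fraction found on the leading strand
#' (the permissive orientation). Undefined (flagged) when the span
#' carries no AIMS occurrence.
#'
#' @param genome Recipient [genome].
#' @param map Recipient [replichore_map].
#' @param aims `aims_set` (or character vector of IUPAC octamers)
#'   identified on the recipient backbone.
#' @param span `c(start, end)` 0-based half-open bp interval.
#' @return A [permissive_fraction] list with an added `n_occurrences`.
#' @export
span_permissive_fraction <- function(genome, map, aims, span) {
  octs <- if (inherits(aims, "aims_set")) aims$octamers$octamer else aims
  nl <- 0L; ng <- 0L
  for (w in octs) {
    cnt <- count_octamer(genome, map, w, region = span)
    nl <- nl + cnt$n_leading; ng <- ng + cnt$n_lagging
  }
  out <- permissive_fraction(nl, ng)
  out$n_occurrences <- nl + ng
  out
}

#' Annotate insertions with permissive fractions
#'
#' @param insertions `insertion_records`.
#' @param genome,map,aims As in [span_permissive_fraction].
#' @return The records with `permissive_fraction` and `n_occurrences`
#'   columns; spans without occurrences get `NA`.
#' @export
annotate_permissive <- function(insertions, genome, map, aims) {
  pf <- lapply(seq_len(nrow(insertions)), function(i)
    span_permissive_fraction(genome, map, aims,
                             c(insertions$start[i], insertions$end[i])))
  insertions$permissive_fraction <- vapply(pf, function(x) x$value, numeric(1))
  insertions$n_occurrences <- vapply(pf, function(x) x$n_occurrences,
                                     numeric(1))
  insertions
}

#' Bias-versus-distance curve with negative-exponential fit
#'
#' Bins insertions by midpoint distance-from-terminus, computes the
#' length-weighted mean permissive fraction per bin, and fits the
#' decaying-exponential trend `SB(d) = a * exp(-d / b) + c` by
#' bounded nonlinear least squares (`a, c` in `[0, 1]`, `b > 0`).
#' Insertions without AIMS occurrences, and optionally those below
#' `min_span_bp`, are excluded.
#'
#' @param insertions `insertion_records` with `permissive_fraction`.
#' @param bin_pct Bin width in percent (default 2).
#' @param min_span_bp Minimum insertion length (default 0).
#' @param weighted Length-weight the per-bin means? Default `TRUE`
#'   (unweighted means are also returned).
#' @return List of class `bias_curve`: `bins`, fitted `a`, `b`, `c`,
#'   `r_squared`, and `fit` (the nls object or `NULL` on
#'   non-convergence).
#' @export
bias_curve <- function(insertions, bin_pct = 2, min_span_bp = 0,
                       weighted = TRUE) {
  x <- insertions[!is.na(insertions$permissive_fraction) &
                    insertions$length_bp >= min_span_bp, , drop = FALSE]
  x <- x[x$midpoint_pct <= 50, , drop = FALSE]
  edges <- seq(0, 50, by = bin_pct)
  mids <- head(edges, -1) + bin_pct / 2
  bin <- pmin(findInterval(x$midpoint_pct, edges, rightmost.closed = TRUE),
              length(mids))
  agg <- function(w) vapply(seq_along(mids), function(i) {
    sel <- bin == i
    if (!any(sel)) return(NA_real_)
    stats::weighted.mean(x$permissive_fraction[sel], w[sel])
  }, numeric(1))
  mw <- agg(x$length_bp)
  mu <- agg(rep(1, nrow(x)))
  n <- tabulate(bin, nbins = length(mids))
  bins <- data.frame(bin_mid_pct = mids, mean_weighted = mw,
                     mean_unweighted = mu, n = n)
  y <- if (weighted) mw else mu
  ok <- !is.na(y)
  fit <- NULL; a <- NA_real_; b <- NA_real_; cc <- NA_real_; r2 <- NA_real_
  if (sum(ok) >= 3L) {
    if (stats::sd(y[ok]) == 0) {
      a <- 0; b <- 1; cc <- y[ok][1]; r2 <- NA_real_
    } else {
      df <- data.frame(d = mids[ok], y = y[ok])
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-d / b) + c, data = df,
                          start = list(a = max(df$y) - min(df$y),
                                       b = 10, c = min(df$y)),
                          lower = c(a = 0, b = 1e-6, c = 0),
                          upper = c(a = 1, b = Inf, c = 1),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("exponential fit did not converge; curve returned unfitted")
      } else {
        cf <- coef(fit)
        a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
        r2 <- 1 - sum(residuals(fit)^2) / sum((df$y - mean(df$y))^2)
      }
    }
  }
  structure(list(bins = bins, a = a, b = b, c = cc, r_squared = r2,
                 fit = fit, weighted = weighted),
            class = "bias_curve")
}

#' Terminus-region loss of acquired DNA
#'
#' Compares insertions near the terminus with insertions near the
#' origin. For each window the normalized cumulative inserted-length
#' curve `F(s)` (fraction of inserted bp in fragments with permissive
#' fraction <= s) is constructed; the loss estimate is the difference
#' of the areas under the two curves, which equals the difference of
#' the length-weighted mean permissive fractions (terminus minus
#' origin). A two-sample Kolmogorov-Smirnov test compares the
#' per-fragment (unweighted) distributions.
#'
#' @param insertions `insertion_records` with `permissive_fraction`.
#' @param ter_window,ori_window Percent-from-terminus windows, default
#'   `c(0, 6)` and `c(42, 48)` (the final 2% is ignored to accommodate
#'   unequal arms).
#' @return List: `loss`, `ks_p`, the two window means, fragment counts
#'   and the window definitions.
#' @export
loss_fraction <- function(insertions, ter_window = c(0, 6),
                          ori_window = c(42, 48)) {
  x <- insertions[!is.na(insertions$permissive_fraction), , drop = FALSE]
  pick <- function(wdw) x[x$midpoint_pct >= wdw[1] &
                            x$midpoint_pct < wdw[2], , drop = FALSE]
  tw <- pick(ter_window); ow <- pick(ori_window)
  if (nrow(tw) == 0L || nrow(ow) == 0L)
    stop("empty window: terminus n=", nrow(tw), ", origin n=", nrow(ow))
  wmean <- function(d) stats::weighted.mean(d$permissive_fraction, d$length_bp)
  mt <- wmean(tw); mo <- wmean(ow)
  ks <- suppressWarnings(stats::ks.test(tw$permissive_fraction,
                                        ow$permissive_fraction))
  list(loss = mt - mo, ks_p = ks$p.value,
       mean_ter = mt, mean_ori = mo,
       n_ter = nrow(tw), n_ori = nrow(ow),
       ter_window = ter_window, ori_window = ori_window)
}

#' Normalized cumulative inserted-length curve
#'
#' `F(s)` = fraction of the window's total inserted bp contained in
#' fragments whose permissive fraction is at most `s`.
#'
#' @param insertions `insertion_records` with `permissive_fraction`.
#' @param s Evaluation points in `[0, 1]`.
#' @return data.frame with `s` and `F`.
#' @export
cumulative_length_curve <- function(insertions, s = seq(0, 1, by = 0.01)) {
  x <- insertions[!is.na(insertions$permissive_fraction), , drop = FALSE]
  tot <- sum(x$length_bp)
  Fv <- vapply(s, function(si)
    sum(x$length_bp[x$permissive_fraction <= si]) / tot, numeric(1))
  data.frame(s = s, F = Fv)
}
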