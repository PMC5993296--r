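# Monte-Carlo simulation of inversion generation with counter-selection
# by polar Ter-like sites placed in a gradient from terminus to origin.

#' Place Ter-like sites along one chromosome arm
#'
#' Sites are placed from the terminus (position 0 of the arm) outward
#' with inter-site spacings that increase linearly with the site index:
#' `s_k = s_0 * (1 + alpha * (k - 1))`, with `s_0` solved so that the
#' `n` spacings exactly span the arm. The default `alpha` makes the
#' final spacing ten times the first, giving a site density that
#' decreases with distance from the terminus.
#'
#' @param n Number of sites (0 allowed).
#' @param arm_length Arm length in bp.
#' @param alpha Spacing growth per site; default `9 / (n - 1)` (last
#'   spacing = 10 x first). Use `alpha = 0` for uniform spacing.
#' @param scheme `"linear_spacing"` (gradient) or `"uniform_random"`
#'   (iid uniform positions, used by the closed-form checks).
#' @param seed Seed for the random scheme.
#' @return Sorted numeric positions in `(0, arm_length]`, measured from
#'   the terminus.
#' @export
place_ter_sites <- function(n, arm_length, alpha = NULL,
                            scheme = c("linear_spacing", "uniform_random"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 0, arm_length > 0)
  if (n == 0L) return(numeric(0))
  if (scheme == "uniform_random")
    return(sort(with_seed(seed, runif(n, 0, arm_length))))
  if (is.null(alpha)) alpha <- if (n > 1) 9 / (n - 1) else 0
  k <- seq_len(n)
  rel <- 1 + alpha * (k - 1)
  if (any(rel <= 0)) stop("negative spacing; alpha too small")
  s0 <- arm_length / sum(rel)
  cumsum(s0 * rel)
}

#' Configuration for the Ter counter-selection simulation
#'
#' @param genome_length Genome size in bp (default 4.5 Mb).
#' @param n_ter_per_arm Ter-like sites per arm.
#' @param n_inversions Inversions drawn per replicate.
#' @param replicates Number of replicates (default 100000 total
#'   inversions are usually reached via `n_inversions * replicates`).
#' @param size_min,size_max Log-uniform inversion size support
#'   (defaults 1 kb and 500 kb).
#' @param size_fixed Optional fixed inversion length overriding the
#'   log-uniform draw.
#' @param sizes Optional empirical size pool sampled with replacement.
#' @param ter_scheme,alpha Site placement (see [place_ter_sites]).
#' @param ter_sites Optional explicit site positions (bp from the
#'   terminus along the arm), overriding placement.
#' @param bin_pct Width of distance-from-terminus bins (default 2.5).
#' @param seed Seed.
#' @return List of class `ter_sim_config`.
#' @export
ter_sim_config <- function(genome_length = 4500000, n_ter_per_arm = 0,
                           n_inversions = 1000, replicates = 100,
                           size_min = 1000, size_max = 500000,
                           size_fixed = NULL, sizes = NULL,
                           ter_scheme = "linear_spacing", alpha = NULL,
                           ter_sites = NULL, bin_pct = 2.5, seed = NULL) {
  stopifnot(genome_length > 0, n_ter_per_arm >= 0, n_inversions >= 1,
            replicates >= 1, size_min > 0, size_max >= size_min)
  structure(as.list(environment()), class = "ter_sim_config")
}

#' Simulate inversion generation under Ter counter-selection
#'
#' Per replicate, inversions are drawn with uniform midpoints within a
#' uniformly chosen arm and sizes from the configured distribution
#' (truncated so each inversion stays within its arm, matching the
#' arm-restricted class under analysis). An inversion is discarded
#' (counter-selected) when at least one Ter-like site lies strictly
#' inside its span. Surviving inverted bp are accumulated into
#' distance-from-terminus bins.
#'
#' @param config A [ter_sim_config].
#' @return List of class `ter_sim_result`: `bins` (per-bin surviving
#'   inverted bp), `acceptance_rate`, counts, and the config echo.
#' @export
simulate_ter <- function(config) {
  stopifnot(inherits(config, "ter_sim_config"))
  with_seed(config$seed, {
    A <- config$genome_length / 2        # arm length; ter at 0, ori at A
    edges <- seq(0, 50, by = config$bin_pct)
    mids <- head(edges, -1) + config$bin_pct / 2
    bp <- numeric(length(mids))
    acc <- numeric(config$replicates)
    n_prop <- 0L; n_acc <- 0L
    for (rep_i in seq_len(config$replicates)) {
      # each replicate is one simulated genome with its own Ter placement
      sites <- if (!is.null(config$ter_sites)) sort(config$ter_sites)
      else place_ter_sites(config$n_ter_per_arm, A,
                           alpha = config$alpha,
                           scheme = config$ter_scheme)
      nrep <- config$n_inversions
      # midpoint along the arm, measured from the terminus; the two
      # arms are statistically identical, so one arm is simulated.
      mid <- runif(nrep, 0, A)
      maxfit <- 2 * pmin(mid, A - mid)
      if (!is.null(config$size_fixed)) {
        len <- rep(config$size_fixed, nrep)
        keepable <- len <= maxfit
      } else if (!is.null(config$sizes)) {
        len <- sample(config$sizes, nrep, replace = TRUE)
        keepable <- len <= maxfit
      } else {
        lo <- log(config$size_min)
        hi <- pmax(lo, log(pmin(config$size_max, maxfit)))
        len <- exp(runif(nrep, lo, hi))  # log-uniform, truncated to fit
        len <- pmin(len, maxfit)
        keepable <- maxfit >= config$size_min
      }
      a <- mid - len / 2; b <- mid + len / 2
      ok <- keepable & a >= 0 & b <= A
      a <- a[ok]; b <- b[ok]; mid <- mid[ok]; len <- len[ok]
      # reject inversions containing a site strictly inside (a, b)
      if (length(sites)) {
        inside <- findInterval(b - 1e-9, sites) - findInterval(a, sites)
        keep <- inside == 0
      } else keep <- rep(TRUE, length(a))
      pct <- 100 * mid[keep] / config$genome_length
      bin <- pmin(findInterval(pct, edges, rightmost.closed = TRUE),
                  length(mids))
      bp <- bp + vapply(seq_along(mids), function(i)
        sum(len[keep][bin == i]), numeric(1))
      if (rep_i == 1L) cnt <- numeric(length(mids))
      cnt <- cnt + tabulate(bin, nbins = length(mids))
      acc[rep_i] <- mean(keep)
      n_prop <- n_prop + length(a); n_acc <- n_acc + sum(keep)
    }
    structure(list(bins = data.frame(bin_mid_pct = mids, inverted_bp = bp,
                                     n_inversions = cnt),
                   acceptance_rate = n_acc / n_prop,
                   replicate_acceptance = acc,
                   n_proposed = n_prop, n_accepted = n_acc,
                   config = config),
              class = "ter_sim_result")
  })
}

#' Compare a simulated inversion distribution with a reference
#'
#' Distance is the sum of squared differences between the normalized
#' (unit-sum) binned inverted-bp distributions. Optionally searches a
#' grid of Ter-site counts for the best match.
#'
#' @param result A `ter_sim_result` (ignored when `n_grid` given and
#'   `config` supplied).
#' @param reference Numeric vector of reference bin totals (same bins).
#' @param config Optional [ter_sim_config] template for the search.
#' @param n_grid Optional integer vector of `n_ter_per_arm` values to
#'   search.
#' @return List `distance` (for `result`), and when searching,
#'   `search` (data.frame n, distance) and `best_n`.
#' @export
compare_to_reference <- function(result, reference, config = NULL,
                                 n_grid = NULL) {
  ssd <- function(x, y) {
    if (length(x) != length(y)) stop("bin mismatch")
    xn <- x / sum(x); yn <- y / sum(y)
    sum((xn - yn)^2)
  }
  out <- list(distance = if (!is.null(result))
    ssd(result$bins$inverted_bp, reference) else NA_real_)
  if (!is.null(n_grid)) {
    stopifnot(!is.null(config))
    search <- data.frame(n_ter_per_arm = n_grid, distance = NA_real_)
    for (i in seq_along(n_grid)) {
      cfg <- config; cfg$n_ter_per_arm <- n_grid[i]
      cfg$seed <- if (is.null(config$seed)) NULL else config$seed + i
      r <- simulate_ter(cfg)
      search$distance[i] <- ssd(r$bins$inverted_bp, reference)
    }
    out$search <- search
    out$best_n <- search$n_ter_per_arm[which.min(search$distance)]
  }
  out
}
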