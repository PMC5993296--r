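# Replichore geometry: arms, leading-strand predicate, terminus distance.

#' Construct a replichore map
#'
#' Partitions a circular chromosome into its two replichores (arms).
#' Arm 1 runs from `ori` forward (increasing coordinates, wrapping) to
#' `ter`; arm 2 is the complement. On arm 1 the replication fork travels
#' in the increasing-coordinate direction, so a Watson-strand (`+1`)
#' occurrence on arm 1 is on the leading strand; on arm 2 the Crick
#' strand (`-1`) is leading.
#'
#' @param ori,ter Breakpoint positions, 0-based bp. Must differ.
#' @param length Genome length in bp.
#' @param delta Optional pentamer-difference score at the optimum.
#' @param delta_profile Optional data frame of evaluated breakpoint pairs.
#' @param confidence Optional flag (`"ok"`, `"low"`, `"ambiguous"`).
#' @return Object of class `replichore_map`.
#' @export
replichore_map <- function(ori, ter, length, delta = NA_real_,
                           delta_profile = NULL, confidence = "ok") {
  stopifnot(length > 0, ori != ter, ori >= 0, ter >= 0,
            ori < length, ter < length)
  structure(list(ori = as.numeric(ori), ter = as.numeric(ter),
                 length = as.numeric(length), delta = delta,
                 delta_profile = delta_profile, confidence = confidence),
            class = "replichore_map")
}

#' @export
print.replichore_map <- function(x, ...) {
  cat(sprintf("<replichore_map> ori=%s ter=%s length=%s delta=%.4g [%s]\n",
              format(x$ori, big.mark = ","), format(x$ter, big.mark = ","),
              format(x$length, big.mark = ","), x$delta, x$confidence))
  invisible(x)
}

#' Which arm contains a position?
#'
#' @param pos Vector of 0-based positions.
#' @param map A [replichore_map].
#' @return Integer vector: 1 for the ori-to-ter arm (forward), 2 otherwise.
#' @export
arm_of <- function(pos, map) {
  L <- map$length
  ifelse(((pos - map$ori) %% L) < ((map$ter - map$ori) %% L), 1L, 2L)
}

#' Leading-strand predicate
#'
#' @param pos Vector of 0-based positions.
#' @param strand Vector of `+1`/`-1` (Watson/Crick).
#' @param map A [replichore_map].
#' @return Logical: is an occurrence at `pos` on strand `strand` on the
#'   leading strand of its replichore?
#' @export
is_leading <- function(pos, strand, map) {
  (arm_of(pos, map) == 1L) == (strand > 0)
}

#' Distance from the replication terminus
#'
#' Circular distance from `pos` to the terminus along the arm containing
#' `pos`, as a percentage of genome length. For equal arms the origin is
#' at 50; on the longer arm of an unequal-arm genome values exceed 50 and
#' are clamped unless `clamp = FALSE`.
#'
#' @param pos Vector of 0-based positions.
#' @param map A [replichore_map]; must carry a terminus.
#' @param clamp Clamp to `[0, 50]`? Default `TRUE`.
#' @return Numeric vector of percentages.
#' @export
distance_from_terminus <- function(pos, map, clamp = TRUE) {
  if (is.null(map$ter) || is.na(map$ter)) stop("map lacks a terminus")
  L <- map$length
  d <- ifelse(arm_of(pos, map) == 1L,
              (map$ter - pos) %% L,
              (pos - map$ter) %% L)
  pct <- 100 * d / L
  if (clamp) pmin(pct, 50) else pct
}

#' Strand-bias statistic (sup form)
#'
#' The strand-bias of a sequence in a DNA segment of unknown replichore
#' polarity: `max(N_W, N_C) / (N_W + N_C)`, in `[0.5, 1]`. Undefined
#' (flagged, value `NA`) when both counts are zero.
#'
#' @param n_watson,n_crick Non-negative occurrence counts.
#' @return List with `n_watson`, `n_crick`, `value`, `defined`.
#' @export
strand_bias <- function(n_watson, n_crick) {
  stopifnot(n_watson >= 0, n_crick >= 0)
  tot <- n_watson + n_crick
  list(n_watson = n_watson, n_crick = n_crick,
       value = if (tot == 0) NA_real_ else max(n_watson, n_crick) / tot,
       defined = tot > 0)
}

#' Permissive-orientation fraction
#'
#' Fraction of occurrences in the permissive (leading-strand)
#' orientation, in `[0, 1]`; used when the replichore map of the
#' measured DNA is known. Undefined at zero total.
#'
#' @param n_permissive,n_nonpermissive Non-negative counts.
#' @return List with counts, `value` and `defined`.
#' @export
permissive_fraction <- function(n_permissive, n_nonpermissive) {
  stopifnot(n_permissive >= 0, n_nonpermissive >= 0)
  tot <- n_permissive + n_nonpermissive
  list(n_permissive = n_permissive, n_nonpermissive = n_nonpermissive,
       value = if (tot == 0) NA_real_ else n_permissive / tot,
       defined = tot > 0)
}

#' Linearize a circular genome at its terminus
#'
#' Rotates the sequence so the terminus sits at coordinate 0, giving a
#' view in which neither arm wraps the coordinate origin; downstream
#' window arithmetic then needs no special-casing. Feature coordinates
#' and the map are rotated coherently.
#'
#' @param genome A circular [genome].
#' @param map Its [replichore_map].
#' @param features Optional [gene_features] to rotate.
#' @return List `genome`, `map`, `features` (if given), and `offset`
#'   (the rotation applied, bp; original = (new + offset) mod length).
#' @export
linearize_at_terminus <- function(genome, map, features = NULL) {
  L <- genome$length
  off <- map$ter %% L
  s <- as.character(genome_subseq(genome, off, off + L))
  g2 <- genome(genome$id, s, circular = genome$circular)
  m2 <- replichore_map((map$ori - off) %% L, 0, L, map$delta,
                       map$delta_profile, map$confidence)
  out <- list(genome = g2, map = m2, offset = off)
  if (!is.null(features)) {
    f <- features
    f$start <- (f$start - off) %% L
    f$end <- f$start + (features$end - features$start)
    out$features <- f
  }
  out
}

# Intersections of a region [a,b) (percent-from-terminus window or bp
# interval) with each arm, returned as a list of non-wrapping bp
# intervals (0-based half-open, end may exceed L to denote wrap).
arm_intervals <- function(map) {
  L <- map$length
  a1 <- if (map$ter > map$ori) list(c(map$ori, map$ter)) else
    list(c(map$ori, map$ter + L))
  a2 <- if (map$ori > map$ter) list(c(map$ter, map$ori)) else
    list(c(map$ter, map$ori + L))
  list(arm1 = a1[[1]], arm2 = a2[[1]])
}

# Window of +/- half_pct percent of genome length around a focal
# position, split at the focal point into the two flanks so that each
# returned interval lies within a single arm (for ori/ter-centred
# windows). Returns list of c(start, end) 0-based, possibly end > L.
centred_window <- function(centre, half_pct, map) {
  L <- map$length
  h <- L * half_pct / 100
  s <- (centre - h) %% L
  list(c(s, s + 2 * h))
}
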