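# AIMS discovery: strand-biased degenerate octamers whose leading-strand
# abundance and bias increase toward the replication terminus, called
# against a within-arm segment-shuffled null.

# run expr with a temporary RNG state seeded by `seed` (NULL = leave
# the RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Excise insertion spans from a genome
#'
#' Returns the "backbone" genome: the sequence with (merged)
#' horizontally acquired spans removed, together with a coordinate
#' remap table from backbone to original coordinates.
#'
#' @param genome A [genome].
#' @param insertions data.frame with `start`, `end` (0-based half-open
#'   bp spans), or a list of such spans.
#' @return List `genome` (the excised genome), `removed_bp`, and
#'   `remap` (data.frame of kept original intervals in order).
#' @export
backbone_genome <- function(genome, insertions) {
  if (is.null(insertions) || NROW(insertions) == 0L)
    return(list(genome = genome, removed_bp = 0,
                remap = data.frame(start = 0, end = genome$length)))
  sp <- data.frame(start = insertions$start, end = insertions$end)
  stopifnot(all(sp$start >= 0), all(sp$end <= genome$length),
            all(sp$end > sp$start))
  sp <- sp[order(sp$start), , drop = FALSE]
  merged <- sp[1, , drop = FALSE]
  overlapped <- FALSE
  for (i in seq_len(nrow(sp))[-1]) {
    if (sp$start[i] <= merged$end[nrow(merged)]) {
      if (sp$start[i] < merged$end[nrow(merged)]) overlapped <- TRUE
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], sp$end[i])
    } else merged <- rbind(merged, sp[i, ])
  }
  if (overlapped) warning("overlapping insertion spans merged")
  keep_start <- c(0, merged$end)
  keep_end <- c(merged$start, genome$length)
  keep <- data.frame(start = keep_start, end = keep_end)
  keep <- keep[keep$end > keep$start, , drop = FALSE]
  seqs <- lapply(seq_len(nrow(keep)), function(i)
    genome_subseq(genome, keep$start[i], keep$end[i]))
  newseq <- do.call(Biostrings::xscat, seqs)
  list(genome = genome(paste0(genome$id, "_backbone"),
                       as.character(newseq), circular = genome$circular),
       removed_bp = sum(merged$end - merged$start),
       remap = keep)
}

#' Shuffle fixed-size segments within each chromosome arm
#'
#' Randomly permutes `segment_bp` segments within each arm without
#' strand flips and never across arms, preserving genome-wide
#' leading/lagging k-mer counts (up to windows spanning segment
#' junctions). This is the null genome used to calibrate AIMS
#' detection: overall strand-bias is retained but any
#' origin-to-terminus gradient is destroyed.
#'
#' @param genome A [genome].
#' @param map A [replichore_map].
#' @param segment_bp Segment size (default 40000; 10000 is the common
#'   alternative).
#' @param seed Optional integer seed for a reproducible shuffle.
#' @return A shuffled [genome] (same length, same ori/ter).
#' @export
shuffle_arms <- function(genome, map, segment_bp = 40000, seed = NULL) {
  with_seed(seed, {
    L <- genome$length
    arms <- arm_intervals(map)
    shuf <- function(iv) {
      alen <- iv[2] - iv[1]
      s <- as.character(genome_subseq(genome, iv[1] %% L, iv[2]))
      nseg <- floor(alen / segment_bp)
      if (nseg < 2L) {
        warning("arm shorter than two segments; left intact")
        return(s)
      }
      starts <- (seq_len(nseg) - 1L) * segment_bp + 1L
      segs <- substring(s, starts, starts + segment_bp - 1L)
      tailseq <- if (nseg * segment_bp < alen)
        substr(s, nseg * segment_bp + 1L, alen) else ""
      paste0(paste0(segs[sample.int(nseg)], collapse = ""), tailseq)
    }
    s1 <- shuf(arms$arm1); s2 <- shuf(arms$arm2)
    # reassemble: [ori, ter) = arm1, [ter, ori) = arm2
    full <- paste0(s1, s2)               # starts at ori
    shift <- map$ori %% L
    rotated <- paste0(substr(full, L - shift + 1L, L),
                      substr(full, 1L, L - shift))
    genome(paste0(genome$id, "_shuffled"), rotated, circular = genome$circular)
  })
}

# --- count tables -----------------------------------------------------------

#' Leading/lagging octamer count tables for AIMS detection
#'
#' Builds the concrete 4^8 leading- and lagging-strand count vectors
#' genome-wide and within the terminus and origin regions. The terminus
#' region spans `ter_half_pct` percent of the genome on either side of
#' the terminus (default 12.5, i.e. the terminus-proximal 25% of the
#' genome); the origin region spans `ori_half_pct` on either side of
#' the origin (default 30, the origin-proximal 60%).
#'
#' @param genome A [genome] (typically a backbone genome).
#' @param map A [replichore_map].
#' @param ter_half_pct,ori_half_pct Region half-widths, percent.
#' @return List of count vectors and region lengths, class `aims_tables`.
#' @export
aims_count_tables <- function(genome, map, ter_half_pct = 12.5,
                              ori_half_pct = 30) {
  ter_iv <- centred_window(map$ter, ter_half_pct, map)[[1]]
  ori_iv <- centred_window(map$ori, ori_half_pct, map)[[1]]
  gw <- octamer_region_counts(genome, map)
  tr <- octamer_region_counts(genome, map, ter_iv)
  or <- octamer_region_counts(genome, map, ori_iv)
  structure(list(lead_gw = gw$leading, lag_gw = gw$lagging,
                 lead_ter = tr$leading, lag_ter = tr$lagging,
                 lead_ori = or$leading, lag_ori = or$lagging,
                 bp_ter = tr$bp, bp_ori = or$bp, bp_gw = gw$bp,
                 genome_id = genome$id),
            class = "aims_tables")
}

# apply the four AIMS criteria to 6 parallel count vectors; returns the
# indices of qualifying candidates. Division-free with early subsetting
# so the 15M-candidate degenerate space stays cheap.
aims_pass <- function(ld_gw, lg_gw, ld_t, lg_t, ld_o, lg_o,
                      bp_t, bp_o, params) {
  idx <- which(ld_gw >= params$min_copies)
  if (!length(idx)) return(integer(0))
  # (i) genome-wide leading bias
  idx <- idx[ld_gw[idx] >= params$min_bias * (ld_gw[idx] + lg_gw[idx])]
  if (!length(idx)) return(integer(0))
  lt <- ld_t[idx]; gt <- lg_t[idx]; lo <- ld_o[idx]; go <- lg_o[idx]
  keep <- (lt + gt > 0) & (lo + go > 0) &
    # (iii) terminus-region per-bp leading abundance increase
    (lt * bp_o >= (1 + params$min_ter_increase) * lo * bp_t) &
    # (iv) terminus-region bias exceeds origin-region bias
    (lt * (lo + go) > (lo + params$bias_margin * (lo + go)) * (lt + gt))
  idx[keep]
}

# scan the whole <=2-degenerate octamer space against criteria.
# Returns either the total count (collect = FALSE) or a data.frame of
# qualifying octamers with statistics.
scan_degenerate_space <- function(tables, params, collect = TRUE) {
  D <- iupac_membership(params$alphabet)
  vecs <- tables[c("lead_gw", "lag_gw", "lead_ter", "lag_ter",
                   "lead_ori", "lag_ori")]
  grab <- function(ld_gw, lg_gw, ld_t, lg_t, ld_o, lg_o, octs) {
    w <- aims_pass(ld_gw, lg_gw, ld_t, lg_t, ld_o, lg_o,
                   tables$bp_ter, tables$bp_ori, params)
    if (!collect) return(length(w))
    if (length(w) == 0L) return(NULL)
    data.frame(octamer = octs(w),
               n_i = ld_gw[w],
               bias = ld_gw[w] / (ld_gw[w] + lg_gw[w]),
               ter_increase = (ld_t[w] / tables$bp_ter) /
                 (ld_o[w] / tables$bp_ori) - 1,
               ter_bias = ld_t[w] / (ld_t[w] + lg_t[w]),
               ori_bias = ld_o[w] / (ld_o[w] + lg_o[w]),
               stringsAsFactors = FALSE)
  }
  res <- list(); total <- 0L
  # concrete octamers
  r0 <- grab(vecs$lead_gw, vecs$lag_gw, vecs$lead_ter, vecs$lag_ter,
             vecs$lead_ori, vecs$lag_ori, octamer_index_to_string_w)
  if (collect) { if (!is.null(r0)) { r0$n_deg <- 0L; res <- c(res, list(r0)) } }
  else total <- total + r0
  if (params$max_degenerate >= 1L) {
    for (p in 1:8) {
      cc <- lapply(vecs, function(v) contract_counts(v, p, D))
      r <- grab(cc[[1]], cc[[2]], cc[[3]], cc[[4]], cc[[5]], cc[[6]],
                function(w) {
                  rows <- (w - 1L) %% nrow(D) + 1L
                  cols <- (w - 1L) %/% nrow(D) + 1L
                  assemble_octamers(rows, cols, p, params$alphabet)
                })
      if (collect) { if (!is.null(r)) { r$n_deg <- 1L; res <- c(res, list(r)) } }
      else total <- total + r
    }
  }
  if (params$max_degenerate >= 2L) {
    for (p1 in 1:7) for (p2 in (p1 + 1L):8) {
      pos <- c(p1, p2)
      cc <- lapply(vecs, function(v) contract_counts(v, pos, D))
      ns <- nrow(D)
      r <- grab(cc[[1]], cc[[2]], cc[[3]], cc[[4]], cc[[5]], cc[[6]],
                function(w) {
                  rows <- (w - 1L) %% (ns * ns) + 1L
                  cols <- (w - 1L) %/% (ns * ns) + 1L
                  assemble_octamers(rows, cols, pos, params$alphabet)
                })
      if (collect) { if (!is.null(r)) { r$n_deg <- 2L; res <- c(res, list(r)) } }
      else total <- total + r
    }
  }
  if (!collect) return(total)
  if (length(res) == 0L)
    return(data.frame(octamer = character(), n_i = numeric(),
                      bias = numeric(), ter_increase = numeric(),
                      ter_bias = numeric(), ori_bias = numeric(),
                      n_deg = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

octamer_index_to_string_w <- function(w) octamer_index_to_string(w - 1L)

aims_default_params <- function(min_bias = 0.70, min_copies = 96,
                                min_ter_increase = 0.5, bias_margin = 0,
                                max_degenerate = 2L,
                                alphabet = DEGENERATE_SYMBOLS,
                                n_null = 100, enrichment_fold = 10,
                                segment_bp = 40000, seed = NULL) {
  list(min_bias = min_bias, min_copies = min_copies,
       min_ter_increase = min_ter_increase, bias_margin = bias_margin,
       max_degenerate = as.integer(max_degenerate), alphabet = alphabet,
       n_null = n_null, enrichment_fold = enrichment_fold,
       segment_bp = segment_bp, seed = seed)
}

#' Identify AIMS in a backbone genome
#'
#' Scans all octamers degenerate at up to `max_degenerate` positions
#' (full IUPAC alphabet by default) for the four AIMS criteria:
#' (i) genome-wide leading-strand bias at least `min_bias`;
#' (ii) at least `min_copies` leading-strand copies genome-wide;
#' (iii) terminus-region per-bp leading-strand abundance at least
#' `(1 + min_ter_increase)` times the origin-region per-bp abundance;
#' (iv) terminus-region leading-strand bias exceeding the origin-region
#' bias by more than `bias_margin`. The count of qualifying octamers is
#' compared with the counts obtained from `n_null` within-arm
#' segment-shuffled genomes; the fold enrichment (genuine / mean null)
#' calibrates specificity.
#'
#' @param backbone A [genome] with foreign DNA already excised.
#' @param map A [replichore_map].
#' @param min_bias,min_copies,min_ter_increase,bias_margin Detection
#'   thresholds (defaults 0.70, 96, 0.5, 0).
#' @param max_degenerate Maximum ambiguous positions (0-2).
#' @param alphabet Degenerate symbols permitted (default all 11
#'   non-ACGT IUPAC codes; use `"N"` for N-only degeneracy).
#' @param n_null Number of shuffled null genomes (default 100).
#' @param segment_bp Shuffle segment size (default 40000; the 10 kb
#'   variant is selected with `segment_bp = 10000`).
#' @param seed Optional seed for the null shuffles.
#' @param tables Optional precomputed [aims_count_tables] for `backbone`.
#' @return An object of class `aims_set`: data.frame `octamers`
#'   (octamer, N_i, biases, enrichment), `null_counts`, `fold`
#'   (`Inf`-flagged when the null mean is zero), and the parameters.
#' @export
identify_aims <- function(backbone, map, min_bias = 0.70, min_copies = 96,
                          min_ter_increase = 0.5, bias_margin = 0,
                          max_degenerate = 2L,
                          alphabet = DEGENERATE_SYMBOLS,
                          n_null = 100, segment_bp = 40000, seed = NULL,
                          tables = NULL) {
  params <- aims_default_params(min_bias, min_copies, min_ter_increase,
                                bias_margin, max_degenerate, alphabet,
                                n_null, 10, segment_bp, seed)
  if (is.null(tables)) tables <- aims_count_tables(backbone, map)
  octs <- scan_degenerate_space(tables, params, collect = TRUE)
  null_counts <- integer(0)
  if (n_null > 0) {
    null_counts <- with_seed(seed, vapply(seq_len(n_null), function(i) {
      g0 <- shuffle_arms(backbone, map, segment_bp = segment_bp)
      t0 <- aims_count_tables(g0, map)
      scan_degenerate_space(t0, params, collect = FALSE)
    }, integer(1)))
  }
  null_mean <- if (length(null_counts)) mean(null_counts) else NA_real_
  fold <- if (!length(null_counts)) NA_real_
  else if (null_mean == 0) Inf else nrow(octs) / null_mean
  structure(list(octamers = octs, params = params,
                 genome_id = backbone$id,
                 null_counts = null_counts, null_mean = null_mean,
                 fold = fold,
                 zero_null_flag = isTRUE(null_mean == 0) && nrow(octs) > 0),
            class = "aims_set")
}

#' @export
print.aims_set <- function(x, ...) {
  cat(sprintf("<aims_set> %s: %d octamers (fold enrichment %.3g over %d null replicates)\n",
              x$genome_id, nrow(x$octamers), x$fold, length(x$null_counts)))
  invisible(x)
}

#' Calibrate AIMS detection thresholds
#'
#' Evaluates a grid of `(min_ter_increase, min_bias)` operating points,
#' reporting for each the genuine octamer count, the null mean and
#' standard deviation over shuffled genomes, and the fold enrichment.
#' The chosen operating point is the least stringent one achieving at
#' least `min_fold` enrichment and more than `min_genuine` genuine
#' octamers. Two conventional operating points are also reported when
#' available: (a) the qualifying point with the weakest abundance
#' increase (most abundant AIMS) and (b) the one with the strongest
#' increase (fewer, strongly graded AIMS).
#'
#' @param backbone A [genome].
#' @param map A [replichore_map].
#' @param ter_increase_grid,bias_grid Numeric grids.
#' @param min_fold Required genuine/null fold (default 10).
#' @param min_genuine Required genuine count (default 100).
#' @param n_null,segment_bp,seed,max_degenerate,alphabet,min_copies As
#'   in [identify_aims].
#' @return List with the calibration `table`, the `chosen` row (or
#'   `NULL` if no point qualifies), and rows `point_abundant` /
#'   `point_graded`.
#' @export
calibrate_thresholds <- function(backbone, map,
                                 ter_increase_grid = c(0.25, 0.5, 1, 2),
                                 bias_grid = c(0.70, 0.80),
                                 min_fold = 10, min_genuine = 100,
                                 min_copies = 96, n_null = 20,
                                 segment_bp = 40000, seed = NULL,
                                 max_degenerate = 2L,
                                 alphabet = DEGENERATE_SYMBOLS) {
  stopifnot(length(ter_increase_grid) > 0, length(bias_grid) > 0)
  tables <- aims_count_tables(backbone, map)
  null_tables <- with_seed(seed, lapply(seq_len(n_null), function(i)
    aims_count_tables(shuffle_arms(backbone, map, segment_bp = segment_bp),
                      map)))
  grid <- expand.grid(min_ter_increase = ter_increase_grid,
                      min_bias = bias_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- aims_default_params(min_bias = grid$min_bias[i],
                                  min_copies = min_copies,
                                  min_ter_increase = grid$min_ter_increase[i],
                                  max_degenerate = max_degenerate,
                                  alphabet = alphabet)
    genuine <- scan_degenerate_space(tables, params, collect = FALSE)
    nulls <- vapply(null_tables, function(t0)
      scan_degenerate_space(t0, params, collect = FALSE), integer(1))
    nm <- mean(nulls)
    data.frame(min_ter_increase = grid$min_ter_increase[i],
               min_bias = grid$min_bias[i],
               genuine = genuine, null_mean = nm, null_sd = sd(nulls),
               fold = if (nm == 0) Inf else genuine / nm)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$fold >= min_fold & tab$genuine > min_genuine
  chosen <- NULL; pa <- NULL; pg <- NULL
  if (any(ok)) {
    qual <- tab[ok, , drop = FALSE]
    # least stringent: lowest bias, then lowest abundance-increase
    qual <- qual[order(qual$min_bias, qual$min_ter_increase), , drop = FALSE]
    chosen <- qual[1, ]
    pa <- qual[which.min(qual$min_ter_increase), ]
    pg <- qual[which.max(qual$min_ter_increase), ]
  }
  list(table = tab, chosen = chosen,
       point_abundant = pa, point_graded = pg)
}

# --- clustering -------------------------------------------------------------

iupac_sets <- function() lapply(Biostrings::IUPAC_CODE_MAP,
                                function(x) strsplit(x, "")[[1]])

# do two IUPAC strings of equal length have overlapping concrete match
# sets (non-empty base-set intersection at every position)?
iupac_compatible <- function(a, b) {
  sets <- iupac_sets()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  all(vapply(seq_along(ca), function(i)
    length(intersect(sets[[ca[i]]], sets[[cb[i]]])) > 0, logical(1)))
}

aims_linked <- function(a, b) {
  if (iupac_compatible(a, b)) return(TRUE)
  # 7-mer overlap: suffix of one vs prefix of the other
  iupac_compatible(substr(a, 2, 8), substr(b, 1, 7)) ||
    iupac_compatible(substr(b, 2, 8), substr(a, 1, 7))
}

# concrete expansions of an IUPAC string (per-position base sets)
iupac_expand <- function(s) {
  sets <- iupac_sets()
  cs <- strsplit(s, "")[[1]]
  grid <- expand.grid(lapply(cs, function(ch) sets[[ch]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1L, paste0, collapse = "")
}

#' Cluster AIMS into families
#'
#' Single-linkage clustering: two octamers are linked if their concrete
#' match sets overlap (equivalently, they share a concrete expansion),
#' or if a 7-mer suffix of one is compatible with a 7-mer prefix of the
#' other (equivalently, a concrete suffix expansion of one equals a
#' concrete prefix expansion of the other). Implemented as union-find
#' over shared concrete keys, so the result is independent of input
#' order.
#'
#' @param aims An `aims_set` or character vector of IUPAC octamers.
#' @return Integer family ids parallel to the input octamers (families
#'   numbered by first occurrence in sorted octamer order).
#' @export
cluster_aims <- function(aims) {
  octs <- if (inherits(aims, "aims_set")) aims$octamers$octamer else aims
  n <- length(octs)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  link <- function(a, b) {
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  union_groups <- function(ids) {
    ids <- unique(ids)
    if (length(ids) > 1L) for (j in seq_along(ids)[-1]) link(ids[1L], ids[j])
  }
  ex8 <- lapply(octs, iupac_expand)
  for (grp in split(rep(seq_len(n), lengths(ex8)), unlist(ex8)))
    union_groups(grp)
  pre <- lapply(octs, function(s) iupac_expand(substr(s, 1L, 7L)))
  suf <- lapply(octs, function(s) iupac_expand(substr(s, 2L, 8L)))
  pmap <- split(rep(seq_len(n), lengths(pre)), unlist(pre))
  smap <- split(rep(seq_len(n), lengths(suf)), unlist(suf))
  for (key in intersect(names(pmap), names(smap)))
    union_groups(c(pmap[[key]], smap[[key]]))
  roots <- vapply(seq_len(n), findp, integer(1))
  # renumber by sorted-octamer first appearance
  ord <- order(octs)
  fam <- integer(n)
  seen <- integer(0)
  for (ii in seq_len(n)) {
    r <- roots[ord[ii]]
    if (!r %in% seen) seen <- c(seen, r)
    fam[ord[ii]] <- match(r, seen)
  }
  fam
}

#' One representative octamer per AIMS family
#'
#' Qualifying octamers fall into families of related, overlapping
#' patterns (selection acting on a longer degenerate sequence). For
#' downstream per-AIMS work (permissive-fraction annotation,
#' compatibility scoring) a compact set with one representative per
#' family — the member with the largest leading-strand abundance,
#' ties broken lexicographically — stands in for the full halo.
#'
#' @param aims An `aims_set`.
#' @return data.frame with one row per family (`octamer`, `n_i`,
#'   `bias`, `family`, `family_size`).
#' @export
aims_representatives <- function(aims) {
  octs <- aims$octamers
  if (nrow(octs) == 0L) return(octs)
  fam <- if (!is.null(octs$family)) octs$family else cluster_aims(aims)
  octs$family <- fam
  o <- order(fam, -octs$n_i, octs$octamer)
  top <- octs[o, ][!duplicated(fam[o]), , drop = FALSE]
  top$family_size <- as.integer(table(fam)[as.character(top$family)])
  rownames(top) <- NULL
  top
}

# --- serialization ----------------------------------------------------------

#' Write an AIMS set to JSON
#' @param aims An `aims_set`.
#' @param path Output path.
#' @export
write_aims_set <- function(aims, path) {
  jsonlite::write_json(list(schema = "aims_set/1",
                            genome_id = aims$genome_id,
                            params = aims$params[c("min_bias", "min_copies",
                                                   "min_ter_increase",
                                                   "bias_margin",
                                                   "max_degenerate",
                                                   "segment_bp")],
                            octamers = aims$octamers,
                            null_counts = aims$null_counts,
                            fold = aims$fold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AIMS set from JSON
#' @param path Input path.
#' @return An `aims_set`.
#' @export
read_aims_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(octamers = as.data.frame(x$octamers),
                 params = x$params, genome_id = x$genome_id,
                 null_counts = x$null_counts,
                 null_mean = if (length(x$null_counts)) mean(x$null_counts) else NA_real_,
                 fold = x$fold, zero_null_flag = FALSE),
            class = "aims_set")
}
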