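# Synthetic circular genomes with planted architecture: replichore-
# dependent codon composition, gradient-planted AIMS, and sister
# genomes carrying planted inversions and foreign insertions. Every
# planted feature is recorded in a truth table that is re-verified
# against the emitted sequence at generation time.

#' Specification for a synthetic genome
#'
#' Defaults describe a moderate-signal bacterial chromosome: equal
#' replichores, 75% of genes transcribed from the leading strand, and a
#' codon-composition asymmetry between leading- and lagging-strand
#' genes that produces a frame-specific pentamer signal.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of the intergenic background.
#' @param gene_length Coding length per gene, bp (multiple of 3).
#' @param intergenic_bp Mean intergenic gap.
#' @param leading_fraction Probability a gene is leading-strand.
#' @param pentamer_effect Codon-composition asymmetry between strand
#'   classes, in `[0, 1)`.
#' @param ori,ter Planted breakpoints (defaults 0 and `length / 2`).
#' @param aims_plants Optional data.frame with columns `octamer`,
#'   `a_ori`, `a_ter` (copies per 10 kb at the origin and terminus; the
#'   density interpolates linearly in distance-from-terminus) and
#'   `p_ori`, `p_ter` (leading-strand probability at each end). See
#'   [gradient_aims_plants].
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(length = 2e6, gc = 0.5, gene_length = 900,
                       intergenic_bp = 150, leading_fraction = 0.75,
                       pentamer_effect = 0.25, ori = 0, ter = length / 2,
                       aims_plants = NULL) {
  stopifnot(length > 10 * (gene_length + intergenic_bp),
            gc > 0, gc < 1, gene_length %% 3 == 0,
            leading_fraction >= 0, leading_fraction <= 1,
            pentamer_effect >= 0, pentamer_effect < 1)
  if (!is.null(aims_plants)) {
    stopifnot(all(c("octamer", "a_ori", "a_ter", "p_ori", "p_ter") %in%
                    names(aims_plants)),
              all(aims_plants$a_ter >= aims_plants$a_ori),
              all(aims_plants$a_ori >= 0),
              all(aims_plants$p_ori >= 0 & aims_plants$p_ter <= 1))
  }
  structure(as.list(environment()), class = "plant_spec")
}

#' Standard gradient AIMS plant list
#'
#' `n` random concrete octamers planted with a linear
#' origin-to-terminus abundance gradient (`a_ori` to `a_ter` copies per
#' 10 kb) and a linear leading-strand bias gradient (`p_ori` to
#' `p_ter`). The defaults give each octamer roughly a two-fold
#' terminus-region leading-strand density increase and a genome-wide
#' planted bias of about 0.85.
#'
#' @param n Number of octamers.
#' @param a_ori,a_ter Copies per 10 kb at origin / terminus.
#' @param p_ori,p_ter Leading-strand probability at origin / terminus.
#' @param seed Seed for octamer choice.
#' @return data.frame accepted by [plant_spec].
#' @export
gradient_aims_plants <- function(n = 20, a_ori = 0.45, a_ter = 1.8,
                                 p_ori = 0.75, p_ter = 0.95, seed = 1) {
  octs <- with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      w <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                 collapse = "")
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
      if (!w %in% out && !rc %in% out && w != rc) out <- c(out, w)
    }
    out
  })
  data.frame(octamer = octs, a_ori = a_ori, a_ter = a_ter,
             p_ori = p_ori, p_ter = p_ter, stringsAsFactors = FALSE)
}

# two codon-frequency vectors for the leading/lagging strand classes
strand_codon_freqs <- function(effect, gc) {
  gcode <- GENETIC_CODE_TABLE()
  sense <- names(gcode)[gcode != "*"]
  gcw <- vapply(sense, function(cd) {
    s <- strsplit(cd, "")[[1]]
    ngc <- sum(s %in% c("G", "C"))
    (gc / 0.5)^ngc * ((1 - gc) / 0.5)^(3 - ngc)
  }, numeric(1))
  q <- gcw / sum(gcw)
  delta <- rep(c(1, -1), length.out = length(sense))   # fixed pattern
  ql <- q * (1 + effect * delta); ql <- ql / sum(ql)
  qg <- q * (1 - effect * delta); qg <- qg / sum(qg)
  list(sense = sense, leading = ql, lagging = qg)
}

#' Generate a synthetic genome with planted architecture
#'
#' Builds a circular genome of i.i.d. background at the requested GC,
#' lays down non-overlapping genes whose strand follows the
#' leading-strand fraction and whose codons are drawn from
#' strand-class-specific frequencies (the pentamer signal), then
#' injects AIMS copies at positions drawn from the planted linear
#' abundance gradient, each copy oriented to the leading strand with
#' the planted position-dependent probability. Truth counts are
#' re-measured from the emitted sequence and checked against the
#' injection log.
#'
#' @param spec A [plant_spec].
#' @param seed Integer seed.
#' @return List: `genome`, `features`, `map` (the planted
#'   [replichore_map]), and `truth` (injection log, per-octamer
#'   recounts, parameters).
#' @export
generate_genome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(seed, {
    L <- as.integer(spec$length)
    map <- replichore_map(spec$ori, spec$ter, L)
    codes <- c(65L, 67L, 71L, 84L)       # A C G T
    probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
               (1 - spec$gc) / 2)
    seq_int <- sample(codes, L, replace = TRUE, prob = probs)

    # gene layout
    glen <- spec$gene_length
    step <- glen + spec$intergenic_bp
    starts <- seq(spec$intergenic_bp %/% 2, L - glen - 1L, by = step)
    n_genes <- length(starts)
    mids <- starts + glen / 2
    arm <- arm_of(mids, map)
    leading <- runif(n_genes) < spec$leading_fraction
    strand <- ifelse(leading == (arm == 1L), 1L, -1L)

    cf <- strand_codon_freqs(spec$pentamer_effect, spec$gc)
    ncod <- glen %/% 3L
    codon_ints <- lapply(cf$sense, function(cd) utf8ToInt(cd))
    for (i in seq_len(n_genes)) {
      pr <- if (leading[i]) cf$leading else cf$lagging
      idx <- sample.int(length(cf$sense), ncod, replace = TRUE, prob = pr)
      gene_int <- unlist(codon_ints[idx], use.names = FALSE)
      if (strand[i] < 0) {
        comp <- c(`65` = 84L, `67` = 71L, `71` = 67L, `84` = 65L)
        gene_int <- rev(unname(comp[as.character(gene_int)]))
      }
      seq_int[(starts[i] + 1L):(starts[i] + glen)] <- gene_int
    }
    features <- gene_features(sprintf("g%05d", seq_len(n_genes)),
                              starts, starts + glen, strand)

    # AIMS planting
    injection <- NULL
    occupied <- logical(L)
    if (!is.null(spec$aims_plants)) {
      ap <- spec$aims_plants
      rows <- list()
      for (j in seq_len(nrow(ap))) {
        dens <- function(d) ap$a_ter[j] + (ap$a_ori[j] - ap$a_ter[j]) * d / 50
        pbias <- function(d) ap$p_ter[j] + (ap$p_ori[j] - ap$p_ter[j]) * d / 50
        total <- round((ap$a_ori[j] + ap$a_ter[j]) / 2 * L / 1e4)
        amax <- max(ap$a_ori[j], ap$a_ter[j])
        placed <- 0L; lead_placed <- 0L
        pos_list <- integer(0); str_list <- integer(0)
        attempts <- 0L
        woct <- utf8ToInt(ap$octamer[j])
        roct <- utf8ToInt(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ap$octamer[j]))))
        while (placed < total && attempts < 100L * total) {
          attempts <- attempts + 1L
          x <- sample.int(L - 8L, 1L) - 1L
          d <- distance_from_terminus(x, map)
          if (runif(1) > dens(d) / amax) next
          if (any(occupied[(x + 1L):(x + 8L)])) next
          lead <- runif(1) < pbias(d)
          watson_is_leading <- arm_of(x, map) == 1L
          on_watson <- (lead == watson_is_leading)
          seq_int[(x + 1L):(x + 8L)] <- if (on_watson) woct else roct
          occupied[(x + 1L):(x + 8L)] <- TRUE
          placed <- placed + 1L
          lead_placed <- lead_placed + as.integer(lead)
          pos_list <- c(pos_list, x)
          str_list <- c(str_list, if (on_watson) 1L else -1L)
        }
        rows[[j]] <- data.frame(octamer = ap$octamer[j],
                                n_injected = placed,
                                n_lead_injected = lead_placed,
                                stringsAsFactors = FALSE)
      }
      injection <- do.call(rbind, rows)
    }

    g <- genome(sprintf("synth_seed%d", seed), intToUtf8(seq_int),
                circular = TRUE)

    recounts <- NULL
    if (!is.null(injection)) {
      recounts <- do.call(rbind, lapply(seq_len(nrow(injection)), function(j) {
        cnt <- count_octamer(g, map, injection$octamer[j])
        data.frame(octamer = injection$octamer[j],
                   n_leading = cnt$n_leading, n_lagging = cnt$n_lagging)
      }))
      # emit-time self-check: recounts must cover every injected copy
      tot <- recounts$n_leading + recounts$n_lagging
      if (any(tot < injection$n_injected))
        stop("truth-table inconsistency: recount below injection count")
    }
    list(genome = g, features = features, map = map,
         truth = list(injection = injection, recounts = recounts,
                      spec = spec, seed = seed,
                      leading_genes = leading))
  })
}

# shift positions by accumulated insertion lengths
shift_positions <- function(pos, ins_at, ins_len) {
  if (length(ins_at) == 0L) return(pos)
  o <- order(ins_at)
  ins_at <- ins_at[o]; ins_len <- ins_len[o]
  pos + vapply(pos, function(p) sum(ins_len[ins_at <= p]), numeric(1))
}

#' Derive a sister genome with planted inversions and insertions
#'
#' Applies point substitutions at the requested per-site rate, reverses
#' (and strand-flips) planted blocks of consecutive genes that never
#' span the origin or terminus, and inserts novel foreign segments
#' carrying the recipient's AIMS at a controlled permissive
#' probability. Emits a homology table consistent with construction:
#' native genes have reciprocal-best orthologs in the parent (as a
#' sister species) and in two pseudo conspecific strains; inserted
#' genes have no ortholog anywhere and a sub-threshold best conspecific
#' similarity.
#'
#' @param parent Output of [generate_genome].
#' @param divergence Substitutions per site (< 0.1).
#' @param n_inversions Number of planted inversions.
#' @param inv_genes Range `c(min, max)` of genes per inversion.
#' @param n_insertions Number of planted foreign insertions.
#' @param ins_genes Genes per insertion.
#' @param ins_gene_bp Length of each foreign gene.
#' @param ins_aims Character vector of octamers planted inside
#'   insertions (typically the recipient's planted AIMS).
#' @param ins_aims_per_kb Planted AIMS occurrences per kb of insertion.
#' @param permissive_p Function of distance-from-terminus percent
#'   giving the probability an occurrence is placed in the permissive
#'   (leading) orientation; default a linear gradient from 0.55 at the
#'   origin to 0.90 at the terminus.
#' @param seed Integer seed.
#' @return List: `genome`, `features`, `map`, `homology`, and `truth`
#'   (planted inversion and insertion tables in sister coordinates).
#' @export
derive_sister <- function(parent, divergence = 0.01,
                          n_inversions = 0, inv_genes = c(3, 8),
                          n_insertions = 0, ins_genes = 3,
                          ins_gene_bp = 900, ins_aims = character(0),
                          ins_aims_per_kb = 2,
                          permissive_p = function(d) 0.55 + 0.35 * (1 - d / 50),
                          seed = 1) {
  stopifnot(divergence < 0.1)
  with_seed(seed, {
    L <- parent$genome$length
    map <- parent$map
    seq_int <- utf8ToInt(as.character(parent$genome$sequence))
    feats <- parent$features
    comp <- c(`65` = 84L, `67` = 71L, `71` = 67L, `84` = 65L)

    # substitutions
    nmut <- rbinom(1, L, divergence)
    if (nmut > 0) {
      at <- sample.int(L, nmut)
      for (p in at) {
        cur <- seq_int[p]
        seq_int[p] <- sample(setdiff(c(65L, 67L, 71L, 84L), cur), 1L)
      }
    }

    # planted inversions: blocks of consecutive genes within one arm
    inv_truth <- NULL
    if (n_inversions > 0) {
      o <- order(feats$start)
      f <- feats[o, , drop = FALSE]
      n <- nrow(f)
      arm <- arm_of((f$start + f$end) / 2, map)
      taken <- rep(FALSE, n)
      recs <- list()
      tries <- 0L
      while (length(recs) < n_inversions && tries < 1000L) {
        tries <- tries + 1L
        k <- sample(inv_genes[1]:inv_genes[2], 1L)
        i <- sample.int(n - k, 1L)
        idx <- i:(i + k - 1L)
        # guard zone so flanking synteny is never consumed
        zone <- max(1L, i - 3L):min(n, i + k + 2L)
        if (any(taken[zone])) next
        if (length(unique(arm[idx])) > 1L) next
        s <- f$start[i]; e <- f$end[i + k - 1L]
        if (span_contains(c(s, e), map$ori, L) ||
            span_contains(c(s, e), map$ter, L)) next
        # also require flank genes on the same arm (no ori/ter adjacency)
        if (i == 1L || (i + k) > n) next
        taken[zone] <- TRUE
        seq_int[(s + 1L):e] <- rev(unname(comp[as.character(
          seq_int[(s + 1L):e])]))
        # remap features inside the block
        for (jj in idx) {
          os <- f$start[jj]; oe <- f$end[jj]
          f$start[jj] <- s + (e - oe)
          f$end[jj] <- s + (e - os)
          f$strand[jj] <- -f$strand[jj]
        }
        recs[[length(recs) + 1L]] <-
          data.frame(start = s, end = e, n_genes = k,
                     genes = paste(sort(f$gene_id[idx]), collapse = ","),
                     midpoint_pct = distance_from_terminus(((s + e) / 2) %% L,
                                                           map),
                     stringsAsFactors = FALSE)
      }
      inv_truth <- if (length(recs)) do.call(rbind, recs) else NULL
      feats <- f
    }

    # planted insertions (after inversions; coordinates then shift)
    ins_truth <- NULL
    homology_extra <- NULL
    if (n_insertions > 0) {
      gaps_after <- order(feats$start)
      fo <- feats[gaps_after, , drop = FALSE]
      gap_pos <- (fo$end[-nrow(fo)] + fo$start[-1]) %/% 2L
      gap_pos <- gap_pos[gap_pos > 0]
      sites <- sort(sample(gap_pos, n_insertions))
      ins_len <- ins_genes * ins_gene_bp
      newseq <- list(); newfeat <- list(); recs <- list()
      shift <- 0L
      gid <- 0L
      pieces <- list(); lastcut <- 0L
      for (si in seq_along(sites)) {
        x <- sites[si]
        d <- distance_from_terminus(x, map)
        watson_is_leading <- arm_of(x, map) == 1L
        frag <- sample(c(65L, 67L, 71L, 84L), ins_len, replace = TRUE)
        n_occ_target <- max(1L, round(ins_aims_per_kb * ins_len / 1000))
        occ_log <- integer(0)
        if (length(ins_aims)) {
          slots <- seq(1L, ins_len - 8L, by = max(10L, ins_len %/%
                                                    (n_occ_target + 1L)))
          slots <- head(slots[-1], n_occ_target)
          for (sl in slots) {
            w <- sample(ins_aims, 1L)
            lead <- runif(1) < permissive_p(d)
            on_watson <- (lead == watson_is_leading)
            oi <- utf8ToInt(if (on_watson) w else
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(w))))
            frag[sl:(sl + 7L)] <- oi
            occ_log <- c(occ_log, as.integer(lead))
          }
        }
        pieces[[length(pieces) + 1L]] <- seq_int[(lastcut + 1L):x]
        pieces[[length(pieces) + 1L]] <- frag
        lastcut <- x
        gstart <- x + shift
        for (gi in seq_len(ins_genes)) {
          gid <- gid + 1L
          newfeat[[length(newfeat) + 1L]] <-
            data.frame(gene_id = sprintf("hgt%04d", gid),
                       start = gstart + (gi - 1L) * ins_gene_bp,
                       end = gstart + gi * ins_gene_bp,
                       strand = 1L, kind = "CDS",
                       stringsAsFactors = FALSE)
        }
        recs[[si]] <- data.frame(start = gstart, end = gstart + ins_len,
                                 n_genes = ins_genes,
                                 midpoint_pct = d,
                                 planted_permissive = if (length(occ_log))
                                   mean(occ_log) else NA_real_,
                                 n_planted_occ = length(occ_log),
                                 stringsAsFactors = FALSE)
        shift <- shift + ins_len
      }
      pieces[[length(pieces) + 1L]] <- seq_int[(lastcut + 1L):L]
      seq_int <- unlist(pieces, use.names = FALSE)
      # shift native features and the map
      feats$start <- as.integer(shift_positions(feats$start, sites, rep(ins_len, length(sites))))
      feats$end <- as.integer(shift_positions(feats$end - 1L, sites,
                                              rep(ins_len, length(sites))) + 1L)
      nf <- do.call(rbind, newfeat)
      feats <- rbind(as.data.frame(feats), nf)
      class(feats) <- c("gene_features", "data.frame")
      newL <- length(seq_int)
      map <- replichore_map(shift_positions(map$ori, sites, rep(ins_len, length(sites))),
                            shift_positions(map$ter, sites, rep(ins_len, length(sites))),
                            newL)
      ins_truth <- do.call(rbind, recs)
    }

    g <- genome(paste0(parent$genome$id, "_sister"), intToUtf8(seq_int),
                circular = TRUE)
    # emit-time check: recorded insertion spans carry the planted genes
    if (!is.null(ins_truth)) {
      stopifnot(all(ins_truth$end <= g$length))
    }

    # homology table: queries = sister genes
    native <- grepl("^g", feats$gene_id)
    sim_native <- pmax(0, pmin(100, 100 * (1 - divergence) -
                                 abs(rnorm(sum(native), 0, 0.5))))
    mk <- function(q, subj_genome, subj_gene, sim, rb)
      data.frame(query_gene = q, subject_genome = subj_genome,
                 subject_gene = subj_gene, similarity = sim,
                 coverage = 95, reciprocal_best = rb,
                 stringsAsFactors = FALSE)
    hom <- rbind(
      mk(feats$gene_id[native], "sister_sp", feats$gene_id[native],
         sim_native, TRUE),
      mk(feats$gene_id[native], "strain_1", feats$gene_id[native],
         pmin(100, sim_native + 1), TRUE),
      mk(feats$gene_id[native], "strain_2", feats$gene_id[native],
         pmin(100, sim_native + 1), TRUE))
    if (any(!native)) {
      nn <- sum(!native)
      hom <- rbind(hom,
                   mk(feats$gene_id[!native], "sister_sp", NA_character_,
                      0, FALSE),
                   mk(feats$gene_id[!native], "strain_1", NA_character_,
                      0, FALSE),
                   mk(feats$gene_id[!native], "strain_2",
                      paste0("weak", seq_len(nn)),
                      runif(nn, 20, 35), FALSE))
    }
    list(genome = g, features = feats, map = map, homology = hom,
         truth = list(inversions = inv_truth, insertions = ins_truth,
                      divergence = divergence, seed = seed))
  })
}
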