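# Shared fixtures and independent oracles used across test files.

random_seq <- function(n, seed = NULL, gc = 0.5) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# minimal local stand-in for withr::with_seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Naive position-by-position IUPAC scan oracle (both strands).
# Returns data.frame(pos [0-based], strand).
naive_motif_scan <- function(seq_chr, pattern, max_mismatch = 0,
                             circular = FALSE) {
  sets <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])
  scan_one <- function(subject, pat) {
    k <- nchar(pat)
    pchars <- strsplit(pat, "")[[1]]
    L <- nchar(subject)
    s <- if (circular) paste0(subject, substr(subject, 1, k - 1)) else subject
    hits <- integer(0)
    for (i in seq_len(if (circular) L else L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      wc <- strsplit(w, "")[[1]]
      mm <- sum(vapply(seq_len(k), function(j)
        !(wc[j] %in% sets[[pchars[j]]]), logical(1)))
      if (mm <= max_mismatch) hits <- c(hits, i - 1L)
    }
    hits
  }
  fw <- scan_one(seq_chr, pattern)
  rv <- scan_one(seq_chr, revcomp_chr(pattern))
  rbind(data.frame(pos = fw, strand = rep(1L, length(fw))),
        data.frame(pos = rv, strand = rep(-1L, length(rv))))
}

# Brute-force pentamer enumeration oracle: frame-specific counts of one
# coding sequence, returned as a named table "frame:pentamer" -> count.
naive_pentamer_counts <- function(seq_chr) {
  n <- nchar(seq_chr)
  out <- list()
  if (n < 5) return(out)
  for (i in seq_len(n - 4)) {
    w <- substr(seq_chr, i, i + 4)
    if (grepl("[^ACGT]", w)) next
    key <- paste0((i - 1) %% 3, ":", w)
    out[[key]] <- (out[[key]] %||% 0) + 1
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive signed-permutation inversion oracle: tests every
# contiguous block of a's order for reversal + sign flip relative to b,
# with flank_k syntenic bridging genes on each side (circular).
oracle_inversions <- function(a, b, flank_k = 2) {
  shared <- intersect(a$gene, b$gene)
  a <- a[a$gene %in% shared, , drop = FALSE]
  b <- b[b$gene %in% shared, , drop = FALSE]
  n <- nrow(a)
  posB <- match(a$gene, b$gene)
  rels <- a$sign * b$sign[posB]
  modn <- function(x) ((x - 1L) %% n) + 1L
  res <- list()
  if (n < 2 * flank_k + 1) return(res)
  for (s in 1:n) for (len in 1:(n - 2 * flank_k)) {
    block <- modn(s + 0:(len - 1))
    # block must be reversed (q decreasing by 1) and sign-flipped
    if (any(rels[block] != -1L)) next
    qs <- posB[block]
    if (len > 1 && any(modn(qs[-1]) != modn(qs[-len] - 1L))) next
    lf <- modn(s - 1:flank_k); rf <- modn(s + len - 1 + 1:flank_k)
    if (length(intersect(c(lf, rf), block)) > 0) next
    if (any(rels[c(lf, rf)] != 1L)) next
    # bridging: left flank precedes the reversed block in b, right
    # flank follows it
    if (modn(posB[lf[1]]) != modn(posB[block[len]] - 1L)) next
    if (modn(posB[rf[1]]) != modn(posB[block[1]] + 1L)) next
    okf <- TRUE
    if (flank_k > 1) for (k in 1:(flank_k - 1)) {
      if (modn(posB[lf[k + 1]]) != modn(posB[lf[k]] - 1L)) okf <- FALSE
      if (modn(posB[rf[k + 1]]) != modn(posB[rf[k]] + 1L)) okf <- FALSE
    }
    if (!okf) next
    res[[length(res) + 1L]] <- sort(a$gene[block])
  }
  unique(lapply(res, identity))
}

# random signed circular permutation with one planted inverted block
plant_signed_inversion <- function(n_genes, block_len, seed) {
  withr_seed(seed, {
    genes <- sprintf("G%03d", 1:n_genes)
    a <- data.frame(gene = genes, sign = sample(c(1L, -1L), n_genes, TRUE),
                    stringsAsFactors = FALSE)
    b <- a
    # choose a block away from the wrap point for simplicity of truth
    s <- sample(3:(n_genes - block_len - 2), 1)
    idx <- s:(s + block_len - 1)
    b$gene[idx] <- rev(a$gene[idx])
    b$sign[idx] <- -rev(a$sign[idx])
    list(a = a, b = b, truth = sort(a$gene[idx]))
  })
}

# small two-arm genome + map for octamer tests
tiny_map_genome <- function(n = 20000, seed = 1) {
  g <- genome("tiny", random_seq(n, seed = seed))
  list(genome = g, map = replichore_map(0, n / 2, n))
}

# naive per-occurrence leading/lagging octamer count oracle
naive_octamer_count <- function(seq_chr, map, octamer, region = NULL) {
  L <- nchar(seq_chr)
  hits <- naive_motif_scan(seq_chr, octamer, circular = TRUE)
  if (!is.null(region)) {
    s <- region[1] %% L; len <- region[2] - region[1]
    hits <- hits[((hits$pos - s) %% L) < len, , drop = FALSE]
  }
  lead <- is_leading(hits$pos, hits$strand, map)
  list(n_leading = sum(lead), n_lagging = sum(!lead))
}

# build a donor with an octamer planted at fixed positions/strands and
# no coincidental background occurrences
planted_donor <- function(n, w, positions, strands, seed) {
  repeat {
    s <- random_seq(n, seed = seed)
    v <- strsplit(s, "")[[1]]
    rc <- revcomp_chr(w)
    for (i in seq_along(positions)) {
      x <- positions[i]
      v[(x + 1):(x + 8)] <- strsplit(if (strands[i] > 0) w else rc, "")[[1]]
    }
    s2 <- paste(v, collapse = "")
    hits <- naive_motif_scan(s2, w, circular = TRUE)
    if (nrow(hits) == length(positions)) return(genome("donor", s2))
    seed <- seed + 1000
  }
}
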