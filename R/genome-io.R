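# Containers and file readers for genomes, gene features and homology tables.

#' Construct a genome object
#'
#' A light container for a single (by default circular) bacterial
#' chromosome. Sequences are stored uppercase over the alphabet
#' `{A,C,G,T,N}`; anything else is mapped to `N` with a warning.
#'
#' @param id Non-empty identifier.
#' @param sequence Nucleotide string.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return An object of class `genome` with fields `id`, `sequence`
#'   (a [Biostrings::DNAString]), `circular` and `length`.
#' @export
genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    warning(sprintf("genome '%s': %d non-ACGTN characters mapped to N",
                    id, nchar(bad)))
    sequence <- chartr(paste(unique(strsplit(bad, "")[[1]]), collapse = ""),
                       strrep("N", length(unique(strsplit(bad, "")[[1]]))),
                       sequence)
  }
  structure(list(id = id,
                 sequence = Biostrings::DNAString(sequence),
                 circular = isTRUE(circular),
                 length = nchar(sequence)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.genome <- function(x) x$length

#' Read genomes from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, applied to every record.
#' @return List of [genome] objects in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    genome(ids[i], as.character(set[[i]]), circular = circular))
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `genome` or list of them.
#' @param path Output path.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, function(g)
    as.character(g$sequence), character(1)))
  names(set) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a gene feature table
#'
#' Features use internal 0-based half-open coordinates and strands
#' `+1`/`-1`. A feature may wrap the circular origin of coordinates, in
#' which case `end > genome length` and `wraps` is `TRUE`.
#'
#' @param gene_id Character vector of identifiers.
#' @param start,end Integer coordinates, 0-based half-open.
#' @param strand Integer `+1`/`-1`.
#' @param kind Feature class, one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"other"`.
#' @return A `data.frame` of class `gene_features`.
#' @export
gene_features <- function(gene_id, start, end, strand, kind = "CDS") {
  stopifnot(all(strand %in% c(1L, -1L)), all(start >= 0), all(end > start))
  df <- data.frame(gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.integer(strand),
                   kind = rep_len(as.character(kind), length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Read gene features from GFF3 or TSV
#'
#' GFF3 coordinates (1-based inclusive) and the 4-column TSV dialect
#' (`gene_id, start, end, strand`, also 1-based inclusive) are converted
#' to internal 0-based half-open coordinates. Features with `end < start`
#' or without a strand are rejected with a warning.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return A [gene_features] table.
#' @export
read_features <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (dialect == "gff3") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L) return(gene_features(character(), integer(), integer(), integer())[0, ])
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    if (ncol(f) < 9L) stop("malformed GFF3: expected 9 columns")
    id <- sub(".*ID=([^;]+).*", "\\1", f[, 9])
    noid <- !grepl("ID=", f[, 9])
    id[noid] <- paste0("feat", which(noid))
    start1 <- as.integer(f[, 4]); end1 <- as.integer(f[, 5])
    strand_chr <- f[, 7]
    kind <- ifelse(f[, 3] %in% c("CDS", "rRNA", "tRNA"), f[, 3], "other")
  } else {
    tb <- read.delim(path, header = FALSE, sep = "",
                     col.names = c("gene_id", "start", "end", "strand"),
                     stringsAsFactors = FALSE)
    # also accept comma-separated rows
    if (nrow(tb) > 0 && any(grepl(",", tb$gene_id, fixed = TRUE))) {
      tb <- read.delim(path, header = FALSE, sep = ",",
                       col.names = c("gene_id", "start", "end", "strand"),
                       stringsAsFactors = FALSE)
    }
    id <- as.character(tb$gene_id)
    start1 <- as.integer(tb$start); end1 <- as.integer(tb$end)
    strand_chr <- as.character(tb$strand)
    kind <- "CDS"
  }
  strand <- ifelse(strand_chr %in% c("+", "+1", "1"), 1L,
                   ifelse(strand_chr %in% c("-", "-1"), -1L, NA_integer_))
  keep <- !is.na(strand) & end1 >= start1
  if (any(!keep))
    warning(sprintf("%d feature(s) rejected (missing strand or end < start)",
                    sum(!keep)))
  gene_features(id[keep], start1[keep] - 1L, end1[keep], strand[keep],
                kind = if (length(kind) == 1L) kind else kind[keep])
}

#' Write gene features as TSV (1-based inclusive)
#'
#' Round-trips bit-exactly with `read_features(dialect = "tsv")`.
#' @param features A [gene_features] table.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  out <- data.frame(gene_id = features$gene_id,
                    start = features$start + 1L,
                    end = features$end,
                    strand = ifelse(features$strand > 0, "+", "-"))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a homology table
#'
#' Expects a TSV with header columns `query_gene, subject_genome,
#' subject_gene, similarity, coverage, reciprocal_best`. A missing
#' orthologue is encoded as an empty or `NA` `subject_gene`.
#'
#' @param path Input TSV.
#' @return A `data.frame` with validated columns.
#' @export
read_homology <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_gene", "subject_genome", "subject_gene",
            "similarity", "coverage", "reciprocal_best")
  if (!all(need %in% names(tb)))
    stop("homology table must contain columns: ", paste(need, collapse = ", "))
  tb$subject_gene[tb$subject_gene %in% c("", ".")] <- NA_character_
  tb$reciprocal_best <- as.logical(tb$reciprocal_best)
  bad <- with(tb, similarity < 0 | similarity > 100 |
                coverage < 0 | coverage > 100)
  if (any(bad, na.rm = TRUE)) stop("similarity/coverage outside [0,100]")
  tb
}

# Extract a (possibly wrapping) subsequence of a circular genome,
# 0-based half-open; end may exceed length for wrap.
genome_subseq <- function(g, start, end) {
  L <- g$length
  if (end <= L) return(Biostrings::subseq(g$sequence, start + 1L, end))
  if (!g$circular) stop("subsequence beyond end of a linear genome")
  Biostrings::xscat(Biostrings::subseq(g$sequence, start + 1L, L),
                    Biostrings::subseq(g$sequence, 1L, end - L))
}
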