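# End-to-end pipeline orchestration over a synthetic fixture or user
# inputs: replichore inference -> AIMS discovery -> inversion and
# insertion analyses -> compatibility scoring, with a manifest
# recording inputs, parameters, per-stage seeds and output checksums.

#' Default pipeline configuration
#'
#' Every stochastic stage receives a seed derived from the global seed
#' by a fixed counter scheme (`seed + stage_index`), so a rerun with
#' the same configuration is bit-identical. All parameters that the
#' method leaves open are explicit here and echoed into the manifest.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory.
#' @param genome_length,aims_plants,pentamer_effect Synthetic fixture
#'   parameters (see [plant_spec]).
#' @param min_bias,min_copies,min_ter_increase,n_null,segment_bp AIMS
#'   detection parameters (see [identify_aims]).
#' @param n_inversions,n_insertions,divergence Sister-genome plants.
#' @param n_fragments,frag_bp Compatibility sampling.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("aimsarch_run_"),
                       genome_length = 1e6,
                       aims_plants = gradient_aims_plants(n = 8, a_ori = 0.9,
                                                          a_ter = 3.6,
                                                          seed = seed),
                       pentamer_effect = 0.25,
                       min_bias = 0.70, min_copies = 96,
                       min_ter_increase = 0.5, n_null = 3,
                       segment_bp = 40000,
                       n_inversions = 6, n_insertions = 20,
                       divergence = 0.01,
                       n_fragments = 500, frag_bp = 10000) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: synthetic-genome generation,
#' replichore inference, AIMS discovery, sister derivation, inversion
#' detection, insertion calling with permissive-fraction annotation,
#' and donor compatibility scoring. Each stage writes a versioned
#' output under `config$outdir`; a `manifest.json` lists every
#' artifact with its md5 checksum. A stage failure aborts with a
#' partial manifest on disk.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("aims_plants"))],
                   aims_plants = config$aims_plants,
                   outputs = list())
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(config$outdir, name)
    if (is.data.frame(obj))
      write.table(format(obj, digits = 12), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
    paths <<- c(paths, p)
    p
  }
  save_manifest <- function() {
    manifest$outputs <- lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  on.exit(save_manifest())

  # stage 1: synthetic fixture
  spec <- plant_spec(length = config$genome_length,
                     pentamer_effect = config$pentamer_effect,
                     aims_plants = config$aims_plants)
  fix <- generate_genome(spec, seed = config$seed + 1L)
  write_fasta(fix$genome, file.path(config$outdir, "recipient.fasta"))
  paths <- c(paths, file.path(config$outdir, "recipient.fasta"))
  write_features(fix$features, file.path(config$outdir, "recipient.tsv"))
  paths <- c(paths, file.path(config$outdir, "recipient.tsv"))

  # stage 2: replichore inference
  map <- find_breakpoints(fix$genome, fix$features)
  emit(data.frame(genome_id = fix$genome$id, ori = map$ori, ter = map$ter,
                  delta = map$delta, confidence = map$confidence),
       "replichore.tsv")

  # stage 3: AIMS discovery on the (insertion-free) recipient backbone
  aims <- identify_aims(fix$genome, map,
                        min_bias = config$min_bias,
                        min_copies = config$min_copies,
                        min_ter_increase = config$min_ter_increase,
                        n_null = config$n_null,
                        segment_bp = config$segment_bp,
                        seed = config$seed + 2L)
  aims$octamers$family <- cluster_aims(aims)
  reps <- aims_representatives(aims)
  emit(aims$octamers, "aims.tsv")
  emit(reps, "aims_representatives.tsv")
  write_aims_set(aims, file.path(config$outdir, "aims.json"))
  paths <- c(paths, file.path(config$outdir, "aims.json"))

  # stage 4: sister genome with planted rearrangements and insertions
  sis <- derive_sister(fix, divergence = config$divergence,
                       n_inversions = config$n_inversions,
                       n_insertions = config$n_insertions,
                       ins_aims = config$aims_plants$octamer,
                       seed = config$seed + 3L)

  # stage 5: inversions
  inv <- detect_inversions(fix$features,
                           sis$features[grepl("^g", sis$features$gene_id), ],
                           fix$map, sis$map,
                           pair_id = paste0(fix$genome$id, "_vs_sister"))
  inv <- dedupe_inversions(inv)
  emit(as.data.frame(inv), "inversions.tsv")
  ps <- positional_summary(inv)
  emit(ps$bins, "inversion_summary.tsv")

  # stage 6: insertions and permissive bias
  ins <- call_insertions(sis$features, sis$homology, "sister_sp",
                         c("strain_1", "strain_2"), sis$map)
  ins <- annotate_permissive(ins, sis$genome, sis$map, reps$octamer)
  emit(as.data.frame(ins), "insertions.tsv")

  # stage 7: compatibility of the sister genome as donor
  cmp <- compatibility(reps[, c("octamer", "n_i")], sis$genome,
                       n_fragments = config$n_fragments,
                       frag_bp = config$frag_bp, seed = config$seed + 4L)
  cmp$recipient_id <- fix$genome$id
  emit(data.frame(recipient = cmp$recipient_id, donor = cmp$donor_id,
                  c_xy = cmp$c_xy,
                  n_informative_aims = cmp$n_informative_aims),
       "compatibility.tsv")

  save_manifest()
  on.exit()
  invisible(list(manifest = manifest,
                 results = list(fixture = fix, map = map, aims = aims,
                                sister = sis, inversions = inv,
                                insertions = ins, compatibility = cmp)))
}
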