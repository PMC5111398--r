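#' Assemble a pipeline configuration
#'
#' Defaults follow the published protocol this pipeline implements: mapping
#' at 99% identity over the full read, presence above 10% coverage,
#' normalisation against a 16 kb canonical mitogenome.
#'
#' @param references path to the reference mitogenome FASTA.
#' @param meta path to the species metadata TSV (columns `species_id`,
#'   `mito_fraction`, `biomass_per_individual`).
#' @param reads named character vector of per-sample FASTQ paths (names are
#'   sample ids).
#' @param truth_counts,truth_biomass optional paths to morphological truth
#'   matrices (species x samples TSV); when absent the evaluation stage is
#'   skipped.
#' @param identity_threshold mapping identity; default 0.99.
#' @param detection_threshold coverage detection threshold; default 0.10.
#' @param canonical_length canonical mitogenome length; default 16000.
#' @param read_length nominal read length for index construction; default
#'   100.
#' @param seed seed for ordination/permutation stages; default 1.
#' @param n_permutations Procrustes permutations; default 9999.
#' @param outdir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(references, meta, reads, truth_counts = NULL,
                            truth_biomass = NULL, identity_threshold = 0.99,
                            detection_threshold = 0.10,
                            canonical_length = 16000, read_length = 100,
                            seed = 1, n_permutations = 9999,
                            outdir = "mitoskim_out") {
  structure(list(references = references, meta = meta, reads = reads,
                 truth_counts = truth_counts, truth_biomass = truth_biomass,
                 identity_threshold = identity_threshold,
                 detection_threshold = detection_threshold,
                 canonical_length = canonical_length,
                 read_length = read_length, seed = seed,
                 n_permutations = n_permutations, outdir = outdir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; `reads` is a mapping of sample id to FASTQ path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$reads <- unlist(y$reads)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full profiling pipeline
#'
#' map -> profile -> quantify -> community -> evaluate, writing every
#' artifact as TSV plus a `manifest.yaml` recording inputs, parameters,
#' seed and package version for auditability. When no truth tables are
#' configured the quantification and evaluation stages are skipped with a
#' logged notice; partial outputs are preserved on stage failure.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  log_ <- function(...) message("[mitoskim] ", ...)

  lib <- .stage("load_references", {
    fa <- read_fasta(config$references)
    data.frame(species_id = fa$id, sequence = fa$sequence,
               achieved_length = nchar(fa$sequence),
               stringsAsFactors = FALSE)
  })
  meta <- .stage("load_meta", {
    m <- utils::read.delim(config$meta, stringsAsFactors = FALSE)
    stopifnot(all(c("species_id", "mito_fraction",
                    "biomass_per_individual") %in% names(m)))
    m
  })

  log_("mapping ", length(config$reads), " sample(s) against ",
       nrow(lib), " references")
  idx <- build_index(lib, read_length = config$read_length,
                     max_mismatch_rate = 1 - config$identity_threshold)
  mappings <- .stage("map", {
    res <- lapply(config$reads, function(fq) map_reads(read_fastq(fq), idx))
    for (sid in names(res)) {
      tab <- table(res[[sid]]$assignments$status)
      log_(sid, ": ", paste(names(tab), unname(tab), collapse = ", "))
      write_assignments_tsv(res[[sid]]$assignments,
                            out(paste0(sid, "_assignments.tsv")))
      write_depth_tsv(res[[sid]]$depth, out(paste0(sid, "_depth.tsv")))
    }
    res
  })

  cfg <- detection_config(config$detection_threshold, config$canonical_length)
  profile <- .stage("profile", {
    p <- profile_table(mappings, lib, meta, cfg)
    write.table(p, out("profile.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_matrix_tsv(presence_matrix(p) * 1, out("presence.tsv"))
    p
  })

  truth_counts <- if (!is.null(config$truth_counts))
    read_matrix_tsv(config$truth_counts) else NULL
  truth_biomass <- if (!is.null(config$truth_biomass))
    read_matrix_tsv(config$truth_biomass) else NULL

  if (!is.null(truth_biomass)) {
    .stage("quantify", {
      reg <- biomass_read_regression(profile, truth_biomass)
      variants <- lapply(c("raw", "normalized", "corrected"), function(v) {
        r <- biomass_read_regression(profile, truth_biomass, variant = v)
        data.frame(variant = v, intercept = r$gls$intercept,
                   slope = r$gls$slope, delta = r$gls$delta,
                   r_squared = r$ols$r_squared, p = r$gls$p_slope)
      })
      write.table(do.call(rbind, variants), out("regression.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      reg
    })
  } else log_("no truth biomass table: quantification stage skipped")

  .stage("community", {
    rf <- read_frequencies(profile)
    keep <- rowSums(rf) > 0
    d_bin <- jaccard(presence_matrix(profile)[keep, , drop = FALSE] * 1,
                     binary = TRUE)
    d_qnt <- jaccard(rf[keep, , drop = FALSE], binary = FALSE)
    write_matrix_tsv(as.matrix(d_bin), out("jaccard_binary.tsv"))
    write_matrix_tsv(as.matrix(d_qnt), out("jaccard_quantitative.tsv"))
    ord <- nmds(d_qnt, seed = config$seed)
    cfgm <- ord$configuration
    colnames(cfgm) <- paste0("NMDS", seq_len(ncol(cfgm)))
    write_matrix_tsv(t(cfgm), out("nmds_read.tsv"))
    rich <- chao2(presence_matrix(profile))
    writeLines(yaml::as.yaml(list(
      read_profile = rich[c("s_obs", "q1", "q2", "m", "chao2", "se")])),
      out("richness.yaml"))
    if (!is.null(truth_biomass)) {
      bf <- sweep(truth_biomass, 2L, colSums(truth_biomass), "/")
      ord_b <- nmds(jaccard(bf[rowSums(bf) > 0, , drop = FALSE],
                            binary = FALSE), seed = config$seed)
      pro <- procrustes_protest(ord_b$configuration, ord$configuration,
                                n_permutations = config$n_permutations,
                                seed = config$seed)
      writeLines(yaml::as.yaml(pro[c("m_squared", "correlation_r", "p_value",
                                     "n_permutations")]),
                 out("procrustes.yaml"))
    }
  })

  if (!is.null(truth_counts)) {
    .stage("evaluate", {
      truth <- truth_counts[lib$species_id, , drop = FALSE] > 0
      cs <- confusion(presence_matrix(profile), truth)
      rep <- data.frame(tp = cs$tp, tn = cs$tn, fp = cs$fp, fn = cs$fn,
                        detection_rate = cs$detection_rate,
                        profiling_success = cs$profiling_success)
      write.table(rep, out("confusion.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      covm <- profile_matrix(profile, "coverage_fraction")
      sweep_tab <- threshold_sweep(covm, truth,
                                   thresholds = seq(0.05, 0.5, by = 0.05))
      write.table(sweep_tab, out("threshold_sweep.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cs
    })
  } else log_("no truth counts table: evaluation stage skipped")

  manifest <- list(
    package = "mitoskim",
    version = as.character(utils::packageVersion("mitoskim")),
    inputs = list(references = config$references, meta = config$meta,
                  reads = as.list(config$reads),
                  truth_counts = config$truth_counts,
                  truth_biomass = config$truth_biomass),
    parameters = list(identity_threshold = config$identity_threshold,
                      detection_threshold = config$detection_threshold,
                      canonical_length = config$canonical_length,
                      read_length = config$read_length,
                      n_permutations = config$n_permutations),
    seed = config$seed,
    outputs = list.files(config$outdir)
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  log_("done: ", config$outdir)
  invisible(config$outdir)
}
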