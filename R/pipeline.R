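# End-to-end orchestration: preprocess -> segment -> filter -> dye-swap
# concordance -> loop attribution -> CNVR merge -> summary, with optional
# FPR and enrichment stages, plus a provenance manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default; all values are validated
#' here so a bad setting fails before any computation. The resolved config
#' is written alongside the outputs of [run_pipeline()].
#'
#' @param ratio_threshold candidate-segment |mean log2 ratio| cut (0.4)
#' @param min_probes minimum consecutive probes per candidate (5)
#' @param penalty segmentation penalty; NULL = per-profile BIC-style default
#' @param n_quantiles q-spline quantile anchors (100)
#' @param span loess span for spatial correction (0.3)
#' @param min_overlap reciprocal overlap for concordance/attribution (0.5)
#' @param n_perm permutations for enrichment tests (10000)
#' @param seed master seed
#' @return list of class `cgh_config`
#' @export
pipeline_config <- function(ratio_threshold = 0.4, min_probes = 5,
                            penalty = NULL, n_quantiles = 100, span = 0.3,
                            min_overlap = 0.5, n_perm = 10000, seed = 1L) {
  if (ratio_threshold < 0) stop_invalid("ratio_threshold must be >= 0")
  if (min_probes < 1) stop_invalid("min_probes must be >= 1")
  if (!is.null(penalty) && penalty < 0) stop_invalid("penalty must be >= 0")
  if (n_quantiles < 3) stop_invalid("n_quantiles must be >= 3")
  if (span <= 0 || span > 1) stop_invalid("span must be in (0, 1]")
  if (min_overlap <= 0 || min_overlap > 1)
    stop_invalid("min_overlap must be in (0, 1]")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  structure(list(ratio_threshold = ratio_threshold, min_probes = min_probes,
                 penalty = penalty, n_quantiles = n_quantiles, span = span,
                 min_overlap = min_overlap, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "cgh_config")
}

stage_log <- function(verbose, stage, n_in, n_out) {
  if (verbose)
    message(sprintf("[%s] in: %d, out: %d", stage, n_in, n_out))
}

#' Call CNVs from per-array probe tables (in-memory pipeline)
#'
#' Runs preprocessing, segmentation, candidate filtering, dye-swap
#' concordance and loop attribution, and CNVR merging on a set of probe
#' tables and their design sheet.
#'
#' @param tables named list of `cgh_ratio` tables, names = array_id
#' @param design validated `cgh_design`
#' @param config `cgh_config`
#' @param preprocess set FALSE when tables already hold clean log2 ratios
#' @param verbose log per-stage row counts
#' @return list: candidates (per-array filtered segments), pair_calls,
#'   calls (`cgh_calls`), cnvrs (`cgh_cnvr`)
#' @export
call_cnvs <- function(tables, design, config = pipeline_config(),
                      preprocess = TRUE, verbose = FALSE) {
  validate_design(design)
  miss <- setdiff(design$array_id, names(tables))
  if (length(miss))
    stop_invalid("no probe table for array(s): %s", paste(miss, collapse = ", "))

  candidates <- lapply(design$array_id, function(aid) {
    tab <- tables[[aid]]
    attr(tab, "array_id") <- attr(tab, "array_id") %||% aid
    if (preprocess)
      tab <- preprocess_array(tab, span = config$span,
                              n_quantiles = config$n_quantiles)
    seg <- segment_ratios(tab, penalty = config$penalty)
    filter_segments(seg, ratio_threshold = config$ratio_threshold,
                    min_probes = config$min_probes)
  })
  names(candidates) <- design$array_id
  stage_log(verbose, "segment+filter", length(tables),
            sum(vapply(candidates, nrow, integer(1))))

  # one concordance run per unordered dye-swap pair
  first <- design$array_id[design$array_id < design$swap_of]
  pair_calls <- do.call(rbind, c(
    list(pair_concordance(candidates[[1]][0, ], candidates[[1]][0, ],
                          design)[0, ]),
    lapply(first, function(aid) {
      mate <- design$swap_of[design$array_id == aid]
      pair_concordance(candidates[[aid]], candidates[[mate]], design,
                       min_overlap = config$min_overlap)
    })))
  rownames(pair_calls) <- NULL
  class(pair_calls) <- c("cgh_paircalls", "data.frame")
  stage_log(verbose, "dye-swap concordance",
            sum(vapply(candidates, nrow, integer(1))), nrow(pair_calls))

  calls <- attribute_cnvs(pair_calls, design,
                          min_overlap = config$min_overlap)
  stage_log(verbose, "loop attribution", nrow(pair_calls), nrow(calls))

  cnvrs <- merge_calls(calls)
  stage_log(verbose, "CNVR merge", nrow(calls), nrow(cnvrs))

  list(candidates = candidates, pair_calls = pair_calls,
       calls = calls, cnvrs = cnvrs)
}

#' Run the full pipeline and write an artifact directory
#'
#' Simulates an experiment (when `experiment` is NULL) or consumes one
#' produced by [sim_experiment()] / read from disk, calls CNVs, summarises
#' the CNVR catalogue and writes every intermediate plus a provenance
#' manifest (config, seed, package version) to `out_dir`. Identical config
#' and seed give byte-identical outputs.
#'
#' @param out_dir output directory (created if needed)
#' @param config `cgh_config`
#' @param experiment list with genome, probes, panel, design, truth, tables;
#'   NULL simulates one with `sim_args`
#' @param sim_args arguments passed to [sim_experiment()] when simulating
#' @param verbose log stages
#' @return (invisibly) the [call_cnvs()] result plus `summary` and paths
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         experiment = NULL, sim_args = list(),
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(experiment)) {
    sim_args$seed <- sim_args$seed %||% config$seed
    experiment <- do.call(sim_experiment, sim_args)
  }
  res <- call_cnvs(experiment$tables, experiment$design, config,
                   verbose = verbose)
  glen <- genome_length(experiment$genome)
  summ <- cnvr_summary(res$cnvrs, glen)
  res$summary <- summ

  write_design_sheet(experiment$design, file.path(out_dir, "design.tsv"))
  if (nrow(experiment$truth))
    write_bed(data.frame(chrom = experiment$truth$chrom,
                         start = experiment$truth$start,
                         end = experiment$truth$end,
                         name = paste0(experiment$truth$animal_id, ":",
                                       ifelse(experiment$truth$copies < 2,
                                              "loss", "gain"))),
              file.path(out_dir, "truth.bed"))
  if (nrow(res$calls))
    write_bed(data.frame(chrom = res$calls$chrom, start = res$calls$start,
                         end = res$calls$end,
                         name = paste0(res$calls$animal_id, ":",
                                       res$calls$state)),
              file.path(out_dir, "cnv_calls.bed"))
  if (nrow(res$cnvrs))
    write_bed(data.frame(chrom = res$cnvrs$chrom, start = res$cnvrs$start,
                         end = res$cnvrs$end,
                         name = paste0(res$cnvrs$type, ";",
                                       res$cnvrs$n_animals)),
              file.path(out_dir, "cnvr.bed"))
  utils::write.table(summ$table, file.path(out_dir, "cnvr_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(package = "cghloop",
                   version = as.character(utils::packageVersion("cghloop")),
                   config = unclass(config),
                   n_arrays = nrow(experiment$design),
                   n_probes = nrow(experiment$probes),
                   n_calls = nrow(res$calls),
                   n_cnvrs = nrow(res$cnvrs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summ$table, file.path(out_dir, "cnvr_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Compare calls against a planted truth set
#'
#' A planted CNV is recovered when some call for the same animal overlaps it
#' reciprocally by >= `min_overlap` with the correct direction (copies < 2
#' vs loss, copies > 2 vs gain). Wrong-direction recoveries and calls with
#' the right locus but wrong animal are tallied separately.
#'
#' @param calls `cgh_calls`
#' @param truth `cgh_truth` planted CNV set
#' @param min_overlap reciprocal overlap to count a recovery (default 0.5)
#' @return list: recall_loss, recall_gain, recovered (logical per truth
#'   row), wrong_direction (count), wrong_animal (count of truth rows whose
#'   locus was called only in another animal)
#' @export
evaluate_calls <- function(calls, truth, min_overlap = 0.5) {
  n <- nrow(truth)
  recovered <- logical(n)
  wrong_direction <- 0L
  wrong_animal <- 0L
  for (i in seq_len(n)) {
    want <- if (truth$copies[i] < 2) "loss" else "gain"
    ro <- reciprocal_overlap(truth$start[i], truth$end[i],
                             calls$start, calls$end)
    hit <- calls$chrom == truth$chrom[i] & ro >= min_overlap
    mine <- hit & calls$animal_id == truth$animal_id[i]
    if (any(mine & calls$state == want)) {
      recovered[i] <- TRUE
    } else if (any(mine)) {
      wrong_direction <- wrong_direction + 1L
    } else if (any(hit)) {
      wrong_animal <- wrong_animal + 1L
    }
  }
  losses <- truth$copies < 2
  list(recall_loss = if (any(losses)) mean(recovered[losses]) else NA_real_,
       recall_gain = if (any(!losses)) mean(recovered[!losses]) else NA_real_,
       recovered = recovered,
       wrong_direction = wrong_direction,
       wrong_animal = wrong_animal)
}

#' Two-array self-self design (QC helper)
#'
#' @param animal animal id hybridized against itself
#' @param design_id array design label
#' @return `cgh_design` with one dye-swap pair
#' @export
selfself_design <- function(animal, design_id = "D1") {
  d <- data.frame(array_id = c("S001", "S002"),
                  cy3 = animal, cy5 = animal, design_id = design_id,
                  swap_of = c("S002", "S001"), stringsAsFactors = FALSE)
  class(d) <- c("cgh_design", "data.frame")
  d
}
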