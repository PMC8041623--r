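#' Pipeline configuration
#'
#' Collects the preset, inputs and every module-level override into one
#' object that is serialized alongside the outputs; re-running with an
#' identical configuration and inputs reproduces the outputs bit for bit.
#'
#' @param preset_name technology preset (see [preset]).
#' @param contigs draft contig [seq_set], or path to a FASTA.
#' @param long_reads long-read [seq_set], or path to FASTA/FASTQ.
#' @param short_mate1,short_mate2 optional paired short reads for contig QC.
#' @param out_dir output directory for stage artifacts (NULL = no files).
#' @param seed integer seed controlling every stochastic choice.
#' @param resume reuse stage checkpoints found in `out_dir` (written on every
#'   run when `out_dir` is set), restarting after the last completed one.
#' @param min_depth LQI depth threshold.
#' @param min_weight matching-cover weight threshold.
#' @param rparams a [reduction_params].
#' @param vparams a [validation_params].
#' @param cparams a [consensus_params].
#' @param pparams a [polish_params].
#' @param genome_size optional true genome size for NG50 reporting.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset_name = "ontraw", contigs = NULL,
                            long_reads = NULL, short_mate1 = NULL,
                            short_mate2 = NULL, out_dir = NULL, seed = 1L,
                            resume = FALSE, min_depth = 7L, min_weight = 5L,
                            rparams = reduction_params(),
                            vparams = validation_params(),
                            cparams = consensus_params(),
                            pparams = polish_params(),
                            genome_size = NULL) {
  structure(list(preset_name = preset_name, contigs = contigs,
                 long_reads = long_reads, short_mate1 = short_mate1,
                 short_mate2 = short_mate2, out_dir = out_dir, seed = seed,
                 resume = resume, min_depth = min_depth,
                 min_weight = min_weight,
                 rparams = rparams, vparams = vparams, cparams = cparams,
                 pparams = pparams, genome_size = genome_size),
            class = "pipeline_config")
}

stage_msg <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the hybrid assembly pipeline
#'
#' Orchestrates contig QC (when short reads are given), synthetic-pair
#' extraction and mapping, scaffolding-graph construction, repeat masking,
#' transitive reduction, matching-cover backbone, validation, gap filling,
#' polishing and final assembly emission. Stage artifacts (FASTA/TSV) are
#' written under `config$out_dir` when set.
#'
#' @param config a [pipeline_config].
#' @param verbose emit one log line per stage.
#' @return list of class `assembly_result`: `assembly` ([seq_set]), `lines`,
#'   `ssg`, `matching`, `fill_report`, `metrics`, and per-stage reports.
#' @export
run_pipeline <- function(config, verbose = interactive()) {
  set.seed(config$seed)
  contigs <- if (is.character(config$contigs))
    parse_sequences(config$contigs) else config$contigs
  reads <- if (is.character(config$long_reads))
    parse_sequences(config$long_reads) else config$long_reads
  if (is.null(contigs) || is.null(reads)) {
    stop("both contigs and long reads are required")
  }
  od <- config$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)
  short_cov <- NULL
  qc_report <- NULL
  if (!is.null(config$short_mate1)) {
    qc <- run_contig_qc(contigs, config$short_mate1, config$short_mate2,
                        min_depth = config$min_depth)
    contigs <- qc$contigs
    short_cov <- qc$coverage
    qc_report <- qc$report
    stage_msg(verbose, "contig_qc", "%d corrected contigs, %d LQI actions",
              length(contigs), nrow(qc$report))
  }
  if (!is.null(od)) write_sequences(contigs, file.path(od, "contigs.fa"))

  ps <- preset(config$preset_name)
  rl_n50 <- n50(nchar(reads$seq))
  spectrum <- default_spectrum(ps, rl_n50)
  stage_msg(verbose, "spectrum", "%d libraries, inserts %d..%d (N50 %d)",
            nrow(spectrum), min(spectrum$insert), max(spectrum$insert),
            rl_n50)
  resume <- isTRUE(config$resume) && !is.null(od)
  chk <- function(name) file.path(od, paste0("stage_", name, ".rds"))
  # stage checkpoint: pair mapping (the expensive stage)
  if (resume && file.exists(chk("mapres"))) {
    mapres <- readRDS(chk("mapres"))
    stage_msg(verbose, "map_pairs", "resumed from checkpoint (%s pairs)",
              format(nrow(mapres$pairs)))
  } else {
    idx <- build_index(contigs, ps)
    mapres <- map_synthetic_pairs(reads, idx, spectrum, ps)
    if (!is.null(od)) saveRDS(mapres, chk("mapres"))
    stage_msg(verbose, "map_pairs",
              "%s candidate, %s accepted (%s inter-contig)",
              format(mapres$n_candidate), format(mapres$n_accepted),
              format(nrow(mapres$pairs)))
  }

  if (resume && file.exists(chk("reduced"))) {
    st <- readRDS(chk("reduced"))
    g <- st$g; red <- st$red
    stage_msg(verbose, "reduce", "resumed from checkpoint (%d edges reduced)",
              nrow(red$path_db))
  } else {
    g <- build_ssg(contigs, mapres, short_cov = short_cov)
    stage_msg(verbose, "ssg", "%d mate edges, total weight %s", nrow(g$mate),
              format(sum(g$mate$w)))
    g <- mask_repeats(g, config$rparams)
    stage_msg(verbose, "mask", "%d repeat contigs (u_bar %.1f)",
              sum(g$contigs$repeat_flag), attr(g, "u_bar"))
    red <- transitive_reduce(g, config$rparams)
    g <- red$g
    if (!is.null(od)) saveRDS(list(g = g, red = red), chk("reduced"))
    stage_msg(verbose, "reduce", "%d edges reduced, %d remain",
              nrow(red$path_db), sum(!g$mate$removed))
  }
  if (!is.null(od)) write_ssg(g, file.path(od, "ssg.tsv"))

  mc <- matching_cover(g, min_weight = config$min_weight)
  stage_msg(verbose, "matching", "%d matched, r=%.3f%s", length(mc$edges),
            mc$ratio, if (mc$exact) " exact" else "")
  lines0 <- break_cycles_extract_lines(g, mc)
  val <- validate_backbone(lines0, g, red$path_db, config$vparams)
  lines <- val$lines
  stage_msg(verbose, "backbone", "%d lines (%d after validation splits)",
            length(lines0), length(lines))
  if (!is.null(od)) write_backbone_tsv(lines, g, file.path(od, "backbone.tsv"))

  db <- build_read_db(lines, g, reads, config$cparams)
  fg <- fill_gaps(lines, db, g, contigs, config$cparams)
  stage_msg(verbose, "fill", "%d/%d edges filled",
            sum(fg$report$status == "filled"), nrow(fg$report))

  gp <- graph_polish(fg$sequences, fg$fills, g, lines, contigs,
                     config$pparams, config$rparams)
  ap <- alignment_polish(gp$sequences, gp$fills, g, lines, contigs, gp$used,
                         config$pparams)
  stage_msg(verbose, "polish", "%d graph + %d alignment splices",
            if (nrow(gp$report)) sum(gp$report$action == "spliced") else 0L,
            nrow(ap$report))

  assembly <- emit_assembly(ap$sequences, lines, g, contigs, ap$used,
                            config$pparams)
  if (!is.null(od)) write_sequences(assembly, file.path(od, "assembly.fa"),
                                    wrap = 80L)
  metrics <- assembly_metrics(assembly, contigs, config$genome_size)
  if (!is.null(od)) {
    utils::write.table(fg$report, file.path(od, "fill_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(assembly = assembly, lines = lines, ssg = g, matching = mc,
                 fill_report = fg$report, fills = ap$fills,
                 path_db = red$path_db, qc_report = qc_report,
                 validation_report = val$report,
                 polish_report = rbind(if (nrow(gp$report)) gp$report,
                                       if (nrow(ap$report)) ap$report),
                 metrics = metrics, config = config),
            class = "assembly_result")
}

#' Assembly metrics
#' @param assembly final [seq_set].
#' @param contigs input draft contigs.
#' @param genome_size optional genome size for NG50.
#' @return data.frame of summary statistics.
#' @export
assembly_metrics <- function(assembly, contigs, genome_size = NULL) {
  al <- nchar(assembly$seq)
  cl <- nchar(contigs$seq)
  data.frame(
    n_sequences = length(al),
    total_bp = sum(as.numeric(al)),
    n50 = n50(al),
    ng50 = if (!is.null(genome_size)) ng50(al, genome_size) else NA_real_,
    input_contigs = length(cl),
    input_n50 = n50(cl),
    input_ng50 = if (!is.null(genome_size)) ng50(cl, genome_size) else
      NA_real_)
}

#' @export
print.assembly_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "assembly_result: %d sequences, %.0f bp, N50 %s (input contigs N50 %s)\n",
    m$n_sequences, m$total_bp, format(m$n50), format(m$input_n50)))
  invisible(x)
}

write_backbone_tsv <- function(lines, g, path) {
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    gaps <- c(ln$gaps, NA)
    rows[[li]] <- data.frame(
      line = li, order = seq_along(ln$contigs),
      contig = g$contigs$id[ln$contigs],
      orientation = ifelse(ln$orient > 0, "+", "-"),
      gap_estimate = gaps[seq_along(ln$contigs)])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded end-to-end demonstration assembly
#'
#' Simulates a genome with two planted repeat families, error-bearing long
#' reads and gapped draft contigs, runs the full pipeline, and returns the
#' result together with the simulation truth, so the assembly can be
#' compared against a known answer.
#'
#' @param genome_len genome length in bp.
#' @param coverage long-read fold coverage.
#' @param seed integer seed.
#' @param n_breaks draft-contig break count (default scales with genome).
#' @param gap_max largest deleted gap at a break (bp).
#' @param min_weight matching weight threshold (default 5).
#' @param out_dir optional artifact directory.
#' @param verbose log stage lines.
#' @return list with `result` (an `assembly_result`), `genome`, `reads`,
#'   `drafts`.
#' @export
demo_assembly <- function(genome_len = 1e6, coverage = 30, seed = 1L,
                          n_breaks = max(10L, round(genome_len / 10000)),
                          gap_max = 5000L, min_weight = 5L, out_dir = NULL,
                          verbose = FALSE) {
  genome <- simulate_genome(genome_len, n_repeat_families = 2L,
                            repeat_len = 2000L, copies_per_family = 4L,
                            divergence = 0.02, seed = seed)
  lr <- simulate_long_reads(genome, coverage = coverage,
                            length_mean = 15000, length_min = 1000,
                            em = error_model(0.02, 0.015, 0.015, 1.5),
                            seed = seed)
  drafts <- make_draft_contigs(genome, n_breaks = n_breaks, seed = seed,
                               gap_min = 0L, gap_max = gap_max)
  cfg <- pipeline_config(preset_name = "ontraw", contigs = drafts$contigs,
                         long_reads = lr$reads, seed = seed,
                         min_weight = min_weight, out_dir = out_dir,
                         genome_size = genome_len)
  res <- run_pipeline(cfg, verbose = verbose)
  list(result = res, genome = genome, reads = lr, drafts = drafts)
}
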