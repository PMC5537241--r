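# End-to-end pipeline commands. Each cmd_* is a thin, logged wrapper over
# the analysis functions: pure in (inputs, parameters, seed), writing TSV /
# BED / FASTA / JSON outputs plus a run manifest, so deterministic stages
# re-run bit-identically.

write_manifest <- function(out_dir, command, inputs, params) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("satmethyl")),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Consensus pipeline command
#'
#' Reads monomers, aligns if needed, derives the majority-rule consensus,
#' and writes it as single-record FASTA plus a per-column frequency TSV.
#'
#' @param fasta Input monomer FASTA.
#' @param out_dir Output directory.
#' @param tie_rule Consensus tie rule (see [build_consensus()]).
#' @return The `consensus_profile`, invisibly.
#' @export
cmd_consensus <- function(fasta, out_dir, tie_rule = "first_alphabetical") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- enforce_alignment(read_fasta(fasta))
  profile <- build_consensus(aln, tie_rule = tie_rule)
  write_consensus(profile,
                  fasta_path = file.path(out_dir, "consensus.fasta"),
                  freqs_path = file.path(out_dir, "column_freqs.tsv"))
  write_manifest(out_dir, "consensus", list(fasta = fasta),
                 list(tie_rule = tie_rule, n_records = nrow(aln$mat),
                      width = aln$width))
  invisible(profile)
}

#' Diversity pipeline command
#'
#' Overall and sliding-window nucleotide diversity plus the +/-2SD segment
#' classification; writes a Pi report, the window track TSV, and segments
#' as TSV and BED.
#'
#' @param fasta Input monomer FASTA (pre-aligned or alignable).
#' @param out_dir Output directory.
#' @param window,step Sliding-window width and step.
#' @param multiplier SD multiplier of the segment rule.
#' @return List with `pi`, `track`, `segments`, invisibly.
#' @export
cmd_diversity <- function(fasta, out_dir, window = 10L, step = 1L,
                          multiplier = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- enforce_alignment(read_fasta(fasta))
  pi_all <- nucleotide_diversity(aln)
  track <- sliding_window_pi(aln, window = window, step = step)
  segments <- classify_segments(track, multiplier = multiplier)
  write_track(track, file.path(out_dir, "pi_track.tsv"))
  write_segments(segments, file.path(out_dir, "segments.tsv"), "tsv")
  write_segments(segments, file.path(out_dir, "segments.bed"), "bed")
  report <- data.frame(statistic = c("pi", "n_records", "width"),
                       value = c(pi_all, nrow(aln$mat), aln$width))
  utils::write.table(report, file.path(out_dir, "pi_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "diversity", list(fasta = fasta),
                 list(window = window, step = step,
                      multiplier = multiplier))
  invisible(list(pi = pi_all, track = track, segments = segments))
}

#' Methylation pipeline command
#'
#' Full bisulfite analysis: per-position normalized calls, context/strand
#' summary table, per-strand and pooled methylation window tracks, the
#' diversity track of the native library, and the Spearman
#' methylation-diversity correlation report.
#'
#' @param native_fasta Native (untransformed) monomer FASTA.
#' @param bis_fasta Bisulfite clone FASTA.
#' @param sheet Sample sheet TSV (id, strand, fragment_class).
#' @param out_dir Output directory.
#' @param window,step Window parameters shared by both track types.
#' @param normalization `"ct"` or `"c_only"` (see [call_methylation()]).
#' @param mode Summary aggregation (see [summarize_by_context()]).
#' @param control_fasta Optional unmethylated-control FASTA for conversion
#'   efficiency estimation.
#' @return List with `calls`, `summary`, `tracks`, `correlations`,
#'   `efficiency`, invisibly.
#' @export
cmd_methylation <- function(native_fasta, bis_fasta, sheet, out_dir,
                            window = 10L, step = 1L, normalization = "ct",
                            mode = "observation", control_fasta = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  native <- enforce_alignment(read_fasta(native_fasta))
  consensus <- build_consensus(native)
  reads <- read_bisulfite_reads(bis_fasta, sheet)
  calls <- call_methylation(native, reads, consensus,
                            normalization = normalization)
  summary <- summarize_by_context(calls, mode = mode)
  pi_track <- sliding_window_pi(native, window = window, step = step)
  tracks <- list(pi = pi_track)
  correlations <- list()
  for (strand in c("direct", "complementary", "both")) {
    mt <- sliding_window_methylation(calls, window = window, step = step,
                                     strand = strand)
    tracks[[strand]] <- mt
    correlations[[strand]] <- correlate_tracks(mt, pi_track)
    write_track(mt, file.path(out_dir,
                              paste0("methylation_track_", strand, ".tsv")))
  }
  write_track(pi_track, file.path(out_dir, "pi_track.tsv"))
  write_methylation_table(calls, file.path(out_dir, "methylation_calls.tsv"),
                          comment = paste0("normalization=", normalization))
  write_methylation_table(summary,
                          file.path(out_dir, "context_summary.tsv"),
                          comment = paste0("mode=", mode))
  corr_tab <- do.call(rbind, lapply(names(correlations), function(s) {
    data.frame(strand = s, rho = correlations[[s]]$rho,
               p = correlations[[s]]$p, n = correlations[[s]]$n)
  }))
  utils::write.table(corr_tab, file.path(out_dir, "correlation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  efficiency <- NULL
  if (!is.null(control_fasta)) {
    ctrl <- read_fasta(control_fasta)
    ctrl_reads <- bisulfite_reads(ctrl$id, ctrl$seq, "direct", "external")
    efficiency <- estimate_conversion_efficiency(ctrl_reads, consensus)
    utils::write.table(
      data.frame(statistic = "conversion_efficiency", value = efficiency),
      file.path(out_dir, "conversion_efficiency.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "methylation",
                 list(native = native_fasta, bisulfite = bis_fasta,
                      sheet = sheet, controls = control_fasta),
                 list(window = window, step = step,
                      normalization = normalization, mode = mode))
  invisible(list(calls = calls, summary = summary, tracks = tracks,
                 correlations = correlations, efficiency = efficiency))
}

#' Digestion pipeline command
#'
#' Builds a tandem array from the monomers of a FASTA (in file order,
#' repeated to `n_copies` if a single sequence) and digests it with one of
#' the default enzymes (or an enzyme table), writing the fragment spectrum
#' and a text-mode ladder rendering.
#'
#' @param fasta Monomer FASTA.
#' @param enzyme Enzyme name.
#' @param out_dir Output directory.
#' @param n_copies Copies of the input monomer set in the array.
#' @param partial_probability Per-site cut probability.
#' @param seed Seed for partial digestion.
#' @param enzyme_table Optional TSV of enzyme definitions.
#' @return List with `spectrum`, `ladder`, invisibly.
#' @export
cmd_digest <- function(fasta, enzyme, out_dir, n_copies = 1L,
                       partial_probability = 1, seed = 1L,
                       enzyme_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enzymes <- if (is.null(enzyme_table)) default_enzymes()
             else read_enzyme_table(enzyme_table)
  if (!enzyme %in% names(enzymes)) {
    stop("unknown enzyme '", enzyme, "'; available: ",
         paste(names(enzymes), collapse = ", "))
  }
  recs <- read_fasta(fasta)
  seqs <- rep(gsub("-", "", recs$seq, fixed = TRUE), n_copies)
  array <- tandem_array(stats::setNames(seqs, make.unique(
    rep(recs$id, n_copies))))
  spectrum <- digest(array, enzymes[[enzyme]],
                     partial_probability = partial_probability, seed = seed)
  ladder <- ladder_profile(spectrum)
  write_spectrum(spectrum, file.path(out_dir, "fragment_spectrum.tsv"))
  gel <- utils::capture.output(print(ladder))
  writeLines(gel, file.path(out_dir, "virtual_ladder.txt"))
  write_manifest(out_dir, "digest", list(fasta = fasta),
                 list(enzyme = enzyme, n_copies = n_copies,
                      partial_probability = partial_probability,
                      seed = seed))
  invisible(list(spectrum = spectrum, ladder = ladder))
}

#' Simulation pipeline command
#'
#' Writes a complete synthetic dataset (native monomers, bisulfite clones,
#' sample sheet, controls, ground truth) under the study-condition
#' defaults.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed applied to both generator stages.
#' @param cfg,mcfg Optional [family_config] / [methylation_config]
#'   overriding the defaults (their seeds are replaced by `seed` unless
#'   `seed` is `NULL`).
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, cfg = family_config(),
                         mcfg = methylation_config()) {
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    mcfg$seed <- as.integer(seed) + 1000L
  }
  paths <- make_dataset(cfg, mcfg, out_dir)
  write_manifest(out_dir, "simulate", list(),
                 list(seed = seed, monomer_length = cfg$monomer_length,
                      n_monomers = as.list(cfg$n_monomers),
                      rates = as.list(mcfg$rates),
                      conversion_efficiency = mcfg$conversion_efficiency))
  invisible(paths)
}
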