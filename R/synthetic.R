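#' Configuration for the synthetic satellite family generator
#'
#' Defaults emulate the study system: a 315-bp monomer family with
#' intraspecific diversity around 0.03, G+C near 0.44, rare single-base
#' indels, a mosaic of conserved and variable segments, and restriction
#' motifs planted so the digestion analyses have a realistic target map
#' (one conserved HaeIII and TaqI site, a PvuII site in a variable region,
#' three CCGG isoschizomer targets).
#'
#' @param monomer_length Monomer length in bp.
#' @param n_monomers Named integer vector: monomers per species.
#' @param per_site_substitution_prob Baseline per-site substitution
#'   probability per monomer (pairwise diversity is roughly twice this).
#' @param indel_prob Per-monomer probability of a single-base indel.
#' @param gc_target Target G+C fraction of the ancestral monomer.
#' @param conserved_blocks List of 1-based intervals with reduced
#'   substitution rate.
#' @param conserved_multiplier Substitution-rate multiplier inside
#'   conserved blocks.
#' @param variable_blocks List of intervals with elevated substitution rate.
#' @param variable_multiplier Substitution-rate multiplier inside variable
#'   blocks.
#' @param ts_tv_ratio Relative weight of the transition versus each
#'   transversion when a site mutates (1 = uniform among the 3
#'   alternatives).
#' @param planted_motifs Named character vector motif -> 1-based position in
#'   the ancestral monomer.
#' @param seed Integer seed; every draw is deterministic under it.
#' @return A list of class `family_config`.
#' @export
family_config <- function(monomer_length = 315L,
                          n_monomers = c(spA = 39L),
                          per_site_substitution_prob = 0.015,
                          indel_prob = 0.025,
                          gc_target = 0.4405,
                          conserved_blocks = list(c(41L, 89L),
                                                  c(199L, 232L)),
                          conserved_multiplier = 0.2,
                          variable_blocks = list(c(10L, 24L),
                                                 c(105L, 119L),
                                                 c(160L, 174L),
                                                 c(250L, 264L)),
                          variable_multiplier = 2.0,
                          ts_tv_ratio = 1,
                          planted_motifs = c(CCGG = 30L, GGCC = 50L,
                                             CAGCTG = 108L, CCGG2 = 150L,
                                             TCGA = 210L, CCGG3 = 270L),
                          seed = 1L) {
  stopifnot(per_site_substitution_prob >= 0,
            per_site_substitution_prob <= 1,
            indel_prob >= 0, indel_prob <= 1,
            gc_target > 0, gc_target < 1)
  structure(as.list(environment()), class = "family_config")
}

#' Configuration for synthetic methylation and bisulfite conversion
#'
#' Default per-context rates and conversion efficiency are the study-like
#' conditions (CG 5.65%, CHG 1.79%, CHH 2.69%; efficiency 98.7%); hot
#' blocks carry a multiplicative (x3) rate elevation, mirroring a satellite
#' whose methylation triplicates the genomic mean in two segments.
#'
#' @param rates Named fractions: per-context methylation probability.
#' @param strand_symmetric Mirror CG methylation across strands?
#' @param hot_blocks List of intervals with elevated rates.
#' @param hot_multiplier Rate multiplier inside hot blocks.
#' @param conversion_efficiency Probability that an unmethylated C reads T.
#' @param over_conversion Probability that a methylated C reads T (0 =
#'   perfect protection).
#' @param n_reads Named integer vector: clones per strand.
#' @param seed Integer seed.
#' @return A list of class `methylation_config`.
#' @export
methylation_config <- function(rates = c(CG = 0.0565, CHG = 0.0179,
                                         CHH = 0.0269),
                               strand_symmetric = FALSE,
                               hot_blocks = list(c(60L, 89L),
                                                 c(209L, 221L)),
                               hot_multiplier = 3,
                               conversion_efficiency = 0.987,
                               over_conversion = 0,
                               n_reads = c(direct = 33L,
                                           complementary = 26L),
                               seed = 1L) {
  stopifnot(all(rates >= 0), all(rates <= 1),
            conversion_efficiency > 0, conversion_efficiency <= 1,
            all(c("CG", "CHG", "CHH") %in% names(rates)))
  structure(as.list(environment()), class = "methylation_config")
}

# Ancestral monomer: planted motifs first, then the remaining positions
# filled with an exact base count hitting the global G+C target (randomness
# only in the arrangement), and chance occurrences of the planted motifs
# outside their planted positions scrubbed so the restriction map is
# controlled.
draw_ancestral <- function(cfg) {
  L <- cfg$monomer_length
  chars <- rep(NA_character_, L)
  motif_strs <- unique(gsub("[0-9]", "", names(cfg$planted_motifs)))
  for (m in seq_along(cfg$planted_motifs)) {
    motif <- seq_chars(gsub("[0-9]", "", names(cfg$planted_motifs)[m]))
    at <- cfg$planted_motifs[[m]]
    if (at + length(motif) - 1L > L) stop("planted motif exceeds monomer")
    chars[at:(at + length(motif) - 1L)] <- motif
  }
  n_gc_total <- round(cfg$gc_target * L)
  n_gc_rest <- max(0L, n_gc_total - sum(chars %in% c("G", "C"), na.rm = TRUE))
  n_rest <- sum(is.na(chars))
  n_gc_rest <- min(n_gc_rest, n_rest)
  n_at_rest <- n_rest - n_gc_rest
  pool <- c(rep(c("G", "C"), length.out = n_gc_rest),
            rep(c("A", "T"), length.out = n_at_rest))
  chars[is.na(chars)] <- sample(pool)
  s <- chars_seq(chars)
  planted_at <- unname(cfg$planted_motifs)
  for (iter in 1:50) {
    dirty <- FALSE
    for (motif in motif_strs) {
      hit <- gregexpr(motif, s, fixed = TRUE)[[1]]
      hit <- hit[hit > 0 & !(hit %in% planted_at)]
      for (h in hit) {
        repl <- sample(setdiff(SAT_BASES, substr(s, h, h)), 1L)
        substr(s, h, h) <- repl
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  s
}

site_rates <- function(cfg) {
  r <- rep(cfg$per_site_substitution_prob, cfg$monomer_length)
  pos <- seq_len(cfg$monomer_length)
  r[in_intervals(pos, cfg$conserved_blocks)] <-
    cfg$per_site_substitution_prob * cfg$conserved_multiplier
  r[in_intervals(pos, cfg$variable_blocks)] <-
    cfg$per_site_substitution_prob * cfg$variable_multiplier
  pmin(r, 1)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

mutate_base <- function(base, kappa) {
  ts <- TRANSITION[[base]]
  tv <- setdiff(SAT_BASES, c(base, ts))
  sample(c(ts, tv), 1L, prob = c(kappa, 1, 1) / (kappa + 2))
}

#' Generate a synthetic satellite monomer family
#'
#' An ancestral monomer is drawn at the target G+C and each monomer derived
#' from it by independent per-site substitution (rate reduced in conserved
#' blocks, elevated in variable blocks) plus rare single-base indels —
#' a simple concerted-evolution "library" surrogate in which all species
#' sample the same ancestral variant pool.
#'
#' @param cfg A [family_config].
#' @return List with `ancestral` ([sat_records], one row), `records`
#'   (ungapped monomers) and `alignment` (`monomer_alignment`).
#' @export
generate_family <- function(cfg = family_config()) {
  withr::with_seed(cfg$seed, {
    anc <- draw_ancestral(cfg)
    rates <- site_rates(cfg)
    anc_chars <- seq_chars(anc)
    ids <- character(0)
    seqs <- character(0)
    for (sp in names(cfg$n_monomers)) {
      for (i in seq_len(cfg$n_monomers[[sp]])) {
        chars <- anc_chars
        hit <- which(stats::runif(cfg$monomer_length) < rates)
        for (h in hit) chars[h] <- mutate_base(chars[h], cfg$ts_tv_ratio)
        if (stats::runif(1) < cfg$indel_prob) {
          at <- sample.int(length(chars), 1L)
          if (stats::runif(1) < 0.8) {
            chars <- chars[-at] # single-base deletion
          } else {
            chars <- append(chars, sample(SAT_BASES, 1L), after = at)
          }
        }
        ids <- c(ids, sprintf("%s_m%02d", sp, i))
        seqs <- c(seqs, chars_seq(chars))
      }
    }
    records <- sat_records(ids, seqs)
    ancestral <- sat_records("ancestral", anc, species = "ancestral")
    list(ancestral = ancestral, records = records,
         alignment = enforce_alignment(records, reference = ancestral))
  })
}

#' Assign per-molecule methylation states
#'
#' Every cytosine of every molecule (both strands, circular context on the
#' molecule itself) is methylated independently with its context rate,
#' multiplied inside hot blocks. With `strand_symmetric = TRUE` the CG
#' state drawn on the direct strand is mirrored to its complementary-strand
#' partner.
#'
#' @param records A [sat_records] data frame of ungapped monomers.
#' @param mcfg A [methylation_config].
#' @return Named list (by record id) of data frames with columns
#'   `position`, `strand`.
#' @export
assign_methylation <- function(records, mcfg = methylation_config()) {
  withr::with_seed(mcfg$seed, {
    maps <- vector("list", nrow(records))
    names(maps) <- records$id
    for (i in seq_len(nrow(records))) {
      s <- records$seq[i]
      L <- nchar(s)
      rows <- list()
      ctx_d <- context_map(s, "direct")
      ctx_c <- context_map(s, "complementary")
      rate_at <- function(ctx, pos) {
        if (!ctx %in% c("CG", "CHG", "CHH")) return(0)
        r <- mcfg$rates[[ctx]]
        if (in_intervals(pos, mcfg$hot_blocks)) r <- r * mcfg$hot_multiplier
        min(r, 1)
      }
      meth_d <- logical(L)
      for (p in which(ctx_d %in% c("CG", "CHG", "CHH"))) {
        meth_d[p] <- stats::runif(1) < rate_at(ctx_d[p], p)
      }
      meth_c <- logical(L)
      for (p in which(ctx_c %in% c("CG", "CHG", "CHH"))) {
        if (mcfg$strand_symmetric && ctx_c[p] == "CG" && p > 1L &&
            ctx_d[p - 1L] == "CG") {
          meth_c[p] <- meth_d[p - 1L] # mirrored CpG partner
        } else {
          meth_c[p] <- stats::runif(1) < rate_at(ctx_c[p], p)
        }
      }
      maps[[i]] <- data.frame(
        position = c(which(meth_d), which(meth_c)),
        strand = rep(c("direct", "complementary"),
                     c(sum(meth_d), sum(meth_c))),
        stringsAsFactors = FALSE)
    }
    maps
  })
}

#' Bisulfite-convert one molecule
#'
#' Unmethylated cytosines read as `T` with probability `efficiency`
#' (conversion failures stay `C`); methylated cytosines stay `C` (or
#' convert with probability `over_conversion`). Complementary-strand reads
#' are produced from the reverse complement before conversion.
#'
#' @param seq Molecule sequence (direct strand, 5'->3').
#' @param methylation_map Data frame with `position`, `strand` (molecule
#'   coordinates).
#' @param efficiency Conversion efficiency in `(0, 1]`.
#' @param strand Strand of the produced read.
#' @param over_conversion Probability of converting a methylated C.
#' @param seed Optional seed (otherwise the caller's RNG stream is used).
#' @return Converted read sequence (character scalar).
#' @export
bisulfite_convert <- function(seq, methylation_map = NULL,
                              efficiency = 0.987,
                              strand = c("direct", "complementary"),
                              over_conversion = 0, seed = NULL) {
  strand <- match.arg(strand)
  run <- function() {
    L <- nchar(seq)
    if (strand == "direct") {
      chars <- seq_chars(seq)
      meth <- methylation_map$position[methylation_map$strand == "direct"]
    } else {
      chars <- seq_chars(revcomp(seq))
      mp <- methylation_map$position[
        methylation_map$strand == "complementary"]
      meth <- L - mp + 1L # molecule coordinate -> read coordinate
    }
    is_meth <- seq_along(chars) %in% meth
    for (p in which(chars == "C")) {
      pr <- if (is_meth[p]) over_conversion else efficiency
      if (stats::runif(1) < pr) chars[p] <- "T"
    }
    chars_seq(chars)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate bisulfite-treated unmethylated control reads
#'
#' Emulates the PCR-product control: molecules identical to the reference,
#' carrying no methylation, converted at the stated efficiency.
#'
#' @param reference Reference sequence (character scalar or single-row
#'   [sat_records]).
#' @param n Number of control reads.
#' @param efficiency Conversion efficiency.
#' @param strand Strand of the reads.
#' @param seed Integer seed.
#' @return A [bisulfite_reads] data frame.
#' @export
generate_control_reads <- function(reference, n = 30L, efficiency = 0.987,
                                   strand = "direct", seed = 1L) {
  ref <- if (is_sat_records(reference)) reference$seq[1L]
         else as.character(reference)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      bisulfite_convert(ref, NULL, efficiency, strand)
    }, character(1))
    bisulfite_reads(sprintf("ctrl_%02d", seq_len(n)), seqs, strand,
                    "external")
  })
}

#' Write a complete synthetic pipeline dataset
#'
#' Emits the native monomer FASTA, a bisulfite clone FASTA with its sample
#' sheet, an unmethylated control FASTA, and a ground-truth JSON (rates,
#' efficiency, blocks, per-read source molecules) for recovery tests.
#' Byte-identical across runs under the same seeds.
#'
#' @param cfg A [family_config].
#' @param mcfg A [methylation_config].
#' @param out_dir Output directory (created if missing).
#' @param n_controls Number of unmethylated control reads.
#' @return Named character vector of written paths, invisibly; the
#'   generated objects as the `"objects"` attribute.
#' @export
make_dataset <- function(cfg = family_config(),
                         mcfg = methylation_config(), out_dir,
                         n_controls = 30L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam <- generate_family(cfg)
  maps <- assign_methylation(fam$records, mcfg)
  n_mol <- nrow(fam$records)
  ext_frac <- c(direct = 15 / 33, complementary = 15 / 26)
  reads <- withr::with_seed(mcfg$seed + 1L, {
    rows <- list()
    for (strand in names(mcfg$n_reads)) {
      n <- mcfg$n_reads[[strand]]
      src <- sample.int(n_mol, n, replace = TRUE)
      n_ext <- round(ext_frac[[strand]] * n)
      fclass <- sample(rep(c("external", "internal"), c(n_ext, n - n_ext)))
      for (k in seq_len(n)) {
        seqk <- bisulfite_convert(fam$records$seq[src[k]], maps[[src[k]]],
                                  mcfg$conversion_efficiency, strand,
                                  mcfg$over_conversion)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("bis%s_%03d", substr(strand, 1, 1), k),
          seq = seqk, strand = strand, fragment_class = fclass[k],
          source = fam$records$id[src[k]], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  controls <- generate_control_reads(fam$ancestral, n_controls,
                                     mcfg$conversion_efficiency,
                                     seed = mcfg$seed + 2L)
  paths <- c(native = file.path(out_dir, "native_monomers.fasta"),
             bisulfite = file.path(out_dir, "bisulfite_clones.fasta"),
             sheet = file.path(out_dir, "sample_sheet.tsv"),
             controls = file.path(out_dir, "controls.fasta"),
             truth = file.path(out_dir, "truth.json"))
  write_fasta(fam$records, paths[["native"]])
  write_fasta(reads, paths[["bisulfite"]])
  utils::write.table(reads[, c("id", "strand", "fragment_class", "source")],
                     paths[["sheet"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(controls, paths[["controls"]])
  truth <- list(
    rates = as.list(mcfg$rates),
    hot_blocks = lapply(mcfg$hot_blocks, as.integer),
    hot_multiplier = mcfg$hot_multiplier,
    conversion_efficiency = mcfg$conversion_efficiency,
    conserved_blocks = lapply(cfg$conserved_blocks, as.integer),
    variable_blocks = lapply(cfg$variable_blocks, as.integer),
    monomer_length = cfg$monomer_length,
    per_site_substitution_prob = cfg$per_site_substitution_prob,
    seeds = list(family = cfg$seed, methylation = mcfg$seed),
    n_methylated = sum(vapply(maps, nrow, integer(1))),
    read_sources = stats::setNames(as.list(reads$source), reads$id))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res <- structure(paths,
                   objects = list(family = fam, maps = maps,
                                  reads = bisulfite_reads(
                                    reads$id, reads$seq, reads$strand,
                                    reads$fragment_class),
                                  controls = controls))
  invisible(res)
}
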