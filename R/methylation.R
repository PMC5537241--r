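#' Construct a set of bisulfite clone reads
#'
#' Each read is one sequenced clone (Sanger-style: one molecule per read),
#' with a strand label (`direct`/`complementary`) and a fragment class
#' (`external`/`internal`). Primer-derived stretches can be masked per read
#' and are excluded from all downstream counting.
#'
#' @param id,seq Character vectors of ids and sequences.
#' @param strand `"direct"` or `"complementary"`, recycled.
#' @param fragment_class `"external"` or `"internal"`, recycled.
#' @param primer_mask Optional named list (by read id) of 2-column matrices
#'   of 1-based inclusive read-coordinate intervals to exclude.
#' @return A data frame of class `bisulfite_reads` with a `primer_mask`
#'   attribute.
#' @export
bisulfite_reads <- function(id, seq, strand = "direct",
                            fragment_class = "internal",
                            primer_mask = NULL) {
  strand <- rep_len(as.character(strand), length(id))
  fragment_class <- rep_len(as.character(fragment_class), length(id))
  if (!all(strand %in% c("direct", "complementary"))) {
    stop("strand must be 'direct' or 'complementary'")
  }
  if (!all(fragment_class %in% c("external", "internal"))) {
    stop("fragment_class must be 'external' or 'internal'")
  }
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    strand = strand, fragment_class = fragment_class,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicate read IDs")
  attr(out, "primer_mask") <- primer_mask
  class(out) <- c("bisulfite_reads", "data.frame")
  out
}

#' Read bisulfite clones from FASTA plus a sample sheet
#'
#' @param fasta Path to the clone FASTA.
#' @param sheet Path to a TSV sample sheet with columns `id`, `strand`,
#'   `fragment_class` (and optionally `mask_start`, `mask_end`).
#' @return A [bisulfite_reads] data frame.
#' @export
read_bisulfite_reads <- function(fasta, sheet) {
  recs <- read_fasta(fasta)
  meta <- read_sample_sheet(sheet)
  idx <- match(recs$id, meta$id)
  if (anyNA(idx)) {
    stop("reads missing from sample sheet: ",
         paste(recs$id[is.na(idx)], collapse = ", "))
  }
  masks <- NULL
  if (all(c("mask_start", "mask_end") %in% names(meta))) {
    has <- !is.na(meta$mask_start[idx])
    masks <- stats::setNames(
      lapply(which(has), function(i) {
        cbind(meta$mask_start[idx[i]], meta$mask_end[idx[i]])
      }),
      recs$id[has])
  }
  bisulfite_reads(recs$id, recs$seq, meta$strand[idx],
                  meta$fragment_class[idx], primer_mask = masks)
}

#' Classify the methylation context of a position
#'
#' `CG` if the next base (5'->3' on the given sequence) is `G`; else `CHG`
#' if the base two ahead is `G`; else `CHH` (`H` = A, C or T). Positions not
#' carrying a `C` are `non_C`. With `circular = TRUE` successor positions
#' wrap around the monomer end (tandem-array context). Gap characters are
#' skipped when walking to successors; an `N` at a needed successor yields
#' `CHH_unresolved`.
#'
#' @param seq Sequence (character scalar), read 5'->3' on the strand of
#'   interest.
#' @param pos 1-based position(s) within `seq`.
#' @param circular Wrap successor lookups around the sequence end?
#' @return Character vector over
#'   `{CG, CHG, CHH, non_C, CHH_unresolved}`.
#' @export
classify_context <- function(seq, pos, circular = TRUE) {
  chars <- seq_chars(seq)
  if (any(pos < 1L | pos > length(chars))) stop("position out of range")
  ng <- which(chars != "-")
  rank_of <- match(seq_along(chars), ng) # NA for gap positions
  succ <- function(p, k) {
    r <- rank_of[p]
    if (is.na(r)) return(NA_character_)
    r2 <- r + k
    if (r2 > length(ng)) {
      if (!circular) return(NA_character_)
      r2 <- ((r2 - 1L) %% length(ng)) + 1L
    }
    chars[ng[r2]]
  }
  vapply(pos, function(p) {
    b <- chars[p]
    if (is.na(b) || b != "C") return("non_C")
    b1 <- succ(p, 1L)
    if (is.na(b1) || b1 == "N") return("CHH_unresolved")
    if (b1 == "G") return("CG")
    b2 <- succ(p, 2L)
    if (is.na(b2) || b2 == "N") return("CHH_unresolved")
    if (b2 == "G") return("CHG")
    "CHH"
  }, character(1))
}

# context at every monomer coordinate, on the requested strand, using the
# consensus string (coordinates are always direct-strand monomer positions)
context_map <- function(consensus_seq, strand = c("direct", "complementary"),
                        circular = TRUE) {
  strand <- match.arg(strand)
  w <- nchar(consensus_seq)
  if (strand == "direct") {
    return(classify_context(consensus_seq, seq_len(w), circular))
  }
  rc <- revcomp(consensus_seq)
  ctx_rc <- classify_context(rc, seq_len(w), circular)
  ctx_rc[w - seq_len(w) + 1L] # rc position w-p+1 <-> monomer position p
}

# bisulfite-aware substitution matrix: pattern (read) T matches subject C
bisulfite_submat <- function() {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- 1
  m["T", "C"] <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Map a bisulfite read onto monomer coordinates
#'
#' Global alignment of the read against the strand-appropriate consensus
#' (complementary-strand reads are aligned against the reverse complement)
#' under an asymmetric scoring scheme in which read `T` against reference
#' `C` counts as a match (bisulfite conversion is not a mismatch). Reads
#' whose bisulfite-aware identity falls below `min_identity` are rejected.
#'
#' @param seq Read sequence (5'->3' as sequenced).
#' @param consensus A `consensus_profile` or consensus string; coordinates
#'   of the mapping are its (direct-strand) columns.
#' @param strand `"direct"` or `"complementary"`.
#' @param primer_mask Optional 2-column matrix of read-coordinate intervals
#'   to exclude from the mapping.
#' @param min_identity Bisulfite-aware identity threshold (default 0.7).
#' @param min_length Minimal unmasked read length (default 50).
#' @return List with `accepted` (logical), `mapping` (integer vector, one
#'   monomer coordinate or `NA` per read position), `identity`, and
#'   `reason` when rejected.
#' @export
bisulfite_align <- function(seq, consensus,
                            strand = c("direct", "complementary"),
                            primer_mask = NULL, min_identity = 0.7,
                            min_length = 50L) {
  strand <- match.arg(strand)
  cons <- if (inherits(consensus, "consensus_profile")) consensus$consensus
          else as.character(consensus)
  w <- nchar(cons)
  ref_str <- if (strand == "direct") cons else revcomp(cons)
  ref_chars <- seq_chars(ref_str)
  keep <- ref_chars != "-"
  ref_cols <- which(keep) # degapped ref position -> reference column
  ref_seq <- chars_seq(ref_chars[keep])

  read <- gsub("-", "", seq, fixed = TRUE)
  n_read <- nchar(read)
  masked <- in_intervals(seq_len(n_read), primer_mask)
  if (sum(!masked) <= min_length) {
    return(list(accepted = FALSE, mapping = NULL, identity = NA_real_,
                reason = "read shorter than minimum after primer masking"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ref_seq),
    substitutionMatrix = bisulfite_submat(), gapOpening = 4,
    gapExtension = 1, type = "global")
  pc <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sc <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  mapping <- rep(NA_integer_, n_read)
  rp <- 0L
  sp <- 0L
  n_match <- 0L
  for (k in seq_along(pc)) {
    if (pc[k] != "-") rp <- rp + 1L
    if (sc[k] != "-") sp <- sp + 1L
    if (pc[k] == "-" || sc[k] == "-") next
    if (pc[k] == sc[k] || (pc[k] == "T" && sc[k] == "C")) {
      n_match <- n_match + 1L
    }
    mapping[rp] <- sp
  }
  # identity over all alignment columns, so gap-riddled alignments of
  # unrelated sequences cannot masquerade as high-identity matches
  identity <- n_match / length(pc)
  if (identity < min_identity) {
    return(list(accepted = FALSE, mapping = NULL, identity = identity,
                reason = sprintf("bisulfite-aware identity %.3f below %.2f",
                                 identity, min_identity)))
  }
  # degapped ref position -> reference column -> monomer coordinate
  mono <- ref_cols[mapping]
  if (strand == "complementary") mono <- w - mono + 1L
  mono[masked] <- NA_integer_
  list(accepted = TRUE, mapping = mono, identity = identity, reason = NULL)
}

#' Call per-position normalized methylation
#'
#' For every monomer position whose native (untransformed) library column
#' carries cytosine or thymine on the requested strand, the fraction of
#' mapped bisulfite reads retaining `C` is divided by the native C+T
#' fraction — the mutation-bias normalization — giving `m_normalized`. The
#' alternative cytosine-only denominator is available via
#' `normalization = "c_only"`. Ratios above 1 (sampling noise) are clamped
#' to 1 and flagged in the `clamped` column.
#'
#' @param native A `monomer_alignment` of untransformed monomers (its
#'   columns define the coordinate system).
#' @param reads A [bisulfite_reads] data frame.
#' @param consensus Optional `consensus_profile`; built from `native` if
#'   missing.
#' @param normalization `"ct"` (native C+T denominator, default) or
#'   `"c_only"`.
#' @param conversion_efficiency Optional known or estimated bisulfite
#'   conversion efficiency. When supplied, the conversion-failure
#'   background is removed from each call via
#'   `m_adj = (m - (1 - e)) / e` (clamped to `[0, 1]`); by default no
#'   correction is applied and `m_normalized` retains the failure
#'   background, as in the plain normalized estimator.
#' @param min_identity Read acceptance threshold passed to
#'   [bisulfite_align()].
#' @return A data frame of class `methylation_calls` with one row per
#'   (position, strand): `position`, `strand`, `context`, `n_reads`,
#'   `bis_C`, `native_C`, `native_CT`, `m_normalized`, `clamped`. Rejected
#'   read ids are stored in the `rejected` attribute.
#' @export
call_methylation <- function(native, reads, consensus = NULL,
                             normalization = c("ct", "c_only"),
                             conversion_efficiency = NULL,
                             min_identity = 0.7) {
  normalization <- match.arg(normalization)
  if (is.null(consensus)) consensus <- build_consensus(native)
  w <- consensus$width
  if (native$width != w) stop("native alignment and consensus widths differ")
  freqs <- column_freqs(native)
  base_tot <- colSums(freqs[SAT_BASES, , drop = FALSE])
  basef <- sweep(freqs[SAT_BASES, , drop = FALSE], 2L,
                 pmax(base_tot, .Machine$double.eps), "/")
  basef[, base_tot == 0] <- NA_real_
  masks <- attr(reads, "primer_mask")

  out <- list()
  rejected <- character(0)
  for (strand in c("direct", "complementary")) {
    nat_C <- if (strand == "direct") basef["C", ] else basef["G", ]
    nat_T <- if (strand == "direct") basef["T", ] else basef["A", ]
    nat_CT <- nat_C + nat_T
    ctx <- context_map(consensus$consensus, strand)
    cov <- integer(w)
    isC <- integer(w)
    for (i in which(reads$strand == strand)) {
      al <- bisulfite_align(reads$seq[i], consensus, strand,
                            primer_mask = masks[[reads$id[i]]],
                            min_identity = min_identity)
      if (!al$accepted) {
        rejected <- c(rejected, stats::setNames(al$reason, reads$id[i]))
        next
      }
      rc <- gsub("-", "", reads$seq[i], fixed = TRUE)
      ok <- !is.na(al$mapping)
      pos <- al$mapping[ok]
      base <- seq_chars(rc)[ok]
      cov[pos] <- cov[pos] + 1L
      hitC <- pos[base == "C"]
      isC[hitC] <- isC[hitC] + 1L
    }
    emit <- which(!is.na(nat_CT) & nat_CT > 0)
    bis_C <- ifelse(cov[emit] > 0L, isC[emit] / cov[emit], NA_real_)
    denom <- if (normalization == "ct") nat_CT[emit] else nat_C[emit]
    m <- bis_C / denom
    m[!is.finite(m)] <- NA_real_
    if (!is.null(conversion_efficiency)) {
      e <- conversion_efficiency
      stopifnot(e > 0, e <= 1)
      m <- pmax((m - (1 - e)) / e, 0)
    }
    clamped <- !is.na(m) & m > 1
    m[clamped] <- 1
    out[[strand]] <- data.frame(
      position = emit, strand = strand, context = ctx[emit],
      n_reads = cov[emit], bis_C = bis_C, native_C = nat_C[emit],
      native_CT = nat_CT[emit], m_normalized = m, clamped = clamped,
      stringsAsFactors = FALSE)
  }
  calls <- rbind(out$direct, out$complementary)
  rownames(calls) <- NULL
  if (length(rejected) > 0L) {
    warning(length(rejected), " read(s) rejected: ",
            paste(names(rejected), collapse = ", "))
  }
  attr(calls, "normalization") <- normalization
  attr(calls, "width") <- w
  attr(calls, "rejected") <- rejected
  class(calls) <- c("methylation_calls", "data.frame")
  calls
}

#' Summarize methylation by context and strand
#'
#' The default aggregation is observation-weighted (methylation events over
#' eligible cytosine-site observations pooled across reads and sites);
#' `mode = "site"` averages `m_normalized` over sites instead. The `both`
#' column pools the two strands' observations, and the `all_C` row is the
#' weighted mean of the three contexts.
#'
#' @param calls A `methylation_calls` data frame.
#' @param mode `"observation"` (default) or `"site"`.
#' @return A data frame of class `context_summary` with rows
#'   `CG, CHG, CHH, all_C` and columns `direct`, `complementary`, `both`
#'   (fractions; `NA` for empty cells).
#' @export
summarize_by_context <- function(calls, mode = c("observation", "site")) {
  mode <- match.arg(mode)
  use <- calls[calls$context %in% c("CG", "CHG", "CHH") &
                 !is.na(calls$m_normalized), , drop = FALSE]
  cell <- function(rows) {
    if (nrow(rows) == 0L) return(NA_real_)
    if (mode == "observation") {
      if (sum(rows$n_reads) == 0L) return(NA_real_)
      sum(rows$n_reads * rows$m_normalized) / sum(rows$n_reads)
    } else {
      mean(rows$m_normalized)
    }
  }
  contexts <- c("CG", "CHG", "CHH", "all_C")
  out <- data.frame(site = contexts, direct = NA_real_,
                    complementary = NA_real_, both = NA_real_,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(contexts)) {
    sub <- if (contexts[ci] == "all_C") use
           else use[use$context == contexts[ci], , drop = FALSE]
    out$direct[ci] <- cell(sub[sub$strand == "direct", , drop = FALSE])
    out$complementary[ci] <-
      cell(sub[sub$strand == "complementary", , drop = FALSE])
    out$both[ci] <- cell(sub)
  }
  attr(out, "mode") <- mode
  class(out) <- c("context_summary", "data.frame")
  out
}

#' Estimate bisulfite conversion efficiency from unmethylated controls
#'
#' Control reads derive from PCR product and are unmethylated by
#' construction, so every reference cytosine should read as `T`; the
#' efficiency is the fraction that does, over covered reference-C positions
#' (primer-masked stretches excluded).
#'
#' @param control_reads A [bisulfite_reads] data frame.
#' @param reference Reference sequence (character scalar, single-row
#'   [sat_records], or `consensus_profile`).
#' @param min_identity Read acceptance threshold.
#' @return Efficiency, a fraction in `[0, 1]`.
#' @export
estimate_conversion_efficiency <- function(control_reads, reference,
                                           min_identity = 0.7) {
  ref <- if (inherits(reference, "consensus_profile")) reference$consensus
         else if (is_sat_records(reference)) reference$seq[1L]
         else as.character(reference)
  masks <- attr(control_reads, "primer_mask")
  ref_chars <- seq_chars(ref)
  n_cov <- 0L
  n_T <- 0L
  for (i in seq_len(nrow(control_reads))) {
    strand <- control_reads$strand[i]
    al <- bisulfite_align(control_reads$seq[i], ref, strand,
                          primer_mask = masks[[control_reads$id[i]]],
                          min_identity = min_identity)
    if (!al$accepted) next
    rc <- seq_chars(gsub("-", "", control_reads$seq[i], fixed = TRUE))
    ok <- !is.na(al$mapping)
    pos <- al$mapping[ok]
    base <- rc[ok]
    ref_base <- ref_chars[pos]
    target <- if (strand == "direct") "C" else "G" # C on that strand
    at_C <- ref_base == target
    n_cov <- n_cov + sum(at_C)
    n_T <- n_T + sum(at_C & base == "T")
  }
  if (n_cov == 0L) stop("no covered reference cytosine positions")
  n_T / n_cov
}

#' Sliding-window methylation track
#'
#' Per window, the observation-weighted mean of `m_normalized` over
#' cytosine-capable positions (contexts CG/CHG/CHH). Windows containing no
#' such position (or no covered one) are `NA`. The `mean + 2*sd` threshold
#' used to annotate highly methylated windows is stored as the
#' `threshold_hi` element.
#'
#' @param calls A `methylation_calls` data frame.
#' @param window,step Window width and step (defaults 10 and 1).
#' @param strand `"direct"`, `"complementary"` or `"both"` (pooled).
#' @return A `window_track` (stat `"methylation"`).
#' @export
sliding_window_methylation <- function(calls, window = 10L, step = 1L,
                                       strand = c("direct", "complementary",
                                                  "both")) {
  strand <- match.arg(strand)
  w <- attr(calls, "width") %||% max(calls$position)
  use <- calls[calls$context %in% c("CG", "CHG", "CHH"), , drop = FALSE]
  if (strand != "both") use <- use[use$strand == strand, , drop = FALSE]
  if (nrow(use) == 0L) stop("no cytosine-context calls for strand ", strand)
  events <- numeric(w)
  opp <- numeric(w)
  scored <- !is.na(use$m_normalized)
  for (i in which(scored)) {
    p <- use$position[i]
    events[p] <- events[p] + use$n_reads[i] * use$m_normalized[i]
    opp[p] <- opp[p] + use$n_reads[i]
  }
  starts <- seq(1L, w - window + 1L, by = step)
  values <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    o <- sum(opp[idx])
    if (o == 0) return(NA_real_)
    sum(events[idx]) / o
  }, numeric(1))
  track <- new_window_track(starts, values, window, step, w,
                            stat = "methylation")
  track$threshold_hi <- if (is.na(track$sd)) NA_real_ else
    track$mean + 2 * track$sd
  track
}

#' Spearman correlation between two position/window tracks
#'
#' Rank correlation with average ranks for ties; the p-value comes from the
#' large-sample t approximation by default, or from a seeded permutation
#' test.
#'
#' @param meth,pi `window_track` objects or numeric vectors of equal length
#'   (paired by index; `NA` pairs dropped).
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Number of permutations (>= 10000 recommended).
#' @param seed Seed for the permutation test.
#' @return List of class `track_correlation`: `rho`, `p`, `n`, `method`.
#' @export
correlate_tracks <- function(meth, pi, method = c("t", "permutation"),
                             n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  xv <- if (inherits(meth, "window_track")) meth$values else as.numeric(meth)
  yv <- if (inherits(pi, "window_track")) pi$values else as.numeric(pi)
  if (length(xv) != length(yv)) stop("series lengths differ")
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 5L) stop("need at least 5 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    out <- list(rho = NA_real_, p = NA_real_, n = n, method = method)
    class(out) <- "track_correlation"
    return(out)
  }
  if (method == "t") {
    ct <- suppressWarnings(
      stats::cor.test(xv, yv, method = "spearman", exact = FALSE))
    out <- list(rho = unname(ct$estimate), p = ct$p.value, n = n,
                method = "t")
  } else {
    rho <- stats::cor(xv, yv, method = "spearman")
    if (!is.null(seed)) {
      perm <- withr::with_seed(seed, replicate(
        n_perm, stats::cor(xv, sample(yv), method = "spearman")))
    } else {
      perm <- replicate(n_perm,
                        stats::cor(xv, sample(yv), method = "spearman"))
    }
    p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
    out <- list(rho = rho, p = p, n = n, method = "permutation")
  }
  class(out) <- "track_correlation"
  out
}

#' @export
print.track_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Write methylation calls or a context summary as TSV
#'
#' @param x A `methylation_calls` or `context_summary` data frame.
#' @param path Output path.
#' @param comment Optional `#`-prefixed provenance header lines.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
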