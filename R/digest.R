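#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param recognition Recognition motif over `{A,C,G,T}` (length >= 4).
#' @param cut_offset Bases from the motif start to the cut on the direct
#'   strand (0 <= offset <= motif length).
#' @param sensitivity Methylation-sensitivity rule keyword:
#'   `"insensitive"` (cuts regardless of methylation),
#'   `"blocked_by_outer_C"` (MspI-style: blocked when the outer C of a CCGG
#'   site is methylated on either strand), or
#'   `"blocked_by_full_internal_C"` (HpaII-style: blocked only when the
#'   internal C is methylated on both strands, so hemimethylated sites are
#'   still cut).
#' @return A list of class `rest_enzyme`.
#' @export
rest_enzyme <- function(name, recognition, cut_offset,
                        sensitivity = c("insensitive", "blocked_by_outer_C",
                                        "blocked_by_full_internal_C")) {
  sensitivity <- match.arg(sensitivity)
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition motif shorter than 4")
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset outside recognition motif")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 sensitivity = sensitivity),
            class = "rest_enzyme")
}

#' Default enzyme table
#'
#' The enzymes used in the satellite restriction analyses: HaeIII (GGCC),
#' TaqI (TCGA) and PvuII (CAGCTG) are methylation-insensitive; the
#' isoschizomers MspI and HpaII share the CCGG target but differ in
#' sensitivity (MspI blocked by outer-C methylation; HpaII blocked only by
#' full internal-C methylation, cutting hemimethylated sites).
#'
#' @return Named list of [rest_enzyme] objects.
#' @export
default_enzymes <- function() {
  list(
    HaeIII = rest_enzyme("HaeIII", "GGCC", 2L, "insensitive"),
    TaqI   = rest_enzyme("TaqI",   "TCGA", 1L, "insensitive"),
    PvuII  = rest_enzyme("PvuII",  "CAGCTG", 3L, "insensitive"),
    MspI   = rest_enzyme("MspI",   "CCGG", 1L, "blocked_by_outer_C"),
    HpaII  = rest_enzyme("HpaII",  "CCGG", 1L, "blocked_by_full_internal_C"))
}

#' Read an enzyme table from TSV
#'
#' Columns: `name`, `recognition`, `cut_offset`, `sensitivity`.
#'
#' @param path Path to the TSV file.
#' @return Named list of [rest_enzyme] objects.
#' @export
read_enzyme_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rest_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i],
                tab$sensitivity[i])
  })
  stats::setNames(out, tab$name)
}

#' Construct a tandem repeat array
#'
#' @param monomers Character vector of monomer sequences (head-to-tail
#'   order), a [sat_records] data frame, or a single sequence.
#' @param methylation_map Optional data frame with columns `position`
#'   (1-based array coordinate) and `strand` (`direct`/`complementary`)
#'   marking methylated cytosines.
#' @param circular Treat the array as circular?
#' @return A list of class `tandem_array` with `monomer_ids`, `sequence`,
#'   `unit` (monomer length of the first monomer), `methylation_map`,
#'   `circular`.
#' @export
tandem_array <- function(monomers, methylation_map = NULL,
                         circular = FALSE) {
  if (is_sat_records(monomers)) {
    ids <- monomers$id
    seqs <- monomers$seq
  } else {
    seqs <- as.character(monomers)
    ids <- names(seqs) %||% paste0("m", seq_along(seqs))
  }
  seqs <- gsub("-", "", toupper(seqs), fixed = TRUE)
  seqc <- paste(seqs, collapse = "")
  if (!is.null(methylation_map)) {
    stopifnot(all(c("position", "strand") %in% names(methylation_map)))
    chars <- seq_chars(seqc)
    need <- ifelse(methylation_map$strand == "direct", "C", "G")
    if (any(chars[methylation_map$position] != need)) {
      stop("methylation_map marks non-cytosine position(s)")
    }
  }
  lens <- nchar(seqs)
  unit <- as.integer(names(which.max(table(lens)))) # modal monomer length
  structure(list(monomer_ids = ids, sequence = seqc,
                 unit = unit,
                 methylation_map = methylation_map, circular = circular),
            class = "tandem_array")
}

#' Find restriction sites on a tandem array
#'
#' Exact matches of the recognition motif on the direct strand plus
#' reverse-complement matches (palindromic motifs counted once); circular
#' arrays are searched across the origin.
#'
#' @param array A [tandem_array].
#' @param enzyme A [rest_enzyme].
#' @return Data frame with `start` (1-based motif start, direct-strand
#'   coordinates, possibly > array length only never — wrapped starts are
#'   reported modulo length) and `cut` (number of array bases preceding the
#'   cut).
#' @export
find_sites <- function(array, enzyme) {
  s <- array$sequence
  L <- nchar(s)
  motif <- enzyme$recognition
  k <- nchar(motif)
  search_str <- if (array$circular && L >= k) {
    paste0(s, substr(s, 1L, k - 1L))
  } else {
    s
  }
  hits <- function(m) {
    # overlapping matches: rescan from each hit + 1
    out <- integer(0)
    from <- 1L
    while (TRUE) {
      h <- regexpr(m, substr(search_str, from, nchar(search_str)),
                   fixed = TRUE)
      if (h == -1L) break
      pos <- from + as.integer(h) - 1L
      out <- c(out, pos)
      from <- pos + 1L
    }
    out
  }
  starts <- hits(motif)
  offsets <- rep(enzyme$cut_offset, length(starts))
  rc <- revcomp(motif)
  if (rc != motif) {
    s2 <- hits(rc)
    starts <- c(starts, s2)
    offsets <- c(offsets, rep(k - enzyme$cut_offset, length(s2)))
  }
  keep <- starts <= L
  starts <- starts[keep]
  offsets <- offsets[keep]
  raw <- starts - 1L + offsets
  if (array$circular) {
    cuts <- ((raw - 1L) %% L) + 1L # wrapped cut boundaries
  } else {
    cuts <- raw
    inside <- cuts >= 1L & cuts <= L - 1L # boundary cuts leave array intact
    starts <- starts[inside]
    cuts <- cuts[inside]
  }
  ord <- order(starts, cuts)
  out <- data.frame(start = starts[ord], cut = cuts[ord])
  out[!duplicated(out), , drop = FALSE]
}

# does the enzyme's sensitivity rule allow cutting at this site?
site_cuttable <- function(array, enzyme, start) {
  map <- array$methylation_map
  if (is.null(map) || nrow(map) == 0L ||
      enzyme$sensitivity == "insensitive") {
    return(TRUE)
  }
  L <- nchar(array$sequence)
  at <- function(offset, strand) {
    p <- ((start - 1L + offset) %% L) + 1L
    any(map$position == p & map$strand == strand)
  }
  # CCGG-type geometry: direct-strand Cs at offsets 0 (outer) and 1
  # (internal); complementary-strand partners at offsets 3 and 2.
  if (enzyme$sensitivity == "blocked_by_outer_C") {
    return(!(at(0L, "direct") || at(3L, "complementary")))
  }
  # blocked_by_full_internal_C
  !(at(1L, "direct") && at(2L, "complementary"))
}

#' In-silico (partial) restriction digestion
#'
#' Every site passing the enzyme's methylation-sensitivity rule is cut
#' independently with probability `partial_probability` (Bernoulli partial
#' digestion model). Fragment lengths between successive realized cuts are
#' returned; an uncut linear array yields one whole-length fragment.
#'
#' @param array A [tandem_array].
#' @param enzyme A [rest_enzyme].
#' @param partial_probability Per-site cut probability in `(0, 1]`.
#' @param seed Seed for the partial-digestion draws (required when
#'   `partial_probability < 1`).
#' @return A list of class `fragment_spectrum`: `lengths` (integer
#'   multiset), `unit` (monomer length), `circular`, `enzyme`, `n_cuts`.
#' @export
digest <- function(array, enzyme, partial_probability = 1, seed = NULL) {
  if (partial_probability <= 0 || partial_probability > 1) {
    stop("partial_probability must be in (0, 1]")
  }
  if (partial_probability < 1 && is.null(seed)) {
    stop("seed required for partial digestion")
  }
  sites <- find_sites(array, enzyme)
  ok <- vapply(sites$start, function(st) site_cuttable(array, enzyme, st),
               logical(1))
  cuts <- sites$cut[ok]
  if (partial_probability < 1 && length(cuts) > 0L) {
    cuts <- withr::with_seed(seed, {
      cuts[stats::runif(length(cuts)) <= partial_probability]
    })
  }
  cuts <- sort(unique(cuts))
  L <- nchar(array$sequence)
  lengths <- if (length(cuts) == 0L) {
    L
  } else if (array$circular) {
    if (length(cuts) == 1L) L else diff(c(cuts, cuts[1L] + L))
  } else {
    diff(c(0L, cuts, L))
  }
  lengths <- as.integer(lengths[lengths > 0L])
  structure(list(lengths = lengths, unit = array$unit,
                 circular = array$circular, enzyme = enzyme$name,
                 n_cuts = length(cuts)),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat("fragment_spectrum (", x$enzyme, "): ", length(x$lengths),
      " fragments, total ", sum(x$lengths), " bp, unit ", x$unit, " bp\n",
      sep = "")
  invisible(x)
}

#' Assign digestion fragments to the multimer ladder
#'
#' Each fragment joins rung `k` of the ladder when its length is within
#' `tolerance` bp of `k * unit`; other fragments are off-ladder.
#'
#' @param spec A `fragment_spectrum`.
#' @param tolerance Length tolerance in bp (default 2).
#' @param unit Monomer unit length; defaults to the spectrum's.
#' @return List of class `ladder_profile`: `ladder` (named counts by
#'   multimer index), `off_ladder_fraction`, `unit`, `tolerance`.
#' @export
ladder_profile <- function(spec, tolerance = 2L, unit = NULL) {
  unit <- unit %||% spec$unit
  if (unit <= 0) stop("unit must be positive")
  k <- pmax(1L, as.integer(round(spec$lengths / unit)))
  on_ladder <- abs(spec$lengths - k * unit) <= tolerance
  tab <- table(k[on_ladder])
  structure(list(ladder = stats::setNames(as.integer(tab), names(tab)),
                 off_ladder_fraction = mean(!on_ladder),
                 unit = unit, tolerance = tolerance),
            class = "ladder_profile")
}

#' @export
print.ladder_profile <- function(x, ...) {
  cat("ladder_profile: unit", x$unit, "bp, tolerance", x$tolerance, "bp\n")
  for (k in names(x$ladder)) {
    cat(sprintf("  %2s-mer : %s\n", k,
                strrep("#", min(60L, x$ladder[[k]]))))
  }
  cat(sprintf("  off-ladder fraction: %.3f\n", x$off_ladder_fraction))
  invisible(x)
}

#' Write a fragment spectrum as a TSV histogram
#'
#' @param spec A `fragment_spectrum`.
#' @param path Output path.
#' @param comment Optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("# enzyme=%s unit=%d total_bp=%d", spec$enzyme,
                     spec$unit, sum(spec$lengths)), con)
  tab <- as.data.frame(table(length = spec$lengths),
                       stringsAsFactors = FALSE)
  names(tab) <- c("length", "count")
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
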