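#' Pairwise differences between two aligned sequences
#'
#' Columns where either sequence carries a gap or `N` are excluded from the
#' comparison (pairwise deletion).
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @return Integer vector `c(mismatches, compared_sites)`.
#' @export
pairwise_differences <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  ok <- ca %in% SAT_BASES & cb %in% SAT_BASES
  c(mismatches = sum(ca[ok] != cb[ok]), compared_sites = sum(ok))
}

# integer-coded alignment: A=1..T=4, gap/N = NA
encode_alignment <- function(aln) {
  m <- matrix(match(aln$mat, SAT_BASES), nrow = nrow(aln$mat))
  rownames(m) <- aln$ids
  m
}

# per-pair, per-column mismatch/valid indicator matrices (pairs x width)
pair_indicators <- function(enc) {
  n <- nrow(enc)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  xi <- enc[pairs[1L, ], , drop = FALSE]
  xj <- enc[pairs[2L, ], , drop = FALSE]
  valid <- !is.na(xi) & !is.na(xj)
  mism <- valid & (xi != xj)
  mism[is.na(mism)] <- FALSE
  list(mism = mism, valid = valid, n_pairs = np)
}

#' Nucleotide diversity (Pi)
#'
#' Average uncorrected p-distance over all unordered sequence pairs, with
#' pairwise deletion of gap/`N` columns (the DnaSP-style estimator; no
#' Jukes-Cantor correction). Pairs with no comparable sites are excluded
#' with a warning.
#'
#' @param aln A `monomer_alignment` with at least 2 records (or a character
#'   vector of equal-length aligned sequences).
#' @return Pi, a fraction in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_alignment(aln)
  if (nrow(aln$mat) < 2L) stop("diversity needs at least 2 records")
  ind <- pair_indicators(encode_alignment(aln))
  m <- rowSums(ind$mism)
  v <- rowSums(ind$valid)
  if (any(v == 0L)) {
    warning(sum(v == 0L), " pair(s) with no comparable sites excluded")
  }
  keep <- v > 0L
  if (!any(keep)) stop("no comparable pairs")
  mean(m[keep] / v[keep])
}

as_alignment <- function(x) {
  if (inherits(x, "monomer_alignment")) return(x)
  if (is_sat_records(x)) return(enforce_alignment(x))
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq_", seq_along(x))
    return(new_monomer_alignment(ids, parse_species(ids), unname(x)))
  }
  stop("cannot interpret input as an alignment")
}

new_window_track <- function(starts, values, window, step, width,
                             stat = "pi") {
  ok <- !is.na(values)
  mu <- if (any(ok)) mean(values[ok]) else NA_real_
  sdv <- if (sum(ok) > 1L) stats::sd(values[ok]) else NA_real_
  structure(list(window = window, step = step, starts = starts,
                 values = values, mean = mu, sd = sdv, width = width,
                 stat = stat),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track (", x$stat, "): ", length(x$starts), " windows of ",
      x$window, " bp, step ", x$step, "; mean ", signif(x$mean, 4),
      ", sd ", signif(x$sd, 4), "\n", sep = "")
  invisible(x)
}

#' Sliding-window nucleotide diversity
#'
#' Pi is recomputed on the columns of each window (pairwise deletion within
#' the window). Windows lie fully inside the alignment; no wraparound.
#'
#' @param aln A `monomer_alignment`.
#' @param window Window width in alignment columns (default 10).
#' @param step Step between window starts (default 1, overlapping).
#' @return A `window_track` with 1-based window `starts`, per-window
#'   `values`, and their `mean` and `sd`.
#' @export
sliding_window_pi <- function(aln, window = 10L, step = 1L) {
  aln <- as_alignment(aln)
  if (window < 2L) stop("window must be at least 2")
  if (window > aln$width) stop("window wider than alignment")
  ind <- pair_indicators(encode_alignment(aln))
  cm <- cbind(0L, t(apply(ind$mism, 1L, cumsum)))
  cv <- cbind(0L, t(apply(ind$valid, 1L, cumsum)))
  starts <- seq(1L, aln$width - window + 1L, by = step)
  values <- vapply(starts, function(s) {
    m <- cm[, s + window] - cm[, s]
    v <- cv[, s + window] - cv[, s]
    keep <- v > 0L
    if (!any(keep)) return(NA_real_)
    mean(m[keep] / v[keep])
  }, numeric(1))
  new_window_track(starts, values, window, step, aln$width, stat = "pi")
}

#' Classify monomer segments as conserved / variable / intermediate
#'
#' A window is `variable` if its value exceeds `mean + multiplier * sd` and
#' `conserved` if it falls below `mean - multiplier * sd` (default
#' multiplier 2, the +/-2SD rule); otherwise `intermediate`. Window labels
#' are projected onto positions (a position takes the extreme label of any
#' covering window; `variable` wins on conflict) and maximal runs are merged
#' into segments that tile `[1, width]`.
#'
#' @param track A `window_track` with at least 3 windows.
#' @param multiplier SD multiplier of the classification rule.
#' @return A data frame of class `segment_classification` with columns
#'   `start`, `end`, `label` (1-based inclusive coordinates).
#' @export
classify_segments <- function(track, multiplier = 2) {
  if (length(track$starts) < 3L) stop("need at least 3 windows")
  width <- track$width %||% (max(track$starts) + track$window - 1L)
  vals <- track$values
  labels <- rep("intermediate", length(vals))
  if (!is.na(track$sd) && track$sd > 0) {
    hi <- track$mean + multiplier * track$sd
    lo <- track$mean - multiplier * track$sd
    labels[!is.na(vals) & vals > hi] <- "variable"
    labels[!is.na(vals) & vals < lo] <- "conserved"
  }
  pos_label <- rep("intermediate", width)
  for (lab in c("conserved", "variable")) { # variable applied last: wins
    for (k in which(labels == lab)) {
      s <- track$starts[k]
      pos_label[s:min(width, s + track$window - 1L)] <- lab
    }
  }
  r <- rle(pos_label)
  ends <- cumsum(r$lengths)
  out <- data.frame(start = ends - r$lengths + 1L, end = ends,
                    label = r$values, stringsAsFactors = FALSE)
  class(out) <- c("segment_classification", "data.frame")
  out
}

#' Export a window track as TSV
#'
#' @param track A `window_track`.
#' @param path Output path.
#' @param comment Optional `#`-prefixed provenance header lines.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("# window=%d step=%d mean=%.6g sd=%.6g",
                     track$window, track$step, track$mean, track$sd), con)
  tab <- data.frame(start = track$starts,
                    end = track$starts + track$window - 1L,
                    value = track$values)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export segments as TSV (1-based) or BED (0-based half-open)
#'
#' @param segments A `segment_classification` data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param chrom Sequence name used in the BED output.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("tsv", "bed"),
                           chrom = "monomer") {
  format <- match.arg(format)
  tab <- if (format == "bed") {
    data.frame(chrom = chrom, start = segments$start - 1L,
               end = segments$end, name = segments$label)
  } else {
    segments
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = format == "tsv")
  invisible(path)
}
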