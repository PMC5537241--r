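# Internal helpers shared across modules.

SAT_BASES <- c("A", "C", "G", "T")
SAT_ALPHABET <- c(SAT_BASES, "N", "-")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of DNA strings
#'
#' Gap (`-`) and `N` characters are preserved.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N,-}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) chars_seq(rev(seq_chars(s))), character(1),
         USE.NAMES = FALSE)
}

# pos in any of the closed intervals given as a 2-column matrix (start, end)?
in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  intervals <- as_interval_matrix(intervals)
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (pos >= intervals[i, 1L] & pos <= intervals[i, 2L])
  }
  out
}

as_interval_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    return(x)
  }
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, function(v) as.integer(v[1:2]))))
  }
  matrix(as.integer(x[1:2]), ncol = 2L)
}

# alignment matrix (n x width) from sequences of equal length
seqs_to_matrix <- function(seqs, ids = NULL) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  mat
}

validate_alphabet <- function(seqs, ids, allow_gap = TRUE) {
  allowed <- if (allow_gap) SAT_ALPHABET else setdiff(SAT_ALPHABET, "-")
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(seq_chars(seqs[i])), allowed)
    if (length(bad) > 0L) {
      stop("record '", ids[i], "' contains invalid characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
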