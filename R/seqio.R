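#' Construct a set of satellite monomer records
#'
#' The basic sequence container of the package: one row per cloned monomer
#' (or bisulfite clone), with a species label parsed from the record id
#' prefix (the part before the first underscore) unless given explicitly.
#'
#' @param id Character vector of unique record identifiers.
#' @param seq Character vector of sequences over `{A,C,G,T,N,-}` (upper case).
#' @param species Optional character vector of species labels; by default
#'   parsed from `id`.
#' @return A data frame of class `sat_records` with columns `id`, `species`,
#'   `seq`.
#' @export
sat_records <- function(id, seq, species = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  if (anyDuplicated(id)) {
    stop("duplicate record IDs: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(nchar(seq) == 0L) && length(seq) > 0L) {
    stop("empty sequence in records: ",
         paste(id[nchar(seq) == 0L], collapse = ", "), call. = FALSE)
  }
  validate_alphabet(seq, id)
  if (is.null(species)) species <- parse_species(id)
  out <- data.frame(id = id, species = as.character(species), seq = seq,
                    stringsAsFactors = FALSE)
  class(out) <- c("sat_records", "data.frame")
  out
}

#' @rdname sat_records
#' @param x Object to test.
#' @export
is_sat_records <- function(x) inherits(x, "sat_records")

parse_species <- function(id) sub("_.*$", "", id)

#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased and `U` is mapped to `T`. Species labels are
#' parsed from the id prefix before the first underscore, or taken from an
#' optional sample sheet.
#'
#' @param path Path to a FASTA file.
#' @param sample_sheet Optional path to a TSV sample sheet with at least
#'   columns `id` and `species` (see [read_sample_sheet()]).
#' @return A [sat_records] data frame (zero rows, with a warning, for an
#'   empty file).
#' @export
read_fasta <- function(path, sample_sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(sat_records(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA (", path, "): line ", nonblank[1L],
         " does not start a record: '", lines[nonblank[1L]], "'",
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  recs <- sat_records(ids, as.character(set))
  if (!is.null(sample_sheet)) {
    sheet <- read_sample_sheet(sample_sheet)
    idx <- match(recs$id, sheet$id)
    recs$species[!is.na(idx)] <- sheet$species[idx[!is.na(idx)]]
  }
  recs
}

#' Write records to a FASTA file
#'
#' @param records A [sat_records] data frame (or anything with `id` and
#'   `seq` columns).
#' @param path Output path.
#' @param line_width Sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with a header; recognised columns are `id`, `species`,
#' `strand` (`direct`/`complementary`) and `fragment_class`
#' (`external`/`internal`).
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(sheet)) stop("sample sheet lacks an 'id' column")
  sheet
}

#' Coerce records into a monomer alignment
#'
#' If all sequences already share one length the records pass through
#' unchanged. Off-length records are pairwise globally aligned (unit gap
#' cost) against a reference — by default the longest record — and the
#' induced gap columns are merged into a common coordinate system. The
#' operation is idempotent.
#'
#' @param records A [sat_records] data frame.
#' @param reference Optional single-row [sat_records] (or list with `id`,
#'   `seq`) used as alignment reference.
#' @param max_length_diff Maximal tolerated relative length difference from
#'   the reference; records beyond it are rejected as non-family members.
#' @return A `monomer_alignment`: list with `ids`, `species`, `mat`
#'   (character matrix, one row per record) and `width`.
#' @export
enforce_alignment <- function(records, reference = NULL,
                              max_length_diff = 0.2) {
  if (nrow(records) == 0L) stop("no records to align")
  lens <- nchar(records$seq)
  if (length(unique(lens)) == 1L) {
    return(new_monomer_alignment(records$id, records$species, records$seq))
  }
  if (is.null(reference)) {
    ref_seq <- records$seq[which.max(lens)]
  } else {
    ref_seq <- if (is.list(reference)) reference$seq else as.character(reference)
  }
  ref_seq <- gsub("-", "", ref_seq, fixed = TRUE)
  rlen <- nchar(ref_seq)
  off <- abs(lens - rlen) / rlen
  if (any(off > max_length_diff)) {
    stop("record(s) differ from reference length by >",
         round(100 * max_length_diff), "%: ",
         paste(records$id[off > max_length_diff], collapse = ", "),
         call. = FALSE)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  # per record: sequence projected onto reference coordinates, plus the
  # read bases inserted after each reference position (slot 0..rlen)
  proj <- vector("list", nrow(records))
  ins <- matrix("", nrow(records), rlen + 1L)
  for (i in seq_len(nrow(records))) {
    s <- gsub("-", "", records$seq[i], fixed = TRUE)
    if (nchar(s) == rlen) { # on-length records pass through unchanged
      proj[[i]] <- seq_chars(s)
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(ref_seq),
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 1,
      type = "global")
    pc <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    sc <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    row <- character(rlen)
    refpos <- 0L
    for (k in seq_along(sc)) {
      if (sc[k] == "-") {
        ins[i, refpos + 1L] <- paste0(ins[i, refpos + 1L], pc[k])
      } else {
        refpos <- refpos + 1L
        row[refpos] <- pc[k]
      }
    }
    proj[[i]] <- row
  }
  max_ins <- apply(nchar(ins), 2L, max)
  out <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    pieces <- character(0)
    for (slot in seq_len(rlen + 1L)) {
      chunk <- ins[i, slot]
      pad <- strrep("-", max_ins[slot] - nchar(chunk))
      pieces <- c(pieces, paste0(chunk, pad),
                  if (slot <= rlen) proj[[i]][slot])
    }
    out[i] <- paste(pieces, collapse = "")
  }
  new_monomer_alignment(records$id, records$species, out)
}

new_monomer_alignment <- function(ids, species, seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  structure(list(ids = ids, species = species,
                 mat = seqs_to_matrix(seqs, ids),
                 width = nchar(seqs[1L])),
            class = "monomer_alignment")
}

#' @export
print.monomer_alignment <- function(x, ...) {
  cat("monomer_alignment:", nrow(x$mat), "records x", x$width, "columns;",
      length(unique(x$species)), "species\n")
  invisible(x)
}

#' Alignment sequences as character vector
#'
#' @param aln A `monomer_alignment`.
#' @param degap Drop gap characters?
#' @return Named character vector of sequences.
#' @export
alignment_seqs <- function(aln, degap = FALSE) {
  s <- apply(aln$mat, 1L, paste, collapse = "")
  if (degap) s <- gsub("-", "", s, fixed = TRUE)
  names(s) <- aln$ids
  s
}

#' Per-column base/gap frequencies of an alignment
#'
#' `N` is excluded from every denominator. Columns of only `N` have all-zero
#' frequencies.
#'
#' @param aln A `monomer_alignment`.
#' @return 5 x width matrix with rows `A,C,G,T,-`; columns sum to 1 (or 0).
#' @export
column_freqs <- function(aln) {
  symbols <- c(SAT_BASES, "-")
  freqs <- matrix(0, length(symbols), aln$width,
                  dimnames = list(symbols, NULL))
  for (j in seq_len(aln$width)) {
    col <- aln$mat[, j]
    col <- col[col != "N"]
    if (length(col) == 0L) next
    tab <- table(factor(col, levels = symbols))
    freqs[, j] <- as.numeric(tab) / length(col)
  }
  freqs
}

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N")

#' Majority-rule consensus of a monomer alignment
#'
#' Per column, if the gap frequency is at least 0.5 the consensus emits `-`;
#' otherwise gaps are dropped from the denominator and the majority base is
#' chosen. Ties are resolved alphabetically (default) or collapsed to the
#' IUPAC code of the tied set.
#'
#' @param aln A `monomer_alignment` with at least 2 records.
#' @param tie_rule `"first_alphabetical"` or `"iupac"`.
#' @return A `consensus_profile`: list with `width`, `freqs` (per-column
#'   frequencies over `A,C,G,T,-`) and `consensus` string.
#' @export
build_consensus <- function(aln,
                            tie_rule = c("first_alphabetical", "iupac")) {
  tie_rule <- match.arg(tie_rule)
  if (nrow(aln$mat) < 2L) stop("consensus needs at least 2 records")
  freqs <- column_freqs(aln)
  cons <- character(aln$width)
  all_gap <- FALSE
  for (j in seq_len(aln$width)) {
    f <- freqs[, j]
    if (sum(f) == 0) { # all-N column
      cons[j] <- "N"
      next
    }
    if (f["-"] >= 0.5) {
      cons[j] <- "-"
      if (f["-"] == 1) all_gap <- TRUE
      next
    }
    base_f <- f[SAT_BASES] / sum(f[SAT_BASES])
    top <- SAT_BASES[base_f == max(base_f)]
    cons[j] <- if (length(top) == 1L || tie_rule == "first_alphabetical") {
      sort(top)[1L]
    } else {
      IUPAC_FROM_SET[paste(sort(top), collapse = "")]
    }
  }
  if (all_gap) warning("alignment contains all-gap column(s)")
  structure(list(width = aln$width, freqs = freqs,
                 consensus = chars_seq(cons)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("consensus_profile:", x$width, "columns\n")
  cat(strwrap(x$consensus, 70), sep = "\n")
  invisible(x)
}

#' G+C content
#'
#' Fraction (G+C)/(A+C+G+T); gaps and `N` are excluded.
#'
#' @param x A [sat_records] data frame, a `monomer_alignment`, or a
#'   character vector of sequences.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  seqs <- if (is_sat_records(x)) x$seq
          else if (inherits(x, "monomer_alignment")) alignment_seqs(x)
          else as.character(x)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  n_base <- sum(chars %in% SAT_BASES)
  if (n_base == 0L) stop("no A/C/G/T bases in input")
  sum(chars %in% c("G", "C")) / n_base
}

#' Write a consensus profile as single-record FASTA and a frequency table
#'
#' @param profile A `consensus_profile`.
#' @param fasta_path,freqs_path Output paths (either may be `NULL` to skip).
#' @param id Record id for the FASTA entry.
#' @return Invisibly, the paths written.
#' @export
write_consensus <- function(profile, fasta_path = NULL, freqs_path = NULL,
                            id = "consensus") {
  if (!is.null(fasta_path)) {
    write_fasta(data.frame(id = id, seq = profile$consensus,
                           stringsAsFactors = FALSE), fasta_path)
  }
  if (!is.null(freqs_path)) {
    tab <- data.frame(position = seq_len(profile$width),
                      t(profile$freqs), check.names = FALSE)
    names(tab) <- c("position", "A", "C", "G", "T", "gap")
    utils::write.table(tab, freqs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta_path, freqs_path))
}
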