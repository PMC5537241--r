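# Shared fixtures and independent oracles, built in code at test time.

# independent brute-force Pi oracle: plain double loop over pairs and columns
oracle_pi <- function(seqs) {
  n <- length(seqs)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      mism <- 0L
      comp <- 0L
      for (k in seq_along(a)) {
        if (a[k] %in% c("A", "C", "G", "T") &&
            b[k] %in% c("A", "C", "G", "T")) {
          comp <- comp + 1L
          if (a[k] != b[k]) mism <- mism + 1L
        }
      }
      if (comp > 0L) vals <- c(vals, mism / comp)
    }
  }
  mean(vals)
}

random_seqs <- function(n, len, gap_prob = 0, seed = NULL) {
  draw <- function() {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (gap_prob > 0) {
      g <- runif(len) < gap_prob
      chars[g] <- "-"
    }
    paste(chars, collapse = "")
  }
  if (!is.null(seed)) set.seed(seed)
  setNames(vapply(seq_len(n), function(i) draw(), character(1)),
           paste0("sp_r", seq_len(n)))
}

toy_alignment <- function(seqs) {
  enforce_alignment(sat_records(paste0("sp_t", seq_along(seqs)), seqs))
}

# window track built directly from values (window 1 => positions = windows)
toy_track <- function(values, window = 1L, width = NULL) {
  starts <- seq_along(values)
  structure(list(window = as.integer(window), step = 1L, starts = starts,
                 values = values, mean = mean(values, na.rm = TRUE),
                 sd = sd(values, na.rm = TRUE),
                 width = width %||% (length(values) + window - 1L),
                 stat = "pi"),
            class = "window_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference with a single variable column, for methylation call arithmetic:
# backbone of A/G/T (no C except planted), length 60
call_fixture <- function(native_col, read_col) {
  set.seed(401)
  backbone <- sample(c("A", "G", "T"), 60, replace = TRUE)
  backbone[31] <- "A" # successor of the planted C => CHH/CHG control
  backbone[32] <- "T"
  make_seq <- function(base30) {
    x <- backbone
    x[30] <- base30
    paste(x, collapse = "")
  }
  native <- sat_records(paste0("nat_m", seq_along(native_col)),
                        vapply(native_col, make_seq, character(1)))
  reads <- bisulfite_reads(paste0("bis_r", seq_along(read_col)),
                           vapply(read_col, make_seq, character(1)),
                           strand = "direct")
  list(native = enforce_alignment(native), reads = reads)
}
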