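test_that("context classification follows the CG/CHG/CHH definitions", {
  expect_equal(classify_context("ACGA", 2), "CG")
  expect_equal(classify_context("CAGT", 1), "CHG")
  expect_equal(classify_context("CATT", 1), "CHH")
  expect_equal(classify_context("ACGA", 1), "non_C")
  expect_equal(classify_context("CANT", 1), "CHH_unresolved")
  expect_equal(classify_context("CN", 1), "CHH_unresolved")
})

test_that("circular context wraps around the monomer end", {
  s <- "GATTC" # last base C, circular successor = first base G -> CG
  expect_equal(classify_context(s, 5, circular = TRUE), "CG")
  expect_equal(classify_context(s, 5, circular = FALSE), "CHH_unresolved")
  # oracle: context on the doubled string at the same offset
  set.seed(17)
  for (rep in 1:20) {
    m <- unname(random_seqs(1, 30))
    doubled <- paste0(m, m)
    for (p in 25:30) {
      expect_equal(classify_context(m, p, circular = TRUE),
                   classify_context(doubled, p, circular = FALSE))
    }
  }
})

test_that("context counts are conserved on circular sequences", {
  set.seed(29)
  for (rep in 1:10) {
    m <- unname(random_seqs(1, 80))
    for (strand in c("direct", "complementary")) {
      ctx <- satmethyl:::context_map(m, strand)
      n_c <- sum(strsplit(if (strand == "direct") m else revcomp(m),
                          "")[[1]] == "C")
      expect_equal(sum(ctx %in% c("CG", "CHG", "CHH")), n_c)
    }
  }
})

test_that("bisulfite alignment maps converted and unconverted reads", {
  set.seed(43)
  cons <- unname(random_seqs(1, 120))
  # unconverted read = consensus
  al <- bisulfite_align(cons, cons, "direct")
  expect_true(al$accepted)
  expect_equal(al$mapping, 1:120)
  # fully converted read: every C -> T still a perfect identity mapping
  conv <- gsub("C", "T", cons)
  al <- bisulfite_align(conv, cons, "direct")
  expect_true(al$accepted)
  expect_equal(al$identity, 1)
  expect_equal(al$mapping, 1:120)
})

test_that("bisulfite alignment skips a deleted coordinate", {
  set.seed(47)
  cons <- unname(random_seqs(1, 120))
  read <- paste0(substr(cons, 1, 59), substr(cons, 61, 120))
  al <- bisulfite_align(gsub("C", "T", read), cons, "direct")
  expect_true(al$accepted)
  mapped <- al$mapping[!is.na(al$mapping)]
  expect_equal(length(mapped), 119L)
  expect_true(all(diff(mapped) > 0))
  expect_length(setdiff(1:120, mapped), 1L) # exactly one skipped coordinate
  expect_equal(mapped[1], 1L)
  expect_equal(mapped[119], 120L)
})

test_that("bisulfite alignment rejects foreign reads and short reads", {
  set.seed(53)
  cons <- unname(random_seqs(1, 120))
  foreign <- unname(random_seqs(1, 120))
  al <- bisulfite_align(foreign, cons, "direct")
  expect_false(al$accepted)
  expect_match(al$reason, "identity")
  al <- bisulfite_align(substr(cons, 1, 40), cons, "direct")
  expect_false(al$accepted)
  expect_match(al$reason, "shorter")
})

test_that("primer-masked read positions are excluded from the mapping", {
  set.seed(59)
  cons <- unname(random_seqs(1, 120))
  al <- bisulfite_align(cons, cons, "direct",
                        primer_mask = rbind(c(1L, 18L)))
  expect_true(al$accepted)
  expect_true(all(is.na(al$mapping[1:18])))
  expect_equal(al$mapping[19:120], 19:120)
})

test_that("normalized methylation matches hand-computed fractions", {
  # native column all C; reads 5 C / 5 T -> m = 0.5 under both denominators
  fx <- call_fixture(rep("C", 5), c(rep("C", 5), rep("T", 5)))
  calls <- call_methylation(fx$native, fx$reads)
  row <- calls[calls$position == 30 & calls$strand == "direct", ]
  expect_equal(row$n_reads, 10L)
  expect_equal(row$m_normalized, 0.5)
  expect_equal(row$context, "CHH") # successors A, T

  # native column 80% C / 20% T; reads 40% C:
  # printed normalization -> 0.40 / 1.00; C-only denominator -> 0.50
  fx <- call_fixture(c("C", "C", "C", "C", "T"),
                     c(rep("C", 4), rep("T", 6)))
  calls_ct <- call_methylation(fx$native, fx$reads, normalization = "ct")
  calls_c <- call_methylation(fx$native, fx$reads, normalization = "c_only")
  expect_equal(calls_ct[calls_ct$position == 30 &
                          calls_ct$strand == "direct", ]$m_normalized, 0.40)
  expect_equal(calls_c[calls_c$position == 30 &
                         calls_c$strand == "direct", ]$m_normalized, 0.50)
})

test_that("m_normalized is invariant under duplicating every read", {
  fx <- call_fixture(rep("C", 4), c("C", "T", "T", "C", "T"))
  doubled <- bisulfite_reads(c(fx$reads$id, paste0(fx$reads$id, "_dup")),
                             rep(fx$reads$seq, 2), "direct")
  a <- call_methylation(fx$native, fx$reads)
  b <- call_methylation(fx$native, doubled)
  expect_equal(b$m_normalized, a$m_normalized)
  expect_equal(b$n_reads, 2L * a$n_reads)
})

test_that("values above one are clamped and flagged", {
  # native column 50% C / 50% T but reads 80% C -> ratio 1.6 -> clamp
  fx <- call_fixture(c("C", "C", "T", "T"),
                     c("C", "C", "C", "C", "T"))
  calls <- call_methylation(fx$native, fx$reads, normalization = "c_only")
  row <- calls[calls$position == 30 & calls$strand == "direct", ]
  expect_equal(row$m_normalized, 1)
  expect_true(row$clamped)
})

test_that("context summary recovers simulated rates within binomial CIs", {
  cfg <- family_config(seed = 71, monomer_length = 150L,
                       n_monomers = c(spA = 25L),
                       planted_motifs = c(CCGG = 30L),
                       conserved_blocks = list(), variable_blocks = list())
  rates <- c(CG = 0.06, CHG = 0.03, CHH = 0.02)
  mcfg <- methylation_config(rates = rates, hot_blocks = list(),
                             conversion_efficiency = 1,
                             n_reads = c(direct = 20L, complementary = 20L),
                             seed = 72)
  ds <- make_dataset(cfg, mcfg, withr::local_tempdir())
  obj <- attr(ds, "objects")
  calls <- call_methylation(obj$family$alignment, obj$reads)
  summ <- summarize_by_context(calls)
  for (ctx in names(rates)) {
    est <- summ$both[summ$site == ctx]
    n_obs <- sum(calls$n_reads[calls$context == ctx &
                                 !is.na(calls$m_normalized)])
    ci <- 1.96 * sqrt(rates[[ctx]] * (1 - rates[[ctx]]) / n_obs)
    expect_lt(abs(est - rates[[ctx]]), ci + 0.005)
  }
  # all-C row is the observation-weighted mean of the context rows
  use <- calls[calls$context %in% c("CG", "CHG", "CHH") &
                 !is.na(calls$m_normalized), ]
  expect_equal(summ$both[summ$site == "all_C"],
               sum(use$n_reads * use$m_normalized) / sum(use$n_reads))
})

test_that("zero-methylation data with perfect conversion summarizes to zero", {
  cfg <- family_config(seed = 81, monomer_length = 120L,
                       n_monomers = c(spA = 10L),
                       planted_motifs = c(CCGG = 30L),
                       conserved_blocks = list(), variable_blocks = list())
  mcfg <- methylation_config(rates = c(CG = 0, CHG = 0, CHH = 0),
                             hot_blocks = list(), conversion_efficiency = 1,
                             n_reads = c(direct = 8L, complementary = 8L),
                             seed = 82)
  ds <- make_dataset(cfg, mcfg, withr::local_tempdir())
  obj <- attr(ds, "objects")
  calls <- call_methylation(obj$family$alignment, obj$reads)
  summ <- summarize_by_context(calls)
  expect_true(all(summ$both[!is.na(summ$both)] == 0))
})

test_that("conversion efficiency estimation matches arithmetic and truth", {
  set.seed(91)
  ref <- unname(random_seqs(1, 120))
  reads <- bisulfite_reads("r1", gsub("C", "T", ref), "direct")
  expect_equal(estimate_conversion_efficiency(reads, ref), 1.0)

  # a read keeping exactly one C unconverted
  chars <- strsplit(ref, "")[[1]]
  cpos <- which(chars == "C")
  conv <- chars
  conv[setdiff(cpos, cpos[1])] <- "T"
  reads <- bisulfite_reads("r2", paste(conv, collapse = ""), "direct")
  expect_equal(estimate_conversion_efficiency(reads, ref),
               (length(cpos) - 1) / length(cpos))

  # simulated control set at efficiency 0.987
  ctrl <- generate_control_reads(ref, n = 40, efficiency = 0.987, seed = 93)
  est <- estimate_conversion_efficiency(ctrl, ref)
  n_obs <- 40 * length(cpos)
  expect_lt(abs(est - 0.987), 1.96 * sqrt(0.987 * 0.013 / n_obs) + 0.002)
})

test_that("methylation window track localizes and thresholds", {
  # single scored position at 100 with m = 0.6: only windows 91-100 nonzero
  calls <- data.frame(position = c(50L, 100L), strand = "direct",
                      context = "CHH", n_reads = 10L,
                      bis_C = c(0, 0.6), native_C = 1, native_CT = 1,
                      m_normalized = c(0, 0.6), clamped = FALSE,
                      stringsAsFactors = FALSE)
  attr(calls, "width") <- 150L
  class(calls) <- c("methylation_calls", "data.frame")
  tr <- sliding_window_methylation(calls, window = 10)
  nonzero <- tr$starts[!is.na(tr$values) & tr$values > 0]
  expect_equal(nonzero, 91:100)
  expect_true(all(is.na(tr$values[tr$starts > 100 | tr$starts + 9 < 50 |
                                    (tr$starts > 50 & tr$starts + 9 < 100)])))
  expect_equal(tr$threshold_hi, tr$mean + 2 * tr$sd)
})

test_that("strand-symmetric CpG simulation mirrors states across strands", {
  cfg <- family_config(seed = 101, monomer_length = 150L,
                       n_monomers = c(spA = 20L),
                       planted_motifs = c(CCGG = 30L),
                       conserved_blocks = list(), variable_blocks = list())
  fam <- generate_family(cfg)
  mcfg <- methylation_config(rates = c(CG = 0.3, CHG = 0, CHH = 0),
                             strand_symmetric = TRUE, hot_blocks = list(),
                             conversion_efficiency = 1,
                             n_reads = c(direct = 25L, complementary = 25L),
                             seed = 102)
  maps <- assign_methylation(fam$records, mcfg)
  # exact mirroring: comp-strand CG state equals its direct partner's
  for (i in seq_len(nrow(fam$records))) {
    ctx_d <- satmethyl:::context_map(fam$records$seq[i], "direct")
    md <- maps[[i]]$position[maps[[i]]$strand == "direct"]
    mc <- maps[[i]]$position[maps[[i]]$strand == "complementary"]
    for (p in which(ctx_d == "CG")) {
      expect_equal(p %in% md, (p + 1L) %in% mc)
    }
  }
  # summaries from the two strand pipelines agree within Monte-Carlo error
  ds <- make_dataset(cfg, mcfg, withr::local_tempdir())
  obj <- attr(ds, "objects")
  calls <- call_methylation(obj$family$alignment, obj$reads)
  summ <- summarize_by_context(calls)
  cg <- summ[summ$site == "CG", ]
  n_d <- sum(calls$n_reads[calls$context == "CG" &
                             calls$strand == "direct"])
  n_c <- sum(calls$n_reads[calls$context == "CG" &
                             calls$strand == "complementary"])
  se <- sqrt(cg$both * (1 - cg$both) * (1 / n_d + 1 / n_c))
  expect_lt(abs(cg$direct - cg$complementary), 3 * se + 0.01)
})

test_that("Spearman correlation handles antitone, identical and tied input", {
  x <- c(1, 2, 3, 4, 5, 6)
  out <- correlate_tracks(x, rev(x))
  expect_equal(out$rho, -1)
  out <- correlate_tracks(x, x)
  expect_equal(out$rho, 1)
  # matches the standard t-approximation implementation
  set.seed(111)
  a <- runif(40)
  b <- a + rnorm(40, sd = 0.4)
  ours <- correlate_tracks(a, b)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  # permutation p agrees in order of magnitude and is seeded-reproducible
  p1 <- correlate_tracks(a, b, method = "permutation", n_perm = 2000,
                         seed = 7)
  p2 <- correlate_tracks(a, b, method = "permutation", n_perm = 2000,
                         seed = 7)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$rho, ours$rho)
  # constant series: undefined correlation reported as NA
  out <- correlate_tracks(rep(1, 10), seq_len(10))
  expect_true(is.na(out$rho))
})
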