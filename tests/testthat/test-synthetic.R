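test_that("zero substitution rate reproduces the ancestral monomer exactly", {
  cfg <- family_config(seed = 301, per_site_substitution_prob = 0,
                       indel_prob = 0, conserved_blocks = list(),
                       variable_blocks = list())
  fam <- generate_family(cfg)
  expect_true(all(fam$records$seq == fam$ancestral$seq))
  expect_equal(nucleotide_diversity(fam$alignment), 0)
})

test_that("generated families satisfy the alignment container invariants", {
  fam <- generate_family(family_config(seed = 311))
  aln <- fam$alignment
  expect_equal(length(unique(apply(aln$mat, 1, length))), 1L)
  expect_gte(nrow(aln$mat), 2L)
  expect_true(all(aln$mat %in% c("A", "C", "G", "T", "-")))
  # realignment of the generated alignment is a no-op
  again <- enforce_alignment(sat_records(aln$ids, alignment_seqs(aln)))
  expect_identical(alignment_seqs(again), alignment_seqs(aln))
})

test_that("ancestral composition and restriction map follow the config", {
  cfg <- family_config(seed = 321)
  fam <- generate_family(cfg)
  expect_lt(abs(gc_content(fam$ancestral$seq) - cfg$gc_target), 0.01)
  arr <- tandem_array(fam$ancestral$seq)
  expect_equal(nrow(find_sites(arr, default_enzymes()$MspI)), 3L)
  expect_equal(nrow(find_sites(arr, default_enzymes()$HaeIII)), 1L)
  expect_equal(nrow(find_sites(arr, default_enzymes()$TaqI)), 1L)
  expect_equal(nrow(find_sites(arr, default_enzymes()$PvuII)), 1L)
})

test_that("methylation assignment hits every CG when the CG rate is one", {
  fam <- generate_family(family_config(seed = 331, monomer_length = 120L,
                                       n_monomers = c(spA = 3L),
                                       planted_motifs = c(CCGG = 30L)))
  mcfg <- methylation_config(rates = c(CG = 1, CHG = 0, CHH = 0),
                             hot_blocks = list(), seed = 332)
  maps <- assign_methylation(fam$records, mcfg)
  for (i in seq_len(3)) {
    s <- fam$records$seq[i]
    ctx <- satmethyl:::context_map(s, "direct")
    want <- which(ctx == "CG")
    got <- sort(maps[[i]]$position[maps[[i]]$strand == "direct"])
    expect_equal(got, want)
  }
  # all-zero rates give empty maps
  mcfg0 <- methylation_config(rates = c(CG = 0, CHG = 0, CHH = 0),
                              hot_blocks = list(), seed = 333)
  maps0 <- assign_methylation(fam$records, mcfg0)
  expect_true(all(vapply(maps0, nrow, integer(1)) == 0L))
})

test_that("assigned context rates match the configuration on many molecules", {
  cfg <- family_config(seed = 341, monomer_length = 150L,
                       n_monomers = c(spA = 400L),
                       planted_motifs = c(CCGG = 30L),
                       conserved_blocks = list(), variable_blocks = list())
  fam <- generate_family(cfg)
  rates <- c(CG = 0.0565, CHG = 0.0179, CHH = 0.0269)
  mcfg <- methylation_config(rates = rates, hot_blocks = list(), seed = 342)
  maps <- assign_methylation(fam$records, mcfg)
  for (ctx in names(rates)) {
    n_sites <- 0L
    n_meth <- 0L
    for (i in seq_len(nrow(fam$records))) {
      for (strand in c("direct", "complementary")) {
        cm <- satmethyl:::context_map(fam$records$seq[i], strand)
        at <- which(cm == ctx)
        n_sites <- n_sites + length(at)
        hit <- maps[[i]]$position[maps[[i]]$strand == strand]
        n_meth <- n_meth + sum(at %in% hit)
      }
    }
    ci <- 1.96 * sqrt(rates[[ctx]] * (1 - rates[[ctx]]) / n_sites)
    expect_lt(abs(n_meth / n_sites - rates[[ctx]]), ci + 0.002)
  }
})

test_that("bisulfite conversion follows the protection and efficiency model", {
  s <- "ACCGTTCAG"
  # efficiency 1, nothing methylated: no C survives
  expect_false(grepl("C", bisulfite_convert(s, NULL, 1, "direct")))
  # efficiency 1, all direct Cs methylated: direct read unchanged
  cpos <- which(strsplit(s, "")[[1]] == "C")
  map <- data.frame(position = cpos, strand = "direct")
  expect_equal(bisulfite_convert(s, map, 1, "direct"), s)
  # complementary read of fully converted molecule has no C either
  rc <- bisulfite_convert(s, NULL, 1, "complementary")
  expect_false(grepl("C", rc))
  expect_equal(nchar(rc), nchar(s))

  # C retention rate ~ 1 - efficiency
  set.seed(351)
  long <- paste(rep("C", 40000), collapse = "")
  conv <- bisulfite_convert(long, NULL, 0.987, "direct")
  retained <- sum(strsplit(conv, "")[[1]] == "C") / 40000
  expect_lt(abs(retained - 0.013), 4 * sqrt(0.013 * 0.987 / 40000))
})

test_that("datasets are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- family_config(seed = 361, monomer_length = 120L,
                       n_monomers = c(spA = 6L),
                       planted_motifs = c(CCGG = 30L))
  mcfg <- methylation_config(n_reads = c(direct = 5L, complementary = 4L),
                             seed = 362)
  p1 <- make_dataset(cfg, mcfg, d1)
  p2 <- make_dataset(cfg, mcfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = paste("file:", k))
  }
})

test_that("truth file carries the generating parameters", {
  d <- withr::local_tempdir()
  cfg <- family_config(seed = 371, monomer_length = 120L,
                       n_monomers = c(spA = 5L),
                       planted_motifs = c(CCGG = 30L))
  mcfg <- methylation_config(n_reads = c(direct = 4L, complementary = 4L),
                             seed = 372)
  paths <- make_dataset(cfg, mcfg, d)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$conversion_efficiency, 0.987)
  expect_equal(truth$rates$CG, 0.0565)
  expect_equal(length(truth$read_sources), 8L)
  sheet <- read_sample_sheet(paths[["sheet"]])
  expect_equal(sort(sheet$id), sort(names(truth$read_sources)))
})

test_that("end-to-end recovery preserves the CG > CHH > CHG ordering", {
  # rate gaps are ~1 point, so this check needs more clones than the
  # study-scale default to separate CHH from CHG at ~3 sigma
  cfg <- family_config(seed = 381)
  mcfg <- methylation_config(seed = 382, hot_blocks = list(),
                             conversion_efficiency = 1,
                             n_reads = c(direct = 80L, complementary = 80L))
  ds <- make_dataset(cfg, mcfg, withr::local_tempdir())
  obj <- attr(ds, "objects")
  calls <- call_methylation(obj$family$alignment, obj$reads)
  summ <- summarize_by_context(calls)
  cg <- summ$both[summ$site == "CG"]
  chh <- summ$both[summ$site == "CHH"]
  chg <- summ$both[summ$site == "CHG"]
  expect_gt(cg, chh)
  expect_gt(chh, chg)
})
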