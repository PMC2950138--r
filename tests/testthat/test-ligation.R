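test_that("promoter coordinates skip position 0 and map correctly", {
  ps <- promoter_sequence("ACGTACGT", start = -4)
  # coords -4 -3 -2 -1 +1 +2 +3 +4
  expect_error(apply_variant(ps, variant(-4, "C", "T")), "mismatch")
  v <- variant(-4, "A", "A")
  expect_equal(apply_variant(ps, v)$seq, ps$seq)  # identity variant
  expect_error(promoter_sequence("ACGT", start = 0))
  expect_error(promoter_sequence("ACXT", start = 1), "bases")
})

test_that("applying the A>TG indel lengthens the allele by one base", {
  ref <- wt_allele()
  alt <- apply_variant(ref, fcgr3b_indel_variant())
  expect_equal(nchar(alt$seq), nchar(ref$seq) + 1L)
  # the junction context CA|AA becomes CTG|AA
  expect_true(grepl("GGTCAAAGAT", ref$seq, fixed = TRUE))
  expect_true(grepl("GGTCTGAAGAT", alt$seq, fixed = TRUE))
  expect_false(grepl("GGTCAAAGAT", alt$seq, fixed = TRUE))

  # pure deletion shortens by the ref length
  del <- apply_variant(ref, variant(-256, "A", ""))
  expect_equal(nchar(del$seq), nchar(ref$seq) - 1L)
})

test_that("every probe ligates on the reference it was designed from", {
  ref <- wt_allele()
  for (w in c(4L, 8L, 10L)) {
    for (p in default_probes(w = w)) {
      expect_true(isTRUE(ligation_success(p, ref)), label = p$probe_id)
    }
  }
})

test_that("the -256A>TG indel silences probe 1 but not probes 2 and 3", {
  mt <- mt_allele()
  for (w in c(4L, 8L, 10L)) {
    pr <- default_probes(w = w)
    r1 <- ligation_success(pr$FCGR3B_1, mt)
    expect_false(isTRUE(r1))
    expect_equal(attr(r1, "reason"), "junction_mismatch")
    expect_true(isTRUE(ligation_success(pr$FCGR3B_2, mt)))
    expect_true(isTRUE(ligation_success(pr$FCGR3B_3, mt)))
  }
})

test_that("junction window decides which variants disrupt ligation", {
  ref <- wt_allele()
  p1 <- default_probes(w = 10L)$FCGR3B_1
  # substitution inside the window (3 bases upstream of the nick) kills it
  inside <- apply_variant(ref, variant(-258, "T", "A", "inside"))
  expect_false(isTRUE(ligation_success(p1, inside)))
  # substitution 15 bases upstream of the nick: outside the w=10 window,
  # hybridization tolerates it and ligation still succeeds
  b <- substr_at(ref, -271)
  swap <- setdiff(c("A", "C", "G", "T"), b)[1]
  outside <- apply_variant(ref, variant(-271, b, swap, "outside"))
  expect_true(isTRUE(ligation_success(p1, outside)))
  # the same swap disrupts a probe run with a wide enough window
  p1_wide <- default_probes(w = 20L)$FCGR3B_1
  expect_false(isTRUE(ligation_success(p1_wide, outside)))
})

test_that("a probe absent from the allele reports no hybridization", {
  decoy <- promoter_sequence(paste(rep("ACGT", 60), collapse = ""), start = -120)
  r <- ligation_success(default_probes()$FCGR3B_1, decoy)
  expect_false(isTRUE(r))
  expect_equal(attr(r, "reason"), "no_hybridization")
})

test_that("expected probe signal counts ligation-competent copies", {
  pr <- default_probes()
  wt <- wt_allele(); mt <- mt_allele()
  expect_equal(expected_probe_signal(list(wt, mt), pr$FCGR3B_1), 1L)
  expect_equal(expected_probe_signal(list(wt, mt), pr$FCGR3B_2), 2L)
  expect_equal(expected_probe_signal(list(), pr$FCGR3B_1), 0L)
  expect_equal(expected_probe_signal(list(wt, wt, mt), pr$FCGR3B_1), 2L)
})

test_that("probe2 minus probe1 equals the mutant copy count (composition)", {
  pr <- default_probes()
  wt <- wt_allele(); mt <- mt_allele()
  set.seed(14)
  for (i in 1:25) {
    n_wt <- sample(0:3, 1); n_mt <- sample(0:3, 1)
    copies <- alleles_for(c(rep("WT", n_wt), rep("MT", n_mt)), wt, mt)
    s1 <- expected_probe_signal(copies, pr$FCGR3B_1)
    s2 <- expected_probe_signal(copies, pr$FCGR3B_2)
    expect_equal(s2, n_wt + n_mt)            # total copies
    expect_equal(s1, n_wt)                   # WT copies only
    expect_equal(s2 - s1, n_mt)              # the genotyper's premise
    expect_lte(s1, length(copies))
  }
})

test_that("FASTA and TSV readers round-trip the reference and probes", {
  ref <- wt_allele()
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ref$seq, ref$id)), fa)
  back <- read_promoter_fasta(fa, start = ref$start)
  expect_equal(back$seq, ref$seq)
  expect_equal(back$start, ref$start)
  # reverse-complement storage resolves to the same target-matching sense
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref$seq)))
  fa2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(p = rc)), fa2)
  back2 <- read_promoter_fasta(fa2, start = ref$start, reverse_complement = TRUE)
  expect_equal(back2$seq, ref$seq)

  tsv <- tempfile(fileext = ".tsv")
  df <- fcgr3b_probe_sequences()
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  probes <- read_probes_tsv(tsv)
  expect_equal(names(probes), df$probe_id)
  expect_equal(probes$FCGR3B_1$junction_pos, -256L)

  vtsv <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(pos = -256, ref = "A", alt = "TG", label = "-256A>TG"),
    vtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  vs <- read_variants_tsv(vtsv)
  expect_equal(vs[[1]]$alt, "TG")
})
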