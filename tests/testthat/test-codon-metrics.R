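test_that("count_codons counts non-overlapping triplets", {
  ct <- count_codons("ATGAAATAA")
  expect_equal(ct[["ATG"]], 1L)
  expect_equal(ct[["AAA"]], 1L)
  expect_equal(ct[["TAA"]], 1L)
  expect_equal(sum(ct), 3L)
  expect_equal(attr(ct, "total_codons"), 3L)

  ct2 <- count_codons("ATGCTGCTGCTTTAA")
  expect_equal(unname(ct2[c("ATG", "CTG", "CTT", "TAA")]), c(1L, 2L, 1L, 1L))
  expect_equal(sum(ct2), 5L)
})

test_that("RSCU matches its definition on worked examples", {
  # one occurrence of every sense codon: every family balanced -> all 1
  seq_all <- paste0("ATG", paste(setdiff(ORACLE_SENSE, "ATG"), collapse = ""),
                    "TAA")
  r <- compute_rscu(count_codons(seq_all))
  expect_true(all(abs(r - 1) < 1e-12))
  expect_setequal(attr(r, "present_aa"), setdiff(unique(
    vapply(ORACLE_RSCU59, oracle_aa, character(1))), character(0)))

  # Leu family with CTG=2, CTT=1 only: mean count 0.5 -> 4.0 and 2.0
  r2 <- compute_rscu(count_codons("ATGCTGCTGCTTTAA"))
  expect_equal(r2[["CTG"]], 4)
  expect_equal(r2[["CTT"]], 2)
  expect_equal(unname(r2[c("TTA", "TTG", "CTC", "CTA")]), rep(0, 4))
  # absent families are all-zero and not listed as present
  expect_false("K" %in% attr(r2, "present_aa"))
  expect_true(all(r2[c("AAA", "AAG")] == 0))
})

test_that("RSCU family sums equal family size and scaling is irrelevant", {
  set.seed(101)
  fam_of <- vapply(ORACLE_RSCU59, oracle_aa, character(1))
  for (i in 1:20) {
    s <- random_cds(sample(30:120, 1))
    ct <- count_codons(s)
    r <- compute_rscu(ct)
    for (aa in attr(r, "present_aa")) {
      fam <- ORACLE_RSCU59[fam_of == aa]
      expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
    }
    # multiplying all counts by k leaves RSCU unchanged
    k <- sample(2:7, 1)
    expect_equal(as.numeric(compute_rscu(ct * k)), as.numeric(r),
                 tolerance = 1e-12)
  }
})

test_that("average_rscu is an element-wise (optionally weighted) mean", {
  set.seed(7)
  v1 <- compute_rscu(count_codons(random_cds(60)))
  v2 <- compute_rscu(count_codons(random_cds(60)))
  expect_equal(as.numeric(average_rscu(list(v1, v1, v1))), as.numeric(v1))
  expect_equal(as.numeric(average_rscu(list(v1, v2))),
               as.numeric((v1 + v2) / 2))
  # mean of k copies of v plus w: (k v + w) / (k + 1), against a brute mean
  k <- 4
  vecs <- c(rep(list(v1), k), list(v2))
  brute <- Reduce(`+`, lapply(vecs, as.numeric)) / length(vecs)
  expect_equal(as.numeric(average_rscu(vecs)), brute, tolerance = 1e-12)
  # codon-count weighting
  expect_equal(as.numeric(average_rscu(list(v1, v2), weights = c(3, 1))),
               as.numeric((3 * v1 + v2) / 4))
  expect_error(average_rscu(list()), "no RSCU")
})

test_that("CAI is the geometric mean of relative adaptiveness", {
  # reference preferring every family's first codon equally
  freq <- stats::setNames(rep(1, length(ORACLE_SENSE)), ORACLE_SENSE)
  ref <- reference_usage(freq)
  expect_true(all(ref$w == 1))
  # all weights 1 -> CAI exactly 1
  expect_equal(compute_cai(count_codons("ATGAAAGGGTAA"), ref), 1)

  # single scoreable codon with w = 0.5 -> CAI 0.5
  freq2 <- freq
  freq2[["AAA"]] <- 0.5  # AAG stays 1 -> w(AAA) = 0.5
  ref2 <- reference_usage(freq2)
  expect_equal(compute_cai(count_codons("ATGAAATAA"), ref2), 0.5)

  # w-sequence (1.0, 0.25): exp(mean(log)) = 0.5
  freq3 <- freq
  freq3[["GGG"]] <- 0.25
  ref3 <- reference_usage(freq3)
  expect_equal(compute_cai(count_codons("ATGAAAGGGTAA"), ref3), 0.5)

  # zero reference frequency errors unless a pseudo-frequency is enabled
  freq4 <- freq
  freq4[["AAA"]] <- 0
  expect_error(compute_cai(count_codons("ATGAAATAA"),
                           reference_usage(freq4)), "pseudo")
  ref5 <- reference_usage(freq4, pseudo_frequency = 0.01)
  expect_equal(compute_cai(count_codons("ATGAAATAA"), ref5), 0.01)
})

test_that("GC3 is the third-base G/C percentage over non-stop codons", {
  expect_equal(compute_gc3(count_codons("ATGGGGGGCTAA")), 100)
  # codon multiset {GGG, AAA}: drop the start codon from the counts
  ct <- count_codons("ATGGGGAAATAA")
  ct[["ATG"]] <- 0L
  expect_equal(compute_gc3(ct), 50)
  # ATG's third base G counts; the stop codon does not
  expect_equal(compute_gc3(count_codons("ATGAAATAA")), 50)
})

test_that("CCCS is the length-normalised CP sum with required coverage", {
  cp0 <- stats::setNames(rep(0, length(ORACLE_SENSE)), ORACLE_SENSE)
  s <- random_cds(40)
  expect_equal(compute_cccs(count_codons(s), cp0), 0)
  # constant cp c gives exactly c whatever the sequence
  expect_equal(compute_cccs(count_codons(s), cp0 + 0.37), 0.37)
  # hand example: sense codons ATG, AAA, GGG with cp 0, 0.2, -0.1
  cp <- cp0
  cp[c("AAA", "GGG")] <- c(0.2, -0.1)
  expect_equal(compute_cccs(count_codons("ATGAAAGGGTAA"), cp),
               (0 + 0.2 - 0.1) / 3)
  # linearity in the CP table
  set.seed(12)
  cp1 <- stats::setNames(rnorm(length(ORACLE_SENSE)), ORACLE_SENSE)
  cp2 <- stats::setNames(rnorm(length(ORACLE_SENSE)), ORACLE_SENSE)
  ct <- count_codons(s)
  expect_equal(compute_cccs(ct, cp1 + cp2),
               compute_cccs(ct, cp1) + compute_cccs(ct, cp2),
               tolerance = 1e-12)
  # nucleotide-length normalisation switch (denominator includes the stop)
  expect_equal(compute_cccs(count_codons("ATGAAAGGGTAA"), cp, "nt"),
               0.1 / 12)
  used <- names(which(ct[ORACLE_SENSE] > 0))
  expect_error(compute_cccs(ct, cp1[setdiff(names(cp1), used[1])]),
               "missing from the CP")
})

test_that("metric file readers round-trip", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(codon = c("AAA", "AAG"), frequency = c(10, 30)), tsv)
  ref <- read_reference_usage(tsv)
  expect_equal(ref$w[["AAA"]], 1 / 3)
  expect_equal(ref$w[["AAG"]], 1)
  cptsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(codon = c("AAA", "GGG"), cp_value = c(0.2, -0.1)),
            cptsv)
  expect_equal(read_cp_table(cptsv),
               c(AAA = 0.2, GGG = -0.1))
})

test_that("metrics agree with brute-force oracles on random genes", {
  set.seed(2024)
  freq <- stats::setNames(stats::runif(length(ORACLE_SENSE), 0.5, 40),
                          ORACLE_SENSE)
  ref <- reference_usage(freq)
  cp <- stats::setNames(stats::rnorm(length(ORACLE_SENSE)), ORACLE_SENSE)
  for (i in 1:30) {
    s <- random_cds(sample(20:80, 1))
    ct <- count_codons(s)
    expect_equal(as.numeric(compute_rscu(ct)[ORACLE_RSCU59]),
                 as.numeric(oracle_rscu(s)), tolerance = 1e-9)
    expect_equal(compute_cai(ct, ref), oracle_cai(s, ref$w),
                 tolerance = 1e-9)
    expect_equal(compute_gc3(ct), oracle_gc3(s), tolerance = 1e-9)
    expect_equal(compute_cccs(ct, cp), oracle_cccs(s, cp),
                 tolerance = 1e-9)
  }
})

test_that("metrics_table assembles per-entity rows in fixed codon order", {
  cds <- data.frame(entity_id = c("G1", "G2"),
                    sequence = c("ATGAAATAA", "ATGCTGCTGCTTTAA"),
                    n_codons = c(3L, 5L), stringsAsFactors = FALSE)
  freq <- stats::setNames(rep(1, length(ORACLE_SENSE)), ORACLE_SENSE)
  cp <- stats::setNames(rep(0.5, length(ORACLE_SENSE)), ORACLE_SENSE)
  tab <- metrics_table(cds, reference_usage(freq), cp)
  expect_equal(tab$entity_id, c("G1", "G2"))
  expect_equal(tab$cai, c(1, 1))
  expect_equal(tab$cccs, c(0.5, 0.5))
  expect_equal(names(tab)[6:ncol(tab)], ORACLE_RSCU59)
  expect_equal(tab$CTG, c(0, 4))
})
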