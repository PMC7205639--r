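test_that("profiles are family-normalised and hit their GC3 target", {
  p <- codon_profile("p", gc3_target = 0.7, purine3_target = 0.4)
  fams <- split(ORACLE_SENSE,
                vapply(ORACLE_SENSE, oracle_aa, character(1)))
  for (fam in fams) {
    expect_equal(sum(p$probs[fam]), 1, tolerance = 1e-12)
  }
  # expected third-base G+C equals the target exactly for families whose
  # third bases pair G/A and C/T evenly (all 2-, 4- and 6-fold families);
  # the 3-codon Ile family deviates mildly through renormalisation
  for (fam in fams[lengths(fams) %in% c(2L, 4L, 6L)]) {
    gc <- substring(fam, 3, 3) %in% c("G", "C")
    expect_equal(sum(p$probs[fam][gc]), 0.7, tolerance = 1e-9)
  }
  ile <- fams[[which(vapply(fams, function(f) oracle_aa(f[1]) == "I",
                            logical(1)))]]
  expect_lt(abs(sum(p$probs[ile][substring(ile, 3, 3) %in% c("G", "C")]) -
                  0.7), 0.15)
})

test_that("gene sets are seed-reproducible complete ORFs", {
  prof <- codon_profile("p", 0.5)
  g1 <- synthesize_gene_set(prof, 10L, seed = 42L)
  g2 <- synthesize_gene_set(prof, 10L, seed = 42L)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth, g2$truth)
  g3 <- synthesize_gene_set(prof, 10L, seed = 43L)
  expect_false(identical(g1$sequences, g3$sequences))
  expect_true(all(vapply(g1$sequences, validate_orf, character(1)) ==
                    "complete"))
})

test_that("realised GC3 tracks the profile target", {
  lo <- synthesize_gene_set(codon_profile("lo", 0.1), 30L,
                            length_meanlog = log(300), length_sdlog = 0,
                            seed = 5L)
  hi <- synthesize_gene_set(codon_profile("hi", 0.9), 30L,
                            length_meanlog = log(300), length_sdlog = 0,
                            seed = 5L)
  expect_gte(mean(hi$truth$gc3) - mean(lo$truth$gc3), 60)
  # invariant: realised mean within +-5 points of the target at L >= 300
  expect_lt(abs(mean(lo$truth$gc3) - 10), 5)
  expect_lt(abs(mean(hi$truth$gc3) - 90), 5)
})

test_that("a degenerate profile forces RSCU to the family size", {
  # all mass on each family's first codon
  fam_of <- vapply(ORACLE_RSCU59, oracle_aa, character(1))
  first <- vapply(split(ORACLE_RSCU59, fam_of), `[[`, character(1), 1L)
  w <- stats::setNames(rep(1e-9, length(ORACLE_SENSE)), ORACLE_SENSE)
  w[first] <- 1e9
  prof <- codon_profile("degen", 0.5, codon_weights = w)
  g <- synthesize_gene_set(prof, 3L, length_meanlog = log(200),
                           length_sdlog = 0, seed = 9L)
  r <- compute_rscu(count_codons(g$sequences[[1]]))
  for (aa in attr(r, "present_aa")) {
    fam <- ORACLE_RSCU59[fam_of == aa]
    expect_equal(r[[first[[aa]]]], length(fam))
    expect_true(all(r[setdiff(fam, first[[aa]])] == 0))
  }
})

test_that("virus panels cluster by subgroup and respect jitter limits", {
  prof <- codon_profile("v", 0.3)
  sg <- list(list(subgroup_id = "1", group = "+ssRNA", n_species = 3L,
                  profile = prof, cds_range = c(2L, 3L)))
  panel <- synthesize_virus_panel(sg, seed = 8L)
  expect_equal(nrow(panel$truth), 3L)
  expect_true(all(vapply(panel$sequences, validate_orf, character(1)) ==
                    "complete"))
  expect_equal(length(panel$catalog_config$species), 3L)
  # infinite concentration = no jitter at all
  pj <- jitter_profile(prof, concentration = Inf)
  expect_equal(pj$probs, prof$probs)
  # tighter concentration stays closer to the parent profile
  set.seed(10)
  spread <- function(conc) {
    max(abs(jitter_profile(prof, concentration = conc)$probs - prof$probs))
  }
  expect_lt(median(replicate(20, spread(5000))),
            median(replicate(20, spread(20))))
})

test_that("the synthetic CP table signs CCCS by generating profile", {
  opt <- codon_profile("opt", 0.85)
  ccr <- codon_profile("ccr", 0.30)
  cp <- synthesize_cp_table(opt, ccr)
  expect_true(all(cp >= -3 & cp <= 3))
  # identical profiles give cp == 0, hence CCCS == 0 everywhere
  cp0 <- synthesize_cp_table(opt, opt)
  expect_true(all(cp0 == 0))
  # clipping: an extreme family ratio saturates at the bound
  w <- stats::setNames(rep(1, length(ORACLE_SENSE)), ORACLE_SENSE)
  w[["AAA"]] <- 1000
  skew <- codon_profile("skew", 0.5, codon_weights = w)
  flat <- codon_profile("flat", 0.5)
  # AAG's probability collapses under the skew: log2 ratio far below -3
  expect_equal(synthesize_cp_table(flat, skew)[["AAG"]], -3)

  # genes from the ccr profile score positive, from the optimal negative
  g_ccr <- synthesize_gene_set(ccr, 50L, length_meanlog = log(300),
                               length_sdlog = 0, seed = 77L)
  g_opt <- synthesize_gene_set(opt, 50L, length_meanlog = log(300),
                               length_sdlog = 0, seed = 78L)
  cccs_of <- function(g) vapply(g$sequences, function(s)
    compute_cccs(count_codons(s), cp), numeric(1))
  expect_gt(mean(cccs_of(g_ccr)), 0)
  expect_lt(mean(cccs_of(g_opt)), 0)
})

test_that("planted annotations are recoverable exactly when planted", {
  truth <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      profile_id = rep(c("viral_like", "other"),
                                       each = 500),
                      stringsAsFactors = FALSE)
  viral <- truth$gene_id[truth$profile_id == "viral_like"]
  set.seed(300)
  p_planted <- function(factor) {
    ann <- synthesize_annotations(truth, "viral_like", factor = factor,
                                  q = 0.05, n_decoy = 5L)
    res <- enrich_terms(viral, ann, alpha = 0.01)
    res$p_adj[res$term_id == "TERM_planted"]
  }
  # factor 10: planted term significant in >= 90% of replicates
  sig <- replicate(50, p_planted(10) <= 0.01)
  expect_gte(mean(sig), 0.9)
  # factor 1: no signal, non-significant in >= 90% of replicates
  null_sig <- replicate(50, {
    p <- p_planted(1)
    length(p) == 1 && p <= 0.01
  })
  expect_gte(mean(!null_sig), 0.9)
  # q = 0 with factor 1: empty map
  ann0 <- synthesize_annotations(truth, "viral_like", factor = 1, q = 0,
                                 n_decoy = 0L)
  expect_equal(nrow(ann0$pairs), 0L)
})
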