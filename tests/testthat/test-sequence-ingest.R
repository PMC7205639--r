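test_that("parse_cds_fasta reads, normalises and ids records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">T1|GENEA some note", "ATGAAATAA",
               ">T2|GENEA", "atgaaauaa",
               ">T3|GENEB", "ATGCCC", "TGA"), fa)
  out <- parse_cds_fasta(fa, "host")
  expect_equal(out$record_id, c("T1|GENEA", "T2|GENEA", "T3|GENEB"))
  expect_equal(out$entity_id, c("GENEA", "GENEA", "GENEB"))
  # case and U/T normalisation; multi-line bodies joined
  expect_equal(out$sequence, c("ATGAAATAA", "ATGAAATAA", "ATGCCCTGA"))

  virus <- parse_cds_fasta(fa, "virus",
                           species_map = c("T1|GENEA" = "SP1",
                                           "T2|GENEA" = "SP1"))
  expect_equal(virus$entity_id, c("SP1", "SP1", "T3|GENEB"))
})

test_that("parse_cds_fasta rejects empty and malformed files", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(parse_cds_fasta(empty, "host"), "empty|malformed")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ATGAAATAA", "not a fasta"), bad)
  expect_error(parse_cds_fasta(bad, "host"), "malformed")
  expect_error(parse_cds_fasta(tempfile(), "host"), "not found")
})

test_that("validate_orf applies verdicts in fixed order", {
  expect_equal(validate_orf("ATGAAATAA"), "complete")
  expect_equal(validate_orf("ATGAANTAA"), "ambiguous_base")
  expect_equal(validate_orf("ATGTAAAAATAA"), "internal_stop")
  expect_equal(validate_orf("ATGAATAA"), "bad_length")
  expect_equal(validate_orf("TTGAAATAA"), "no_start")
  expect_equal(validate_orf("ATGAAAAAA"), "no_terminal_stop")
  # precedence: ambiguity trumps length, length trumps start
  expect_equal(validate_orf("ATGNA"), "ambiguous_base")
  expect_equal(validate_orf("TTGAA"), "bad_length")
  # a bare stop after ATG is a complete (if trivial) ORF
  expect_equal(validate_orf("ATGTGA"), "complete")
})

test_that("select_major_variants keeps the longest complete variant", {
  entries <- data.frame(
    record_id = c("T1", "T2", "T3", "T4", "T5"),
    entity_id = c("G1", "G1", "G2", "G2", "G3"),
    sequence = c("ATGAAATAA",                # G1: complete, 9 nt
                 "ATGAAACCCTAA",             # G1: complete, 12 nt -> wins
                 "ATGTAACCCAAATAA",          # G2: internal stop, longer
                 "ATGAAATAA",                # G2: complete, shorter -> wins
                 "ATGAAC"),                  # G3: no stop -> omitted
    stringsAsFactors = FALSE)
  expect_message(out <- select_major_variants(entries), "omitted")
  expect_equal(out$entity_id, c("G1", "G2"))
  expect_equal(out$record_id, c("T2", "T4"))
  expect_equal(out$n_codons, c(4L, 3L))
  expect_equal(attr(out, "omitted_entities"), "G3")
})

test_that("equal-length ties break on smallest record id", {
  entries <- data.frame(record_id = c("T2", "T1"),
                        entity_id = c("G1", "G1"),
                        sequence = c("ATGAAATAA", "ATGCCCTAA"),
                        stringsAsFactors = FALSE)
  expect_equal(select_major_variants(entries)$record_id, "T1")
})

test_that("variant selection is order-independent and idempotent", {
  set.seed(31)
  entries <- do.call(rbind, lapply(1:12, function(i) {
    k <- sample(1:3, 1)
    data.frame(record_id = sprintf("T%02d_%d", i, seq_len(k)),
               entity_id = sprintf("G%02d", i),
               sequence = vapply(seq_len(k), function(j)
                 random_cds(sample(3:8, 1)), character(1)),
               stringsAsFactors = FALSE)
  }))
  base <- select_major_variants(entries)
  for (r in 1:5) {
    perm <- entries[sample(nrow(entries)), ]
    out <- select_major_variants(perm)
    expect_equal(out$entity_id, base$entity_id)
    expect_equal(out$record_id, base$record_id)
    expect_equal(out$sequence, base$sequence)
  }
  # idempotent: selecting from the selection changes nothing
  again <- select_major_variants(
    base[, c("record_id", "entity_id", "sequence")])
  expect_equal(again$record_id, base$record_id)
  # conservation: one output row per entity with >= 1 complete variant
  status <- vapply(entries$sequence, validate_orf, character(1))
  expect_equal(nrow(base),
               length(unique(entries$entity_id[status == "complete"])))
  # every selected sequence re-validates complete
  expect_true(all(vapply(base$sequence, validate_orf, character(1)) ==
                    "complete"))
})

test_that("virus catalog round-trips metadata and drops bad CDS", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">R1", "ATGAAATAA",
               ">R2", "ATGCCCTAA",
               ">R3", "ATGTAAAAATAA",   # internal stop -> dropped
               ">R4", "ATGGGGTAA"), fa)
  cfgfile <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(species = list(
    list(species_id = "SPA", group = "+ssRNA", subgroup_id = "2",
         records = c("R1", "R2")),
    list(species_id = "SPB", group = "Retro", subgroup_id = "1",
         records = c("R3", "R4")))), cfgfile)
  cat <- suppressMessages(load_virus_catalog(cfgfile, fa))
  expect_equal(cat$species$group, c("+ssRNA", "Retro"))
  expect_equal(cat$species$subgroup_id, c("2", "1"))
  expect_equal(cat$species$n_cds, c(2L, 1L))
  expect_equal(cat$species$n_dropped, c(0L, 1L))
  expect_equal(nrow(cat$cds), 3L)

  # a species whose only CDS fails validation is an error naming it
  bad <- list(species = list(
    list(species_id = "SPC", group = "dsRNA", subgroup_id = "1",
         records = "R3")))
  expect_error(suppressMessages(load_virus_catalog(bad, fa)), "SPC")
  # unknown record ids -> no records -> error
  none <- list(species = list(
    list(species_id = "SPD", group = "Ambi", subgroup_id = "1",
         records = "Rxx")))
  expect_error(suppressMessages(load_virus_catalog(none, fa)), "SPD")
})
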