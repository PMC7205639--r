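#!/usr/bin/env Rscript
# Step 5 — term overrepresentation and gradient regressions.
#
# Hypergeometric enrichment of each subgroup's selected genes against the
# whole synthetic genome (Bonferroni, p_adj <= 0.01), and the simple
# linear fits of CAI and GC3 against the two components.

suppressPackageStartupMessages(library(codonscape))

metrics <- utils::read.delim("results/tables/metrics.tsv",
                             check.names = FALSE)
points <- utils::read.delim("results/tables/scores.tsv")
host_pts <- points[points$kind == "host_gene", ]
ann <- read_annotation_map("results/synthetic/annotations.tsv",
                           background = metrics$entity_id)

sel_files <- list.files("results/tables", "^selection_.*\\.tsv$",
                        full.names = TRUE)
sel_files <- grep("summary|recovery", sel_files, invert = TRUE,
                  value = TRUE)
for (f in sel_files) {
  tab <- utils::read.delim(f)
  sel <- tab$gene_id[tab$selected]
  key <- sub("^selection_(.*)\\.tsv$", "\\1", basename(f))
  if (length(sel) == 0) { cat(key, ": nothing selected\n"); next }
  res <- enrich_terms(sel, ann, alpha = 0.01)
  write_tsv(res, sprintf("results/tables/enrichment_%s.tsv", key))
  top <- res[res$significant, ]
  cat(sprintf("%s: %d genes, %d significant term(s)", key, length(sel),
              nrow(top)))
  if (nrow(top) > 0) {
    cat(": ", paste(sprintf("%s (-log10 p = %.1f)", top$term_id,
                            -log10(pmax(top$p_adj, 1e-300))),
                    collapse = ", "))
  }
  cat("\n")
}

# gradient regressions over host genes
idx <- match(host_pts$entity_id, metrics$entity_id)
rows <- list()
for (resp in c("cai", "gc3")) {
  for (pred in c("pc1", "pc2")) {
    f <- fit_linear(host_pts[[pred]], metrics[[resp]][idx])
    rows[[paste(resp, pred)]] <- data.frame(
      response = resp, predictor = pred, slope = f$slope,
      intercept = f$intercept, r_squared = f$r_squared, pcc = f$pcc,
      p_value = f$p_value, n = f$n)
  }
}
reg <- do.call(rbind, rows)
rownames(reg) <- NULL
write_tsv(reg, "results/tables/regressions.tsv")
print(reg, digits = 4)
cat("\nDone. All step outputs are under results/tables/.\n")
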