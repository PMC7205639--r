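#!/usr/bin/env Rscript
# Step 2 — ingest the coding sequences and compute per-gene codon metrics.
#
# Selects one major transcript variant per host gene (longest complete
# ORF), validates every virus CDS, and writes per-entity RSCU vectors plus
# CAI, GC3 and CCCS to results/tables/.

suppressPackageStartupMessages(library(codonscape))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

entries <- parse_cds_fasta("results/synthetic/host_cds.fasta", "host")
variants <- select_major_variants(entries)
write_variant_table(variants, "results/tables/selected_variants.tsv")
cat("host records:", nrow(entries), "-> genes:", nrow(variants), "\n")

catalog <- load_virus_catalog("results/synthetic/virus_catalog.yml",
                              "results/synthetic/virus_cds.fasta")
cat("virus species:", nrow(catalog$species),
    "CDS kept:", nrow(catalog$cds), "\n")

ref <- read_reference_usage("results/synthetic/reference_usage.tsv")
cp <- read_cp_table("results/synthetic/cp_table.tsv")

metrics <- metrics_table(variants, ref, cp)
write_tsv(metrics, "results/tables/metrics.tsv")

# virus species RSCU (mean over CDS) in the same 59-codon column order
virus_vecs <- virus_species_rscu(catalog)
vm <- do.call(rbind, lapply(virus_vecs, function(v) as.data.frame(t(v))))
vm <- cbind(data.frame(species_id = names(virus_vecs)), vm)
write_tsv(vm, "results/tables/virus_rscu.tsv")
write_tsv(catalog$species, "results/tables/virus_species.tsv")

cat(sprintf("host CAI range %.3f-%.3f; GC3 range %.1f-%.1f\n",
            min(metrics$cai), max(metrics$cai),
            min(metrics$gc3), max(metrics$gc3)))
truth <- utils::read.delim("results/synthetic/host_truth.tsv")
cccs_by <- tapply(metrics$cccs[match(truth$gene_id, metrics$entity_id)],
                  truth$profile_id, mean)
cat("mean CCCS by generating profile:\n"); print(round(cccs_by, 3))
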