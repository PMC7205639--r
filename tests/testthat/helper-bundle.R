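# a scaled-down configuration for fast pipeline-level tests

small_synthetic_config <- function(seed = 11L) {
  cfg <- default_synthetic_config(seed)
  cfg$host$n_genes <- c(30L, 80L, 40L)
  cfg$host$length_meanlog <- log(200)
  cfg$viruses$subgroups <- lapply(cfg$viruses$subgroups[1:2], function(sg) {
    sg$n_species <- 2L
    sg$cds_range <- c(2L, 3L)
    sg$cds_meanlog <- log(300)
    sg
  })
  cfg$annotations$n_decoy <- 5L
  cfg
}

write_small_bundle <- function(dir, seed = 11L) {
  synthetic_bundle(small_synthetic_config(seed), dir = dir)
}

bundle_pipeline_config <- function(b, out_dir, ...) {
  pipeline_config(host_fasta = b$paths[["host_fasta"]],
                  virus_catalog = b$paths[["virus_catalog"]],
                  virus_fasta = b$paths[["virus_fasta"]],
                  reference_usage = b$paths[["reference_usage"]],
                  cp_table = b$paths[["cp_table"]],
                  annotations = b$paths[["annotations"]],
                  out_dir = out_dir, ...)
}
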