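# Orchestration of the full analysis: ingest -> metrics -> ordination ->
# centroid/disk selection per virus subgroup -> enrichment -> regression
# summaries, with deterministic TSV outputs and a run manifest.

#' Build and validate a pipeline configuration
#'
#' @param host_fasta host CDS multi-FASTA path.
#' @param virus_catalog virus catalog YAML path (see
#'   [load_virus_catalog()]).
#' @param virus_fasta character vector of virus CDS FASTA paths.
#' @param reference_usage reference codon-usage TSV path (codon,
#'   frequency); optional, CAI is skipped without it.
#' @param cp_table codon-preference TSV path (codon, cp_value); optional,
#'   CCCS is skipped without it.
#' @param annotations annotation TSV path (gene_id, term_id); optional,
#'   enrichment is skipped without it.
#' @param out_dir output directory (created if missing).
#' @param radius disk selection radius in component units (default 0.3).
#' @param alpha enrichment significance threshold on corrected p-values
#'   (default 0.01).
#' @param correction multiple-testing correction, `"bonferroni"` or
#'   `"BH"`.
#' @param fit_universe `"all"`: host genes and virus species are rows of
#'   the fitted matrix; `"host_only"`: the components are fitted on host
#'   genes and viruses are projected post hoc.
#' @param host_id_field,host_id_delim host header token layout (see
#'   [parse_cds_fasta()]).
#' @param pseudo_frequency optional pseudo-frequency for zero-frequency
#'   reference codons.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(host_fasta, virus_catalog, virus_fasta,
                            out_dir,
                            reference_usage = NULL, cp_table = NULL,
                            annotations = NULL,
                            radius = 0.3, alpha = 0.01,
                            correction = c("bonferroni", "BH"),
                            fit_universe = c("all", "host_only"),
                            host_id_field = 2L, host_id_delim = "|",
                            pseudo_frequency = NULL) {
  correction <- match.arg(correction)
  fit_universe <- match.arg(fit_universe)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("radius must be a single positive number", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1)
  for (p in c(host_fasta, virus_catalog, virus_fasta, reference_usage,
              cp_table, annotations)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(list(host_fasta = host_fasta, virus_catalog = virus_catalog,
                 virus_fasta = virus_fasta, out_dir = out_dir,
                 reference_usage = reference_usage, cp_table = cp_table,
                 annotations = annotations, radius = radius, alpha = alpha,
                 correction = correction, fit_universe = fit_universe,
                 host_id_field = host_id_field,
                 host_id_delim = host_id_delim,
                 pseudo_frequency = pseudo_frequency),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.subgroup_key <- function(group, subgroup_id) {
  g <- chartr("+-", "pm", group)
  paste0(g, "_sg", subgroup_id)
}

#' Run the full codon-usage comparison pipeline
#'
#' Executes every stage over the configured inputs and writes the
#' interface tables plus a JSON run manifest into `out_dir`. The pipeline
#' draws no random numbers, so identical config and inputs give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the selected variants, virus catalog,
#'   metrics table, PCA model, ordination points, per-subgroup
#'   neighbourhoods and enrichment tables, regression summaries, quadrant
#'   counts and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- if (quiet) function(...) invisible() else message
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(tab, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(tab, p)
    outputs <<- c(outputs, name)
  }

  # --- ingest ---------------------------------------------------------
  variants <- .stage("ingest_host", {
    entries <- parse_cds_fasta(config$host_fasta, "host",
                               id_field = config$host_id_field,
                               id_delim = config$host_id_delim)
    suppressMessages(select_major_variants(entries))
  })
  say("ingest_host: ", nrow(variants), " genes selected, ",
      length(attr(variants, "omitted_entities")), " omitted")
  emit(data.frame(entity_id = variants$entity_id,
                  record_id = variants$record_id,
                  length_nt = nchar(variants$sequence),
                  n_codons = variants$n_codons, orf_status = "complete"),
       "selected_variants.tsv")

  catalog <- .stage("ingest_virus", {
    suppressMessages(load_virus_catalog(config$virus_catalog,
                                        config$virus_fasta))
  })
  say("ingest_virus: ", nrow(catalog$species), " species, ",
      nrow(catalog$cds), " CDS")

  # --- per-gene metrics ----------------------------------------------
  ref <- if (!is.null(config$reference_usage)) {
    read_reference_usage(config$reference_usage,
                         pseudo_frequency = config$pseudo_frequency)
  }
  cp <- if (!is.null(config$cp_table)) read_cp_table(config$cp_table)
  metrics <- .stage("codon_metrics", metrics_table(variants, ref, cp))
  emit(metrics, "metrics.tsv")

  virus_vecs <- .stage("codon_metrics", virus_species_rscu(catalog))
  virus_metrics <- .stage("codon_metrics", {
    by_sp <- split(catalog$cds, catalog$cds$species_id)
    do.call(rbind, lapply(names(by_sp), function(sid) {
      counts <- lapply(by_sp[[sid]]$sequence, count_codons)
      data.frame(
        species_id = sid, n_cds = length(counts),
        gc3 = mean(vapply(counts, compute_gc3, numeric(1))),
        cccs = if (is.null(cp)) NA_real_ else
          mean(vapply(counts, compute_cccs, numeric(1), cp = cp)),
        stringsAsFactors = FALSE)
    }))
  })
  emit(virus_metrics, "virus_metrics.tsv")

  # --- ordination -----------------------------------------------------
  host_vecs <- .stage("ordination", {
    counts <- lapply(variants$sequence, count_codons)
    stats::setNames(lapply(counts, compute_rscu), variants$entity_id)
  })
  model <- .stage("ordination", {
    if (config$fit_universe == "all") {
      fit_pca(assemble_rscu_matrix(host_vecs, virus_vecs))
    } else {
      fit_pca(assemble_rscu_matrix(host_vecs))
    }
  })
  say(sprintf("ordination: retained %d components, KMO %.3f",
              model$retained_k, model$kmo))
  host_points <- .stage("ordination",
                        project_points(model, host_vecs, "host_gene"))
  virus_points <- .stage("ordination",
                         project_points(model, virus_vecs, "virus_species"))
  points <- rbind(host_points, virus_points)
  emit(points, "scores.tsv")
  emit(data.frame(component = seq_along(model$eigenvalues),
                  eigenvalue = model$eigenvalues,
                  variance_fraction = model$variance_fraction),
       "model_summary.tsv")
  emit(data.frame(codon = rownames(model$loadings), model$loadings,
                  row.names = NULL), "loadings.tsv")
  quadrants <- quadrant_counts(host_points)
  emit(data.frame(quadrant = names(quadrants),
                  n_genes = as.integer(quadrants)), "quadrant_counts.tsv")

  # --- neighbourhoods -------------------------------------------------
  sg_tab <- unique(catalog$species[, c("group", "subgroup_id")])
  neighborhoods <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(sg_tab))) {
    g <- sg_tab$group[i]; sg <- sg_tab$subgroup_id[i]
    key <- .subgroup_key(g, sg)
    member_ids <- catalog$species$species_id[
      catalog$species$group == g & catalog$species$subgroup_id == sg]
    members <- virus_points[virus_points$entity_id %in% member_ids, ,
                            drop = FALSE]
    ctr <- .stage("neighborhood", subgroup_centroid(members))
    nb <- .stage("neighborhood",
                 select_neighborhood_genes(ctr, config$radius, host_points))
    neighborhoods[[key]] <- nb
    emit(nb$table, paste0("selection_", key, ".tsv"))
    summary_rows[[key]] <- data.frame(
      group = g, subgroup_id = sg, a = ctr[["a"]], b = ctr[["b"]],
      radius = config$radius, n_members = nrow(members),
      n_selected = length(nb$selected_gene_ids), stringsAsFactors = FALSE)
  }
  sel_summary <- do.call(rbind, summary_rows)
  rownames(sel_summary) <- NULL
  emit(sel_summary, "selection_summary.tsv")
  say("neighborhood: ", paste0(sel_summary$n_selected, collapse = "/"),
      " genes selected per subgroup at radius ", config$radius)

  # --- enrichment -----------------------------------------------------
  enrichment <- list()
  if (!is.null(config$annotations)) {
    ann <- .stage("enrichment", {
      read_annotation_map(config$annotations,
                          background = variants$entity_id)
    })
    for (key in names(neighborhoods)) {
      sel <- neighborhoods[[key]]$selected_gene_ids
      if (length(sel) == 0L) next
      res <- .stage("enrichment",
                    enrich_terms(sel, ann, alpha = config$alpha,
                                 correction = config$correction))
      enrichment[[key]] <- res
      emit(res, paste0("enrichment_", key, ".tsv"))
    }
  }

  # --- regression summaries ------------------------------------------
  regressions <- .stage("regression", {
    hp <- host_points[match(metrics$entity_id, host_points$entity_id), ]
    combos <- expand.grid(response = c("cai", "gc3"),
                          predictor = c("pc1", "pc2"),
                          stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      y <- metrics[[combos$response[i]]]
      if (all(is.na(y))) return(NULL)
      f <- fit_linear(hp[[combos$predictor[i]]], y)
      data.frame(response = combos$response[i],
                 predictor = combos$predictor[i],
                 slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, pcc = f$pcc,
                 p_value = f$p_value, n = f$n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  if (!is.null(regressions)) emit(regressions, "regressions.tsv")

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "codonscape",
    package_version = as.character(utils::packageVersion("codonscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    config_digest = config_digest(unclass(config)),
    counts = list(
      host_genes = nrow(variants),
      host_omitted = length(attr(variants, "omitted_entities")),
      virus_species = nrow(catalog$species),
      virus_cds = nrow(catalog$cds),
      subgroups = nrow(sg_tab),
      selected_per_subgroup = stats::setNames(
        as.list(sel_summary$n_selected),
        paste0(sel_summary$group, "_", sel_summary$subgroup_id))
    ),
    kmo = model$kmo,
    retained_components = model$retained_k,
    outputs = outputs
  )
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", length(outputs), " tables + manifest to ", config$out_dir)

  invisible(list(variants = variants, catalog = catalog, metrics = metrics,
                 virus_metrics = virus_metrics, model = model,
                 points = points, host_points = host_points,
                 virus_points = virus_points,
                 neighborhoods = neighborhoods,
                 selection_summary = sel_summary,
                 enrichment = enrichment, regressions = regressions,
                 quadrants = quadrants, manifest = manifest,
                 manifest_path = manifest_path))
}
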