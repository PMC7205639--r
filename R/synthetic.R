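# Seeded synthetic-data generator: host gene sets drawn from codon-preference
# profiles along a GC3 gradient, virus panels clustered in codon space, a CP
# table tied to one profile, a matching reference-usage table, and annotation
# maps with one planted enriched term. Everything the analysis consumes can
# be produced here, so the whole pipeline is testable without downloads.

# typical human protein amino-acid composition (fractions)
.AA_FREQ <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
              Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
              L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
              S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060)

#' Default amino-acid composition used by the generator
#'
#' A single realistic composition is shared by all profiles so that
#' codon-level (not protein-level) differences drive the ordination.
#' @return named numeric vector of 20 amino-acid fractions (sums to 1).
#' @export
default_aa_freq <- function() .AA_FREQ / sum(.AA_FREQ)

#' Construct a codon-preference profile
#'
#' Within every synonymous family the codon weight is the product of a
#' third-base factor and an optional per-codon weight, then normalised.
#' The third-base factor puts mass `gc3_target` on G/C-ending codons and
#' `1 - gc3_target` on A/T-ending ones (split between purine and
#' pyrimidine by `purine3_target`), so the expected GC3 of generated genes
#' tracks `gc3_target` directly; `purine3_target` is an independent second
#' preference axis that separates profiles with equal GC3.
#'
#' @param profile_id short profile label.
#' @param gc3_target target third-base G+C fraction in `[0, 1]` (clamped
#'   away from the boundary so no family degenerates to zero mass).
#' @param purine3_target target third-base purine fraction (same clamping).
#' @param codon_weights optional named multiplicative weights per codon,
#'   e.g. to build degenerate single-codon-per-family profiles.
#' @return object of class `codon_profile`: `profile_id`, `probs` (named
#'   over the 61 sense codons, normalised within each family),
#'   `gc3_target`, `purine3_target`.
#' @export
codon_profile <- function(profile_id, gc3_target = 0.5,
                          purine3_target = 0.5, codon_weights = NULL) {
  gc3 <- min(max(gc3_target, 0.01), 0.99)
  pur <- min(max(purine3_target, 0.01), 0.99)
  base_w <- c(G = gc3 * pur, C = gc3 * (1 - pur),
              A = (1 - gc3) * pur, T = (1 - gc3) * (1 - pur))
  w <- unname(base_w[.THIRD_BASE[SENSE_CODONS]])
  names(w) <- SENSE_CODONS
  if (!is.null(codon_weights)) {
    shared <- intersect(names(codon_weights), SENSE_CODONS)
    w[shared] <- w[shared] * codon_weights[shared]
  }
  probs <- w
  fams <- c(SYN_FAMILIES, list(M = "ATG", W = "TGG"))
  for (fam in fams) {
    tot <- sum(w[fam])
    probs[fam] <- if (tot > 0) w[fam] / tot else 1 / length(fam)
  }
  structure(list(profile_id = profile_id, probs = probs,
                 gc3_target = gc3_target, purine3_target = purine3_target),
            class = "codon_profile")
}

#' Jitter a profile by family-wise Dirichlet resampling
#'
#' Each family's probability vector is redrawn from a Dirichlet
#' distribution centred on the parent profile; `concentration` is the
#' single knob controlling spread (larger = tighter around the parent).
#' Zero-probability codons stay at zero.
#'
#' @param profile a [codon_profile()].
#' @param concentration Dirichlet concentration (sum of the alpha vector
#'   scale; default 300 gives small per-species jitter).
#' @param profile_id id of the jittered copy.
#' @return a new `codon_profile`.
#' @export
jitter_profile <- function(profile, concentration = 300,
                           profile_id = paste0(profile$profile_id, "_j")) {
  stopifnot(inherits(profile, "codon_profile"), concentration > 0)
  probs <- profile$probs
  if (!is.finite(concentration)) {
    # infinite concentration: no jitter, an exact copy of the parent
    return(structure(list(profile_id = profile_id, probs = probs,
                          gc3_target = profile$gc3_target,
                          purine3_target = profile$purine3_target),
                     class = "codon_profile"))
  }
  fams <- c(SYN_FAMILIES, list(M = "ATG", W = "TGG"))
  for (fam in fams) {
    p <- probs[fam]
    pos <- p > 0
    if (sum(pos) < 2L) next
    g <- stats::rgamma(sum(pos), shape = concentration * p[pos], rate = 1)
    if (sum(g) == 0) next
    p[pos] <- g / sum(g)
    probs[fam] <- p
  }
  structure(list(profile_id = profile_id, probs = probs,
                 gc3_target = profile$gc3_target,
                 purine3_target = profile$purine3_target),
            class = "codon_profile")
}

#' Describe a gene population with per-gene profile variation
#'
#' Host gene sets are generated from populations: either a fixed
#' [codon_profile()] (a tight cluster in codon space) or a range
#' population, where every gene draws its own `gc3` and `purine3` targets
#' uniformly from the given intervals — a continuous cloud emulating the
#' broad codon-usage heterogeneity of a real genome.
#'
#' @param profile_id population label recorded in the truth table.
#' @param gc3,purine3 scalar targets, or length-2 ranges for per-gene
#'   uniform draws.
#' @return object of class `profile_population`.
#' @export
profile_population <- function(profile_id, gc3, purine3 = 0.5) {
  stopifnot(length(gc3) %in% 1:2, length(purine3) %in% 1:2)
  structure(list(profile_id = profile_id, gc3 = gc3, purine3 = purine3),
            class = "profile_population")
}

# draw codon strings for n genes of lengths L (internal codons only)
.draw_codons <- function(profile, L, aa_freq) {
  tot <- sum(L)
  aa_all <- sample(names(aa_freq), tot, replace = TRUE, prob = aa_freq)
  codon_all <- character(tot)
  fams <- c(SYN_FAMILIES, list(M = "ATG", W = "TGG"))
  for (aa in unique(aa_all)) {
    idx <- which(aa_all == aa)
    fam <- fams[[aa]]
    p <- profile$probs[fam]
    codon_all[idx] <- if (length(fam) == 1L) fam else
      sample(fam, length(idx), replace = TRUE, prob = p)
  }
  gene_of <- rep.int(seq_along(L), L)
  vapply(split(codon_all, gene_of), paste, character(1), collapse = "")
}

#' Generate a synthetic host gene set
#'
#' Gene lengths are log-normal; amino acids are drawn from a fixed
#' composition and codons from the gene's profile; an ATG start and TAA
#' stop complete the ORF, so every record validates as complete. The truth
#' table records each gene's generating profile and realised GC3.
#'
#' @param profiles list of [codon_profile()] and/or [profile_population()]
#'   objects.
#' @param n_genes genes per profile (recycled over profiles).
#' @param length_meanlog,length_sdlog log-normal parameters of the internal
#'   codon count (defaults: median 400 codons, sdlog 0.35).
#' @param min_codons lower clamp on the internal codon count.
#' @param aa_freq amino-acid composition (default [default_aa_freq()]).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the output is fully reproducible.
#' @return list with `sequences` (named by record id `Txxxxx|Gxxxxx`),
#'   and `truth` (data.frame `gene_id`, `record_id`, `profile_id`,
#'   `n_codons`, `gc3`).
#' @export
synthesize_gene_set <- function(profiles, n_genes,
                                length_meanlog = log(400),
                                length_sdlog = 0.35,
                                min_codons = 50L,
                                aa_freq = default_aa_freq(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(profiles, c("codon_profile", "profile_population"))) {
    profiles <- list(profiles)
  }
  n_genes <- rep_len(n_genes, length(profiles))
  total <- sum(n_genes)
  gene_id <- sprintf("G%05d", seq_len(total))
  record_id <- sprintf("T%05d|%s", seq_len(total), gene_id)
  profile_id <- rep.int(vapply(profiles, `[[`, character(1), "profile_id"),
                        n_genes)
  seqs <- character(total)
  offset <- 0L
  for (i in seq_along(profiles)) {
    n <- n_genes[i]
    if (n == 0L) next
    L <- pmax(min_codons, round(stats::rlnorm(n, length_meanlog,
                                              length_sdlog)))
    pop <- profiles[[i]]
    if (inherits(pop, "profile_population") &&
        (length(pop$gc3) == 2L || length(pop$purine3) == 2L)) {
      # per-gene profile draws: a continuous cloud in codon-preference space
      gc3_i <- if (length(pop$gc3) == 2L)
        stats::runif(n, pop$gc3[1L], pop$gc3[2L]) else rep(pop$gc3, n)
      pur_i <- if (length(pop$purine3) == 2L)
        stats::runif(n, pop$purine3[1L], pop$purine3[2L])
        else rep(pop$purine3, n)
      body <- vapply(seq_len(n), function(g) {
        prof <- codon_profile(pop$profile_id, gc3_i[g], pur_i[g])
        .draw_codons(prof, L[g], aa_freq)
      }, character(1))
    } else {
      prof <- if (inherits(pop, "profile_population")) {
        codon_profile(pop$profile_id, pop$gc3, pop$purine3)
      } else {
        pop
      }
      body <- .draw_codons(prof, L, aa_freq)
    }
    seqs[offset + seq_len(n)] <- paste0("ATG", unname(body), "TAA")
    offset <- offset + n
  }
  names(seqs) <- record_id
  gc3 <- vapply(seqs, function(s) compute_gc3(count_codons(s)), numeric(1),
                USE.NAMES = FALSE)
  list(sequences = seqs,
       truth = data.frame(gene_id = gene_id, record_id = record_id,
                          profile_id = profile_id,
                          n_codons = nchar(seqs) %/% 3L, gc3 = gc3,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic virus panel
#'
#' Every species draws a Dirichlet-jittered copy of its subgroup's profile
#' and emits several coding sequences from it, emulating a panel of virus
#' species that cluster by subgroup in codon space.
#'
#' @param subgroups list of subgroup descriptions: `subgroup_id`, `group`
#'   (genome-polarity label), `profile` (a [codon_profile()]), `n_species`,
#'   and optionally `jitter_concentration` (default 300), `cds_range`
#'   (default `c(3, 6)` CDS per species), `cds_meanlog` (default log(600)),
#'   `cds_sdlog` (default 0.4).
#' @param aa_freq amino-acid composition.
#' @param min_codons lower clamp on CDS internal codon count.
#' @param seed optional integer seed.
#' @return list with `sequences` (named by record id), `catalog_config`
#'   (list suitable for [load_virus_catalog()]), and `truth` (data.frame
#'   `species_id`, `group`, `subgroup_id`, `profile_id`, `n_cds`).
#' @export
synthesize_virus_panel <- function(subgroups, aa_freq = default_aa_freq(),
                                   min_codons = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- list()
  seqs <- character(0)
  truth <- list()
  sp_i <- 0L
  rec_i <- 0L
  for (sg in subgroups) {
    conc <- sg$jitter_concentration %||% 300
    cds_range <- sg$cds_range %||% c(3L, 6L)
    meanlog <- sg$cds_meanlog %||% log(600)
    sdlog <- sg$cds_sdlog %||% 0.4
    for (s in seq_len(sg$n_species)) {
      sp_i <- sp_i + 1L
      sid <- sprintf("VS%03d", sp_i)
      prof <- jitter_profile(sg$profile, concentration = conc,
                             profile_id = paste0(sg$profile$profile_id,
                                                 "_", sid))
      n_cds <- sample(seq(cds_range[1L], cds_range[2L]), 1L)
      L <- pmax(min_codons, round(stats::rlnorm(n_cds, meanlog, sdlog)))
      body <- .draw_codons(prof, L, aa_freq)
      rid <- sprintf("VC%04d", rec_i + seq_len(n_cds))
      rec_i <- rec_i + n_cds
      cds <- stats::setNames(paste0("ATG", body, "TAA"), rid)
      seqs <- c(seqs, cds)
      species[[sp_i]] <- list(species_id = sid, group = sg$group,
                              subgroup_id = as.character(sg$subgroup_id),
                              records = rid)
      truth[[sp_i]] <- data.frame(species_id = sid, group = sg$group,
                                  subgroup_id = as.character(sg$subgroup_id),
                                  profile_id = prof$profile_id,
                                  n_cds = n_cds, stringsAsFactors = FALSE)
    }
  }
  list(sequences = seqs,
       catalog_config = list(species = species),
       truth = do.call(rbind, truth))
}

#' Generate an annotation map with one planted enriched term
#'
#' The planted term is assigned to genes of the target profile with
#' probability `min(1, factor * q)` and to all other genes with probability
#' `q`; decoy terms are assigned uniformly at `decoy_q`. With `factor = 1`
#' the planted term carries no signal.
#'
#' @param truth gene truth table from [synthesize_gene_set()].
#' @param target_profile profile id whose genes carry the enrichment.
#' @param planted_term term id of the planted term.
#' @param factor enrichment factor (>= 1).
#' @param q baseline annotation probability.
#' @param n_decoy number of uniform decoy terms.
#' @param decoy_q per-gene probability of each decoy term.
#' @param seed optional integer seed.
#' @return an [annotation_map()] with background = all genes.
#' @export
synthesize_annotations <- function(truth, target_profile,
                                   planted_term = "TERM_planted",
                                   factor = 10, q = 0.05,
                                   n_decoy = 20L, decoy_q = 0.05,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(factor >= 1, q >= 0, q <= 1)
  genes <- truth$gene_id
  p <- ifelse(truth$profile_id == target_profile, min(1, factor * q), q)
  hit <- stats::runif(length(genes)) < p
  pairs <- data.frame(gene_id = genes[hit],
                      term_id = rep(planted_term, sum(hit)),
                      stringsAsFactors = FALSE)
  if (n_decoy > 0L && decoy_q > 0) {
    for (j in seq_len(n_decoy)) {
      hit_j <- stats::runif(length(genes)) < decoy_q
      if (!any(hit_j)) next
      pairs <- rbind(pairs,
                     data.frame(gene_id = genes[hit_j],
                                term_id = sprintf("TERM_decoy%02d", j),
                                stringsAsFactors = FALSE))
    }
  }
  annotation_map(pairs, background = genes)
}

#' Derive a synthetic codon-preference table from two profiles
#'
#' cp(codon) = log2(p_ccr / p_opt) within each family, clipped to
#' `[-clip, clip]`, so genes generated from the `ccr` profile have positive
#' expected CCCS and genes from the `optimal` profile negative.
#'
#' @param optimal_profile,ccr_profile two [codon_profile()] objects.
#' @param clip symmetric clipping bound (default 3).
#' @return named numeric vector over the 61 sense codons.
#' @export
synthesize_cp_table <- function(optimal_profile, ccr_profile, clip = 3) {
  p_opt <- optimal_profile$probs
  p_ccr <- ccr_profile$probs
  cp <- numeric(length(SENSE_CODONS))
  names(cp) <- SENSE_CODONS
  both <- p_opt > 0 & p_ccr > 0
  cp[both] <- log2(p_ccr[both] / p_opt[both])
  cp[p_opt == 0 & p_ccr > 0] <- clip
  cp[p_opt > 0 & p_ccr == 0] <- -clip
  pmin(pmax(cp, -clip), clip)
}

#' Reference codon-usage frequencies implied by a profile
#'
#' Per-1000 codon frequencies aa_freq(aa) * p(codon | aa) * 1000, the usage
#' table of a genome dominated by the given profile.
#'
#' @param profile a [codon_profile()].
#' @param aa_freq amino-acid composition.
#' @return named numeric vector over the 61 sense codons.
#' @export
synthesize_reference_usage <- function(profile, aa_freq = default_aa_freq()) {
  aa_of <- GENETIC_CODE_64[SENSE_CODONS]
  freq <- 1000 * unname(aa_freq[aa_of]) * profile$probs[SENSE_CODONS]
  stats::setNames(freq, SENSE_CODONS)
}

#' Study-condition defaults for the synthetic analysis
#'
#' The conditions used by the worked analysis and the acceptance checks:
#' 2,000 host genes from three populations — a tight GC3-rich "optimal"
#' cluster, a broad continuous "gradient" cloud spanning GC3 0.32-0.92
#' with an independent third-base purine preference axis, and a tight
#' AT3-rich "viral_like" cluster — plus ten virus species in three
#' subgroups clustered near the viral-like profile.
#' The planted annotation term enriches viral-like genes tenfold over a 5%
#' baseline; the CP table contrasts the viral-like (cell-cycle-like)
#' profile with the optimal one.
#'
#' @param seed integer seed stored in the config; [synthetic_bundle()]
#'   applies it before generation.
#' @return a nested configuration list.
#' @export
default_synthetic_config <- function(seed = 20190420L) {
  host_profiles <- list(
    codon_profile("optimal",    gc3_target = 0.85, purine3_target = 0.50),
    profile_population("gradient", gc3 = c(0.32, 0.92),
                       purine3 = c(0.25, 0.75)),
    codon_profile("viral_like", gc3_target = 0.30, purine3_target = 0.50)
  )
  virus_subgroups <- list(
    list(subgroup_id = "1", group = "+ssRNA", n_species = 3L,
         profile = codon_profile("vsub1", 0.28, 0.46)),
    list(subgroup_id = "2", group = "-ssRNA", n_species = 4L,
         profile = codon_profile("vsub2", 0.30, 0.50)),
    list(subgroup_id = "3", group = "Ambi", n_species = 3L,
         profile = codon_profile("vsub3", 0.32, 0.54))
  )
  list(
    seed = seed,
    host = list(profiles = host_profiles,
                n_genes = c(250L, 1250L, 500L),
                length_meanlog = log(400), length_sdlog = 0.35,
                min_codons = 50L),
    viruses = list(subgroups = virus_subgroups),
    annotations = list(target_profile = "viral_like",
                       planted_term = "TERM_planted",
                       factor = 10, q = 0.05,
                       n_decoy = 20L, decoy_q = 0.05),
    target_profile = "viral_like",
    optimal_profile = "optimal",
    radius = 0.3
  )
}

#' Generate and (optionally) write a complete synthetic input bundle
#'
#' Runs every generator under the config's seed and, when `dir` is given,
#' writes the standard input files the pipeline consumes: host and virus
#' multi-FASTA, the virus catalog YAML, reference-usage and CP TSVs, the
#' annotation TSV and the two truth tables.
#'
#' @param config configuration list (default [default_synthetic_config()]).
#' @param dir output directory; `NULL` keeps everything in memory.
#' @return list: `host` (sequences + truth), `viruses`, `annotations`,
#'   `cp`, `reference_usage`, `profiles`, and `paths` (named file paths, if
#'   written).
#' @export
synthetic_bundle <- function(config = default_synthetic_config(),
                             dir = NULL) {
  set.seed(config$seed)
  host <- synthesize_gene_set(config$host$profiles, config$host$n_genes,
                              length_meanlog = config$host$length_meanlog,
                              length_sdlog = config$host$length_sdlog,
                              min_codons = config$host$min_codons)
  viruses <- synthesize_virus_panel(config$viruses$subgroups)
  ann_cfg <- config$annotations
  ann <- synthesize_annotations(host$truth, ann_cfg$target_profile,
                                planted_term = ann_cfg$planted_term,
                                factor = ann_cfg$factor, q = ann_cfg$q,
                                n_decoy = ann_cfg$n_decoy,
                                decoy_q = ann_cfg$decoy_q)
  profiles <- config$host$profiles
  names(profiles) <- vapply(profiles, `[[`, character(1), "profile_id")
  cp <- synthesize_cp_table(profiles[[config$optimal_profile]],
                            profiles[[config$target_profile]])
  ref <- synthesize_reference_usage(profiles[[config$optimal_profile]])
  out <- list(host = host, viruses = viruses, annotations = ann, cp = cp,
              reference_usage = ref, profiles = profiles, paths = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(host_fasta = file.path(dir, "host_cds.fasta"),
               virus_fasta = file.path(dir, "virus_cds.fasta"),
               virus_catalog = file.path(dir, "virus_catalog.yml"),
               reference_usage = file.path(dir, "reference_usage.tsv"),
               cp_table = file.path(dir, "cp_table.tsv"),
               annotations = file.path(dir, "annotations.tsv"),
               host_truth = file.path(dir, "host_truth.tsv"),
               virus_truth = file.path(dir, "virus_truth.tsv"))
    write_fasta(host$sequences, paths[["host_fasta"]])
    write_fasta(viruses$sequences, paths[["virus_fasta"]])
    yaml::write_yaml(viruses$catalog_config, paths[["virus_catalog"]])
    write_tsv(data.frame(codon = names(ref), frequency = unname(ref)),
              paths[["reference_usage"]])
    write_tsv(data.frame(codon = names(cp), cp_value = unname(cp)),
              paths[["cp_table"]])
    write_tsv(ann$pairs, paths[["annotations"]])
    write_tsv(host$truth, paths[["host_truth"]])
    write_tsv(viruses$truth, paths[["virus_truth"]])
    out$paths <- paths
  }
  out
}
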