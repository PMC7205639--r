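# Reading CDS FASTA files, ORF validation, major-variant selection and the
# virus catalog.

#' Read a CDS multi-FASTA file
#'
#' Reads a (possibly gzipped) multi-FASTA of protein-coding sequences,
#' upper-cases the sequences and maps U to T so RNA-style records are
#' accepted. The entity a record belongs to (host gene, or virus species) is
#' extracted from the header according to `id_scheme`.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param id_scheme `"host"`: the entity id is a delimited token of the
#'   header (see `id_field`, `id_delim`); `"virus"`: the entity id is looked
#'   up in `species_map` (record id -> species id), falling back to the
#'   record id itself.
#' @param id_field 1-based index of the header token holding the host gene
#'   id. Header token layouts vary between annotation releases, so the
#'   field/delimiter pair is configurable rather than hard-coded.
#' @param id_delim single-character token delimiter in the header.
#' @param species_map named character vector mapping record ids to species
#'   ids (virus scheme only).
#' @return a data.frame with columns `record_id`, `entity_id`, `sequence`,
#'   one row per FASTA record.
#' @export
parse_cds_fasta <- function(path, id_scheme = c("host", "virus"),
                            id_field = 2L, id_delim = "|",
                            species_map = NULL) {
  id_scheme <- match.arg(id_scheme)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  record_id <- vapply(strsplit(headers, "[ \t]"), `[[`, character(1), 1L)
  if (anyNA(record_id) || any(record_id == "")) {
    stop("FASTA record with empty header in ", path, call. = FALSE)
  }
  sequence <- chartr("u", "t", tolower(as.character(set)))
  sequence <- toupper(sequence)
  entity_id <- switch(id_scheme,
    host = {
      tokens <- strsplit(record_id, id_delim, fixed = TRUE)
      bad <- lengths(tokens) < id_field
      if (any(bad)) {
        stop("header of record '", record_id[which(bad)[1L]],
             "' has no field ", id_field, " (delimiter '", id_delim, "')",
             call. = FALSE)
      }
      vapply(tokens, `[[`, character(1), id_field)
    },
    virus = {
      if (is.null(species_map)) {
        record_id
      } else {
        out <- unname(species_map[record_id])
        ifelse(is.na(out), record_id, out)
      }
    }
  )
  data.frame(record_id = record_id, entity_id = entity_id,
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Classify the ORF completeness of a nucleotide sequence
#'
#' A total function returning exactly one verdict, checked in a fixed
#' order: `ambiguous_base` (any character outside A/C/G/T), `bad_length`
#' (length not a positive multiple of 3), `no_start` (first codon not ATG),
#' `internal_stop` (a stop codon before the final position), and
#' `no_terminal_stop` (last codon not TAA/TAG/TGA). Sequences passing all
#' checks are `complete`; only those enter downstream analysis.
#'
#' @param sequence a non-empty nucleotide string.
#' @return one of `"complete"`, `"no_start"`, `"no_terminal_stop"`,
#'   `"internal_stop"`, `"bad_length"`, `"ambiguous_base"`.
#' @export
validate_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (grepl("[^ACGT]", sequence)) return("ambiguous_base")
  n <- nchar(sequence)
  if (n %% 3L != 0L) return("bad_length")
  codons <- split_codons(sequence)
  if (codons[1L] != "ATG") return("no_start")
  k <- length(codons)
  if (k > 1L && any(codons[-k] %in% STOP_CODONS)) return("internal_stop")
  if (!codons[k] %in% STOP_CODONS) return("no_terminal_stop")
  "complete"
}

#' Select one major transcript variant per entity
#'
#' Keeps, for every entity, the longest sequence whose ORF is complete
#' (ties broken by lexicographically smallest record id). Entities with no
#' complete variant are omitted; their ids are reported via a message and
#' the `"omitted_entities"` attribute.
#'
#' @param entries data.frame with columns `record_id`, `entity_id`,
#'   `sequence` (as returned by [parse_cds_fasta()]).
#' @return data.frame of validated coding sequences with columns
#'   `entity_id`, `record_id`, `sequence`, `n_codons`, one row per entity,
#'   ordered by `entity_id`. Attributes: `omitted_entities` (character) and
#'   `orf_status` (per-input-record verdicts).
#' @export
select_major_variants <- function(entries) {
  stopifnot(nrow(entries) > 0L,
            all(c("record_id", "entity_id", "sequence") %in% names(entries)))
  status <- vapply(entries$sequence, validate_orf, character(1),
                   USE.NAMES = FALSE)
  ok <- entries[status == "complete", , drop = FALSE]
  all_entities <- unique(entries$entity_id)
  if (nrow(ok) > 0L) {
    len <- nchar(ok$sequence)
    # longest first, then smallest record_id; first row per entity wins
    ord <- order(ok$entity_id, -len, ok$record_id, method = "radix")
    ok <- ok[ord, , drop = FALSE]
    keep <- !duplicated(ok$entity_id)
    sel <- ok[keep, , drop = FALSE]
  } else {
    sel <- ok
  }
  omitted <- setdiff(all_entities, sel$entity_id)
  if (length(omitted) > 0L) {
    message(length(omitted), " entit",
            if (length(omitted) == 1L) "y" else "ies",
            " without a complete ORF omitted")
  }
  out <- data.frame(entity_id = sel$entity_id, record_id = sel$record_id,
                    sequence = sel$sequence,
                    n_codons = nchar(sel$sequence) %/% 3L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$entity_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted_entities") <- omitted
  attr(out, "orf_status") <- data.frame(record_id = entries$record_id,
                                        orf_status = status,
                                        stringsAsFactors = FALSE)
  out
}

#' Load a virus catalog from a config and CDS FASTA files
#'
#' The catalog config assigns every virus species to a genome-polarity
#' group and a subgroup, and lists the FASTA record ids holding its coding
#' sequences. CDS records failing [validate_orf()] are dropped with a
#' logged count per species; a species left with zero valid CDS is an
#' error.
#'
#' @param config path to a YAML file, or an equivalent list, with an
#'   element `species`: a list of entries `species_id`, `group` (one of
#'   `+ssRNA`, `-ssRNA`, `dsRNA`, `Retro`, `Ambi`), `subgroup_id`, and
#'   `records` (character vector of FASTA record ids).
#' @param fasta_paths character vector of CDS FASTA files to read.
#' @return an object of class `virus_catalog`: a list with `species`
#'   (data.frame `species_id`, `group`, `subgroup_id`, `n_cds`,
#'   `n_dropped`) and `cds` (data.frame `species_id`, `record_id`,
#'   `sequence`, `n_codons`).
#' @export
load_virus_catalog <- function(config, fasta_paths) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$species))
  groups <- c("+ssRNA", "-ssRNA", "dsRNA", "Retro", "Ambi")
  sp <- config$species
  ids <- vapply(sp, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) {
    stop("duplicate species_id in catalog config: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  species_map <- unlist(lapply(sp, function(s) {
    stats::setNames(rep(s$species_id, length(s$records)),
                    unlist(s$records))
  }))
  entries <- do.call(rbind, lapply(fasta_paths, parse_cds_fasta,
                                   id_scheme = "virus",
                                   species_map = species_map))
  entries <- entries[entries$record_id %in% names(species_map), , drop = FALSE]
  cds_list <- vector("list", length(sp))
  meta <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    s <- sp[[i]]
    if (!s$group %in% groups) {
      stop("species '", s$species_id, "': unknown group '", s$group, "'",
           call. = FALSE)
    }
    rec <- entries[entries$entity_id == s$species_id, , drop = FALSE]
    if (nrow(rec) == 0L) {
      stop("species '", s$species_id,
           "' has no FASTA records matching the catalog", call. = FALSE)
    }
    status <- vapply(rec$sequence, validate_orf, character(1),
                     USE.NAMES = FALSE)
    dropped <- sum(status != "complete")
    if (dropped > 0L) {
      message("species ", s$species_id, ": dropped ", dropped,
              " CDS with incomplete ORFs")
    }
    rec <- rec[status == "complete", , drop = FALSE]
    if (nrow(rec) == 0L) {
      stop("species '", s$species_id,
           "' has no CDS with a complete ORF", call. = FALSE)
    }
    cds_list[[i]] <- data.frame(species_id = s$species_id,
                                record_id = rec$record_id,
                                sequence = rec$sequence,
                                n_codons = nchar(rec$sequence) %/% 3L,
                                stringsAsFactors = FALSE)
    meta[[i]] <- data.frame(species_id = s$species_id, group = s$group,
                            subgroup_id = as.character(s$subgroup_id),
                            n_cds = nrow(rec), n_dropped = dropped,
                            stringsAsFactors = FALSE)
  }
  out <- list(species = do.call(rbind, meta), cds = do.call(rbind, cds_list))
  class(out) <- "virus_catalog"
  out
}

#' Write the selected-variant table
#'
#' @param variants data.frame from [select_major_variants()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  tab <- data.frame(entity_id = variants$entity_id,
                    record_id = variants$record_id,
                    length_nt = nchar(variants$sequence),
                    n_codons = variants$n_codons,
                    orf_status = "complete",
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}
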