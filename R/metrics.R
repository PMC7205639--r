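# Per-sequence codon statistics: codon counts, RSCU, CAI, GC3 and CCCS.

#' Count codons of a coding sequence
#'
#' Counts consecutive, non-overlapping triplets from position 1 over all 64
#' codons. Stop codons are retained in the counts; each downstream metric
#' excludes codons per its own definition.
#'
#' @param sequence a nucleotide string over A/C/G/T whose length is a
#'   multiple of 3 (one row of a validated coding-sequence table, or a bare
#'   string).
#' @return named integer vector over the 64 codons in fixed order, with
#'   attribute `total_codons`.
#' @export
count_codons <- function(sequence) {
  codons <- split_codons(sequence)
  idx <- match(codons, CODONS_64)
  if (anyNA(idx)) {
    stop("sequence contains a non-ACGT codon: ",
         codons[which(is.na(idx))[1L]], call. = FALSE)
  }
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- CODONS_64
  structure(counts, total_codons = length(codons))
}

#' Codon-count matrix for many sequences
#'
#' @param sequences named character vector of coding sequences.
#' @return integer matrix, one row per sequence, 64 codon columns.
#' @export
codon_count_matrix <- function(sequences) {
  m <- t(vapply(sequences, function(s) as.integer(count_codons(s)),
                integer(64L)))
  colnames(m) <- CODONS_64
  m
}

#' Relative synonymous codon usage of one gene
#'
#' RSCU of codon i in a synonymous family of size n is
#' X_i / ((1/n) * sum(X)) — the observed count over the count expected if
#' the family's codons were used equally. A value of 1 means no bias;
#' values above 1 mark abundant codons. The three stop codons and the
#' single-codon families Met (ATG) and Trp (TGG) are excluded, leaving 59
#' values. Families that do not occur in the gene get all-zero entries and
#' their amino acid is left out of the `present_aa` attribute (0/0 is
#' undefined; zero keeps the vector numeric while `present_aa` flags
#' absence).
#'
#' @param counts codon counts from [count_codons()] (any named numeric
#'   vector covering the 59 RSCU codons works).
#' @return named numeric vector over the 59 RSCU codons in fixed order,
#'   with attribute `present_aa`.
#' @export
compute_rscu <- function(counts) {
  x <- counts[RSCU_CODONS]
  out <- numeric(length(RSCU_CODONS))
  names(out) <- RSCU_CODONS
  present <- character(0)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    tot <- sum(x[fam])
    if (tot > 0) {
      out[fam] <- x[fam] / (tot / length(fam))
      present <- c(present, aa)
    }
  }
  structure(out, present_aa = present)
}

#' Average several RSCU vectors
#'
#' Element-wise arithmetic mean over the 59 codons; used to represent a
#' virus species by the mean RSCU of its coding sequences. Unweighted by
#' default; `weights` (e.g. codon counts per CDS) gives a weighted mean.
#'
#' @param vectors list of RSCU vectors from [compute_rscu()].
#' @param weights optional numeric vector of non-negative weights, one per
#'   input vector.
#' @return an RSCU vector; `present_aa` is the union of the inputs'.
#' @export
average_rscu <- function(vectors, weights = NULL) {
  if (length(vectors) == 0L) stop("no RSCU vectors to average", call. = FALSE)
  m <- do.call(rbind, lapply(vectors, function(v) v[RSCU_CODONS]))
  if (is.null(weights)) {
    avg <- colMeans(m)
  } else {
    stopifnot(length(weights) == length(vectors), all(weights >= 0),
              sum(weights) > 0)
    avg <- colSums(m * weights) / sum(weights)
  }
  present <- sort(unique(unlist(lapply(vectors, attr, "present_aa"))))
  structure(avg, present_aa = present)
}

#' Build a reference codon-usage object
#'
#' Accepts a reference usage table on any common scale (raw counts,
#' per-1000, fractions) and derives per-codon relative adaptiveness
#' w = frequency / max(frequency in the synonymous family), the weight
#' scheme of the codon adaptation index.
#'
#' @param frequency named numeric vector, codon -> frequency. Stop codons
#'   may be present or absent; they are ignored.
#' @param pseudo_frequency optional small frequency substituted for codons
#'   with zero (or missing) reference frequency, enabling CAI on genes that
#'   use codons unobserved in the reference. `NULL` (default) leaves zero
#'   weights in place; [compute_cai()] then errors if such a codon occurs.
#' @return object of class `reference_usage` with elements `frequency` and
#'   `w` (relative adaptiveness over the 61 sense codons).
#' @export
reference_usage <- function(frequency, pseudo_frequency = NULL) {
  stopifnot(is.numeric(frequency), !is.null(names(frequency)))
  freq <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  shared <- intersect(names(frequency), SENSE_CODONS)
  freq[shared] <- frequency[shared]
  if (any(freq < 0)) stop("negative reference frequency", call. = FALSE)
  if (!is.null(pseudo_frequency)) {
    stopifnot(pseudo_frequency > 0)
    freq[freq == 0] <- pseudo_frequency
  }
  w <- freq
  fams <- c(SYN_FAMILIES, list(M = "ATG", W = "TGG"))
  for (fam in fams) {
    mx <- max(freq[fam])
    w[fam] <- if (mx > 0) freq[fam] / mx else 0
  }
  structure(list(frequency = freq, w = w), class = "reference_usage")
}

#' Read a two-column reference usage TSV (codon, frequency)
#'
#' @inheritParams reference_usage
#' @param path TSV path; a header line is expected.
#' @export
read_reference_usage <- function(path, pseudo_frequency = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  reference_usage(stats::setNames(tab[[2L]], tab[[1L]]),
                  pseudo_frequency = pseudo_frequency)
}

#' Codon adaptation index of one gene
#'
#' Geometric mean of relative adaptiveness over all occurrences of the 59
#' scoreable codons (stop codons and the single-codon families ATG/TGG are
#' excluded, the Sharp-Li convention), computed in log space.
#'
#' @param counts codon counts from [count_codons()].
#' @param ref a [reference_usage()] object.
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_usage"))
  x <- counts[RSCU_CODONS]
  used <- x > 0
  if (!any(used)) stop("no scoreable codons for CAI", call. = FALSE)
  w <- ref$w[RSCU_CODONS][used]
  if (any(w <= 0)) {
    stop("codon ", RSCU_CODONS[used][which(w <= 0)[1L]],
         " has zero reference frequency; set pseudo_frequency in the ",
         "reference usage to score it", call. = FALSE)
  }
  exp(sum(x[used] * log(w)) / sum(x[used]))
}

#' Percentage G+C at the third codon position
#'
#' Computed over all non-stop codons (ATG and TGG included, the standard
#' GC3 convention; stops are excluded as they lie outside the 59-codon
#' analysis universe).
#'
#' @param counts codon counts from [count_codons()].
#' @return percentage in `[0, 100]`.
#' @export
compute_gc3 <- function(counts) {
  x <- counts[SENSE_CODONS]
  tot <- sum(x)
  if (tot == 0) stop("no non-stop codons", call. = FALSE)
  100 * sum(x[third_base_gc(SENSE_CODONS)]) / tot
}

#' Read a two-column codon-preference TSV (codon, cp_value)
#'
#' @param path TSV path; a header line is expected.
#' @return named numeric vector, codon -> signed preference value.
#' @export
read_cp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

#' Cell-cycle codon score of one gene
#'
#' Sum of the codon-preference (CP) values of a designated gene set (e.g.
#' the cell-cycle-regulated "top-600" set) over all sense-codon occurrences
#' of the gene, normalised by gene length. A positive score means the
#' gene's codon usage resembles the CP-defining set. The default length
#' unit is codons, so CP values read as per-codon contributions;
#' `length_unit = "nt"` divides by nucleotide length instead for
#' cross-checks against conventions that normalise by cDNA length.
#'
#' @param counts codon counts from [count_codons()].
#' @param cp named numeric vector of CP values covering every sense codon
#'   used by the gene (see [read_cp_table()]).
#' @param length_unit `"codons"` (default) or `"nt"`.
#' @return the CCCS (signed real).
#' @export
compute_cccs <- function(counts, cp, length_unit = c("codons", "nt")) {
  length_unit <- match.arg(length_unit)
  x <- counts[SENSE_CODONS]
  used <- SENSE_CODONS[x > 0]
  missing_cp <- used[!used %in% names(cp)]
  if (length(missing_cp) > 0L) {
    stop("codon(s) missing from the CP table: ",
         paste(missing_cp, collapse = ", "), call. = FALSE)
  }
  denom <- switch(length_unit,
                  codons = sum(x),
                  nt = 3 * attr(counts, "total_codons"))
  sum(cp[used] * x[used]) / denom
}

#' Per-entity codon metrics table
#'
#' Computes, for each validated coding sequence, the codon count, CAI, GC3,
#' CCCS and the 59 RSCU values in fixed codon order.
#'
#' @param cds data.frame with columns `entity_id`, `sequence`, `n_codons`
#'   (from [select_major_variants()] or a `virus_catalog$cds` table with
#'   `species_id` renamed).
#' @param ref optional [reference_usage()]; omit to skip CAI.
#' @param cp optional CP vector; omit to skip CCCS.
#' @return data.frame: `entity_id`, `n_codons`, `cai`, `gc3`, `cccs`, then
#'   one column per RSCU codon.
#' @export
metrics_table <- function(cds, ref = NULL, cp = NULL) {
  counts <- lapply(cds$sequence, count_codons)
  rscu <- t(vapply(counts, function(ct) as.numeric(compute_rscu(ct)),
                   numeric(length(RSCU_CODONS))))
  colnames(rscu) <- RSCU_CODONS
  out <- data.frame(
    entity_id = cds$entity_id,
    n_codons = cds$n_codons,
    cai = if (is.null(ref)) NA_real_ else
      vapply(counts, compute_cai, numeric(1), ref = ref),
    gc3 = vapply(counts, compute_gc3, numeric(1)),
    cccs = if (is.null(cp)) NA_real_ else
      vapply(counts, compute_cccs, numeric(1), cp = cp),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(rscu))
}

#' RSCU vectors of every virus species in a catalog
#'
#' Each species is represented by the mean RSCU over all its coding
#' sequences across isolates (unweighted by default, mirroring batch
#' per-CDS calculation followed by averaging; `weighted = TRUE` weights by
#' CDS codon count).
#'
#' @param catalog a [load_virus_catalog()] object.
#' @param weighted weight the per-CDS average by codon count?
#' @return named list of RSCU vectors, one per species.
#' @export
virus_species_rscu <- function(catalog, weighted = FALSE) {
  stopifnot(inherits(catalog, "virus_catalog"))
  by_sp <- split(catalog$cds, catalog$cds$species_id)
  lapply(by_sp, function(d) {
    counts <- lapply(d$sequence, count_codons)
    vecs <- lapply(counts, compute_rscu)
    w <- if (weighted) vapply(counts, attr, numeric(1), "total_codons")
         else NULL
    average_rscu(vecs, weights = w)
  })
}
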