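# Virus-subgroup centroids in component space and fixed-radius selection of
# host genes with similar codon usage.

#' Centroid of a virus subgroup in component space
#'
#' The element-wise arithmetic mean (a, b) of the members' (pc1, pc2)
#' coordinates — the subgroup's "mean vRSCU" point. A single-member
#' subgroup's centroid is the member itself.
#'
#' @param members data.frame with `pc1`, `pc2` columns, one row per member
#'   species.
#' @return named numeric vector `c(a = ..., b = ...)`.
#' @export
subgroup_centroid <- function(members) {
  if (is.null(members) || nrow(members) == 0L) {
    stop("subgroup has no members", call. = FALSE)
  }
  c(a = mean(members$pc1), b = mean(members$pc2))
}

#' Select host genes inside a disk around a centroid
#'
#' A gene at (x, y) is selected iff sqrt((a - x)^2 + (b - y)^2) <= radius.
#' The boundary is included: the disk is read as closed, which differs from
#' the open disk only on a measure-zero set.
#'
#' @param center numeric length-2 centroid `(a, b)`.
#' @param radius disk radius (> 0); the pipeline default is 0.3 component
#'   units.
#' @param genes data.frame of gene points with `entity_id`, `pc1`, `pc2`.
#' @return list with `center`, `radius`, `selected_gene_ids` (character),
#'   `distances` (named numeric over all genes) and `table` (data.frame
#'   `gene_id`, `distance`, `selected`).
#' @export
select_neighborhood_genes <- function(center, radius, genes) {
  stopifnot(length(center) == 2L, is.finite(radius), radius > 0)
  d <- sqrt((center[[1L]] - genes$pc1)^2 + (center[[2L]] - genes$pc2)^2)
  names(d) <- genes$entity_id
  sel <- d <= radius
  list(center = c(a = center[[1L]], b = center[[2L]]),
       radius = radius,
       selected_gene_ids = genes$entity_id[sel],
       distances = d,
       table = data.frame(gene_id = genes$entity_id, distance = unname(d),
                          selected = unname(sel), stringsAsFactors = FALSE))
}

#' Data-driven selection radius for one subgroup
#'
#' Formalises the informal radius rule — minimal, not exceeding the
#' standard deviation of gene distances to the centre, covering most of the
#' subgroup's members — as min(sd of gene distances, smallest radius
#' covering at least a `coverage` fraction of the members). The pipeline
#' default stays at the fixed 0.3; this helper exposes the rule for
#' sensitivity checks.
#'
#' @param center numeric length-2 centroid.
#' @param genes data.frame of gene points (`pc1`, `pc2`).
#' @param members data.frame of member points (`pc1`, `pc2`).
#' @param coverage member fraction the radius must cover (default 0.5).
#' @return the radius; 0 (with a warning) in the degenerate all-members-at-
#'   centre case.
#' @export
auto_radius <- function(center, genes, members, coverage = 0.5) {
  stopifnot(nrow(genes) > 0L, nrow(members) > 0L,
            coverage > 0, coverage <= 1)
  gd <- sqrt((center[[1L]] - genes$pc1)^2 + (center[[2L]] - genes$pc2)^2)
  md <- sort(sqrt((center[[1L]] - members$pc1)^2 +
                  (center[[2L]] - members$pc2)^2))
  cover_r <- md[ceiling(coverage * length(md))]
  cap <- stats::sd(gd)
  r <- if (is.na(cap)) cover_r else min(cap, cover_r)
  if (r == 0) warning("degenerate radius 0: members coincide with the centre")
  r
}
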