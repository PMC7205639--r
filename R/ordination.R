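# Ordination of the joint host/virus RSCU matrix: KMO sampling adequacy,
# covariance-matrix PCA, quartimax rotation, projection and quadrant counts.

#' Assemble the host + virus RSCU matrix
#'
#' Rows are entities (host genes first, then virus species, each block
#' sorted by id), columns the 59 RSCU codons in fixed order, so the matrix
#' is identical however the input lists are ordered.
#'
#' @param host named list of host-gene RSCU vectors.
#' @param viruses named list of virus-species RSCU vectors (may be empty).
#' @return numeric matrix with an `entity_kind` attribute (`"host_gene"` /
#'   `"virus_species"` per row).
#' @export
assemble_rscu_matrix <- function(host, viruses = list()) {
  if (length(viruses) == 0L) viruses <- stats::setNames(list(), character(0))
  ids <- c(names(host), names(viruses))
  if (length(ids) != length(host) + length(viruses) || any(ids == "")) {
    stop("all RSCU vectors must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate entity id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  host <- host[order(names(host), method = "radix")]
  viruses <- viruses[order(names(viruses), method = "radix")]
  rows <- c(host, viruses)
  m <- do.call(rbind, lapply(rows, function(v) as.numeric(v[RSCU_CODONS])))
  dimnames(m) <- list(names(rows), RSCU_CODONS)
  if (anyNA(m)) stop("missing RSCU values", call. = FALSE)
  attr(m, "entity_kind") <- rep(c("host_gene", "virus_species"),
                                c(length(host), length(viruses)))
  m
}

#' Kaiser-Meyer-Olkin measure from a correlation matrix
#'
#' KMO = sum(r^2) / (sum(r^2) + sum(q^2)) over off-diagonal elements, where
#' q are the partial correlations obtained from the (pseudo-)inverse of the
#' correlation matrix. The Moore-Penrose pseudo-inverse makes the measure
#' well-defined for singular correlation matrices, which arise here because
#' each present synonymous family's RSCU values sum to the family size.
#'
#' @param R correlation matrix.
#' @return KMO in `[0, 1]`.
#' @export
kmo_from_cor <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), nrow(R) >= 3L)
  A <- MASS::ginv(R)
  d <- sqrt(abs(diag(A)))
  d[d == 0] <- 1
  Q <- -A / tcrossprod(d)
  off <- row(R) != col(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  r2 / (r2 + q2)
}

#' Kaiser-Meyer-Olkin sampling adequacy of a data matrix
#'
#' Zero-variance columns are dropped with a warning before the column
#' correlation matrix is formed. Values of 0.5 and above are conventionally
#' taken as adequate for factoring.
#'
#' @param m numeric matrix, observations in rows.
#' @return overall KMO in `[0, 1]`.
#' @export
compute_kmo <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 3L)
  v <- apply(m, 2L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance column(s) dropped for KMO")
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 3L) stop("fewer than 3 usable columns", call. = FALSE)
  kmo_from_cor(stats::cor(m))
}

#' Quartimax rotation of a loading matrix
#'
#' Orthogonal rotation maximising the quartimax criterion sum(L^4) by
#' pairwise planar rotations with the closed-form orthomax angle
#' (gamma = 0), iterated to convergence. With `normalize = TRUE` rows are
#' Kaiser-normalised (divided by their communality square roots) before
#' rotation and rescaled afterwards.
#'
#' @param L loading matrix (variables x components).
#' @param normalize apply Kaiser row normalisation (default TRUE).
#' @param eps convergence tolerance on the relative criterion increase.
#' @param max_sweeps maximum number of full pairwise sweeps.
#' @return list with `loadings` (rotated matrix) and `rotmat` (orthogonal
#'   matrix R with `loadings = L %*% R`).
#' @export
quartimax <- function(L, normalize = TRUE, eps = 1e-10, max_sweeps = 100L) {
  stopifnot(is.matrix(L))
  k <- ncol(L)
  R <- diag(k)
  if (k < 2L || nrow(L) < 2L) return(list(loadings = L, rotmat = R))
  h <- sqrt(rowSums(L^2))
  scale <- if (normalize) ifelse(h > 0, h, 1) else rep(1, nrow(L))
  A <- L / scale
  crit_old <- sum(A^4)
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(k - 1L)) {
      for (l in seq((j + 1L), k)) {
        x <- A[, j]; y <- A[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- sum(2 * u * v)
        den <- sum(u^2 - v^2)
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-12) next
        cs <- cos(phi); sn <- sin(phi)
        A[, j] <- cs * x + sn * y
        A[, l] <- -sn * x + cs * y
        G <- diag(k)
        G[j, j] <- cs; G[l, l] <- cs; G[j, l] <- -sn; G[l, j] <- sn
        R <- R %*% G
      }
    }
    crit <- sum(A^4)
    if (crit - crit_old <= eps * max(crit_old, 1)) break
    crit_old <- crit
  }
  list(loadings = L %*% R, rotmat = R)
}

#' Principal components of an RSCU matrix
#'
#' Columns are mean-centred and the sample covariance matrix (not the
#' correlation matrix: RSCU columns already share a scale) is
#' eigendecomposed. Components with eigenvalue above 1 are retained, with a
#' floor of two so a 2-D map always exists, and the retained loadings
#' (eigenvectors scaled by the square roots of their eigenvalues) are
#' quartimax-rotated. Component scores are standardised (unit variance over
#' the fitted rows). Because each present synonymous family's RSCU values
#' sum to the family size, the covariance matrix is singular; eigenvalues
#' below `tol` are treated as exactly zero.
#'
#' Component signs are arbitrary in an eigendecomposition; when the columns
#' are codons they are fixed here by a GC3 convention — the loading-weighted
#' third-base G/C direction is made negative on component 1 and positive on
#' component 2 — so that maps are comparable across runs and component 1
#' anticorrelates with GC3. For non-codon matrices the largest absolute
#' loading of each component is made positive.
#'
#' @param m numeric matrix, entities in rows (e.g. from
#'   [assemble_rscu_matrix()]).
#' @param kaiser_normalize Kaiser row normalisation during rotation
#'   (default TRUE, the convention of classic factor-analysis software).
#' @param kmo also compute the overall KMO of `m` (default TRUE; skipped
#'   for matrices with fewer than 3 columns).
#' @param tol eigenvalues below this are treated as zero.
#' @return object of class `pca_model`: `eigenvalues`,
#'   `variance_fraction`, `retained_k`, `loadings` (rotated pattern
#'   matrix), `rotmat`, `scores_coef` (projection weights; see
#'   [project_points()]), `column_means`, `scores` (fitted-row scores),
#'   `kmo`.
#' @export
fit_pca <- function(m, kaiser_normalize = TRUE, kmo = TRUE, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) >= 3L)
  if (!all(is.finite(m))) stop("non-finite values in input", call. = FALSE)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  C <- stats::cov(m)
  ee <- eigen(C, symmetric = TRUE)
  ev <- ee$values
  ev[ev < tol] <- 0
  k <- max(2L, sum(ev > 1))
  k <- min(k, ncol(m))
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  evk <- ev[seq_len(k)]
  A <- V %*% diag(sqrt(evk), k)
  # rotate only components with non-degenerate variance
  live <- evk > tol
  if (sum(live) >= 2L) {
    rot <- quartimax(A[, live, drop = FALSE], normalize = kaiser_normalize)
    R <- diag(k)
    R[live, live] <- rot$rotmat
  } else {
    R <- diag(k)
  }
  A_rot <- A %*% R
  # standardised score coefficients: unit-variance scores over fitted rows
  B <- V %*% diag(ifelse(live, 1 / sqrt(pmax(evk, tol)), 0), k) %*% R
  # order rotated components by decreasing sum of squared loadings
  ss <- colSums(A_rot^2)
  ord <- order(ss, decreasing = TRUE)
  A_rot <- A_rot[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  # sign convention
  signs <- rep(1, k)
  if (all(colnames(m) %in% CODONS_64)) {
    gcdir <- ifelse(third_base_gc(colnames(m)), 1, -1)
    gw <- as.numeric(crossprod(gcdir, A_rot))
    if (gw[1L] > 0) signs[1L] <- -1
    if (k >= 2L && gw[2L] < 0) signs[2L] <- -1
    if (k > 2L) {
      for (j in 3:k) {
        if (A_rot[which.max(abs(A_rot[, j])), j] < 0) signs[j] <- -1
      }
    }
  } else {
    for (j in seq_len(k)) {
      if (A_rot[which.max(abs(A_rot[, j])), j] < 0) signs[j] <- -1
    }
  }
  A_rot <- sweep(A_rot, 2L, signs, `*`)
  B <- sweep(B, 2L, signs, `*`)
  R <- sweep(R, 2L, signs, `*`)
  pc_names <- paste0("PC", seq_len(k))
  dimnames(A_rot) <- list(colnames(m), pc_names)
  dimnames(B) <- list(colnames(m), pc_names)
  scores <- xc %*% B
  model <- list(
    eigenvalues = ev,
    variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
    retained_k = k,
    loadings = A_rot,
    rotmat = R,
    scores_coef = B,
    column_means = mu,
    scores = scores,
    kmo = if (kmo && ncol(m) >= 3L) compute_kmo(m) else NA_real_
  )
  class(model) <- "pca_model"
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Covariance-matrix PCA with quartimax rotation\n")
  cat(sprintf("  %d variables, %d retained components (eigenvalue > 1, floor 2)\n",
              nrow(x$loadings), x$retained_k))
  vf <- sum(x$variance_fraction[seq_len(x$retained_k)])
  cat(sprintf("  retained variance fraction: %.3f; KMO: %.3f\n", vf, x$kmo))
  invisible(x)
}

#' Project RSCU vectors into component space
#'
#' Scores are computed as (vector - column_means) %*% scores_coef; for rows
#' used in the fit this reproduces the stored standardised scores. The
#' first two components are reported as the (x, y) map coordinates.
#'
#' @param model a [fit_pca()] model.
#' @param vectors named list of RSCU vectors, or a numeric matrix with
#'   matching columns.
#' @param kind entity kind recorded per point (`"host_gene"`,
#'   `"virus_species"` or `"centroid"`; recycled).
#' @return data.frame: `entity_id`, `kind`, `pc1`, `pc2`.
#' @export
project_points <- function(model, vectors, kind = "host_gene") {
  stopifnot(inherits(model, "pca_model"))
  cols <- names(model$column_means)
  m <- if (is.matrix(vectors)) {
    vectors[, cols, drop = FALSE]
  } else if (is.numeric(vectors)) {
    matrix(vectors[cols], nrow = 1L,
           dimnames = list("point", cols))
  } else {
    do.call(rbind, lapply(vectors, function(v) as.numeric(v[cols])))
  }
  if (is.null(rownames(m))) rownames(m) <- names(vectors)
  s <- sweep(m, 2L, model$column_means) %*% model$scores_coef
  data.frame(entity_id = rownames(m),
             kind = rep_len(kind, nrow(m)),
             pc1 = s[, 1L], pc2 = s[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count points per quadrant of the component map
#'
#' Points on an axis are assigned by the closed rule x >= 0 -> right,
#' y >= 0 -> upper, so the four counts always sum to the number of points.
#'
#' @param points data.frame with `pc1`, `pc2` columns.
#' @return named integer vector `UL`, `LL`, `UR`, `LR`.
#' @export
quadrant_counts <- function(points) {
  right <- points$pc1 >= 0
  upper <- points$pc2 >= 0
  c(UL = sum(!right & upper), LL = sum(!right & !upper),
    UR = sum(right & upper), LR = sum(right & !upper))
}
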