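# Hypergeometric overrepresentation of annotation terms in selected gene
# sets, and the simple regression / correlation summaries.

#' Build a flat annotation map
#'
#' Flat gene -> term assignments (no ontology structure); every annotated
#' gene must belong to the background universe.
#'
#' @param pairs data.frame with columns `gene_id`, `term_id`, one
#'   annotation pair per row.
#' @param background character vector of background gene ids; defaults to
#'   all genes seen in `pairs`.
#' @return object of class `annotation_map` with elements `pairs` and
#'   `background`.
#' @export
annotation_map <- function(pairs, background = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(pairs)))
  pairs <- unique(pairs[, c("gene_id", "term_id")])
  if (is.null(background)) background <- unique(pairs$gene_id)
  stray <- setdiff(pairs$gene_id, background)
  if (length(stray) > 0L) {
    stop("annotated gene(s) outside the background: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(pairs = pairs, background = unique(background)),
            class = "annotation_map")
}

#' Read a two-column annotation TSV (gene_id, term_id)
#'
#' @param path TSV path; a header line is expected.
#' @param background optional explicit background gene list; defaults to
#'   all genes in the file.
#' @export
read_annotation_map <- function(path, background = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("gene_id", "term_id")
  annotation_map(tab, background = background)
}

#' Hypergeometric upper-tail overrepresentation probability
#'
#' P(X >= k) for X hypergeometric: the probability of seeing at least k
#' annotated genes in a selection of n from a background of N containing K
#' annotated genes.
#'
#' @param k annotated genes in the selection.
#' @param n selection size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return the tail probability in `[0, 1]`.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N)) {
    stop("invalid hypergeometric bounds: k=", k, " n=", n, " K=", K,
         " N=", N, call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term overrepresentation in a selected gene set
#'
#' One hypergeometric upper-tail test per term present in the background
#' (terms with no background annotation are skipped). P-values are
#' corrected over the number of tested terms (Bonferroni by default, the
#' conservative classic; Benjamini-Hochberg via `correction = "BH"`) and
#' flagged significant at `p_adj <= alpha`.
#'
#' @param selected character vector of selected gene ids (must lie in the
#'   background).
#' @param annotations an [annotation_map()].
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.01).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return data.frame sorted by `p_adj`: `term_id`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
enrich_terms <- function(selected, annotations, alpha = 0.01,
                         correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  stopifnot(inherits(annotations, "annotation_map"))
  selected <- unique(selected)
  stray <- setdiff(selected, annotations$background)
  if (length(stray) > 0L) {
    stop("selected gene(s) outside the background: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  pairs <- annotations$pairs
  N <- length(annotations$background)
  n <- length(selected)
  K_tab <- table(pairs$term_id)
  in_sel <- pairs[pairs$gene_id %in% selected, , drop = FALSE]
  k_tab <- table(factor(in_sel$term_id, levels = names(K_tab)))
  terms <- names(K_tab)
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p_raw <- vapply(seq_along(terms),
                  function(i) hypergeometric_test(k[i], n, K[i], N),
                  numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = correction)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple linear fit with Pearson correlation
#'
#' Ordinary least squares y ~ x plus the Pearson correlation coefficient
#' with its two-sided p-value from the t distribution on n - 2 degrees of
#' freedom. For a simple linear fit r_squared equals pcc squared.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs, non-zero variance
#'   in x).
#' @return list: `slope`, `intercept`, `r_squared`, `pcc`, `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired points", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
  if (stats::var(y) == 0) {
    pcc <- 0; p <- 1
  } else {
    ct <- stats::cor.test(x, y)
    pcc <- unname(ct$estimate)
    p <- ct$p.value
  }
  list(slope = unname(fit$coefficients["x"]),
       intercept = unname(fit$coefficients["intercept"]),
       r_squared = pcc^2, pcc = pcc, p_value = p, n = length(x))
}
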