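# Independent brute-force oracles. The genetic code comes from seqinr
# (a different source than the implementation) and every computation is a
# plain loop over codons, so these share no code path with the package.

oracle_aa <- local({
  cache <- new.env()
  function(codon) {
    if (is.null(cache[[codon]])) {
      cache[[codon]] <- seqinr::translate(seqinr::s2c(codon))
    }
    cache[[codon]]
  }
})

oracle_codons <- function(sequence) {
  n <- nchar(sequence)
  substring(sequence, seq(1, n - 2, by = 3), seq(3, n, by = 3))
}

ALL_CODONS <- apply(expand.grid(b3 = c("T", "C", "A", "G"),
                                b2 = c("T", "C", "A", "G"),
                                b1 = c("T", "C", "A", "G")), 1,
                    function(r) paste0(r[["b1"]], r[["b2"]], r[["b3"]]))
ORACLE_STOPS <- Filter(function(cd) oracle_aa(cd) == "*", ALL_CODONS)
ORACLE_SENSE <- setdiff(ALL_CODONS, ORACLE_STOPS)
ORACLE_RSCU59 <- setdiff(ORACLE_SENSE, c("ATG", "TGG"))

# RSCU by definition: X_i / ((1/n) * sum over the synonymous family)
oracle_rscu <- function(sequence) {
  codons <- oracle_codons(sequence)
  out <- stats::setNames(numeric(length(ORACLE_RSCU59)), ORACLE_RSCU59)
  aa_of <- vapply(ORACLE_RSCU59, oracle_aa, character(1))
  for (aa in unique(aa_of)) {
    fam <- ORACLE_RSCU59[aa_of == aa]
    x <- vapply(fam, function(cd) sum(codons == cd), numeric(1))
    if (sum(x) > 0) out[fam] <- x / (sum(x) / length(fam))
  }
  out
}

# CAI: geometric mean of w over scoreable codon occurrences
oracle_cai <- function(sequence, w) {
  codons <- oracle_codons(sequence)
  codons <- codons[codons %in% ORACLE_RSCU59]
  prod(w[codons])^(1 / length(codons))
}

oracle_gc3 <- function(sequence) {
  codons <- oracle_codons(sequence)
  codons <- codons[!codons %in% ORACLE_STOPS]
  100 * mean(substring(codons, 3, 3) %in% c("G", "C"))
}

oracle_cccs <- function(sequence, cp) {
  codons <- oracle_codons(sequence)
  codons <- codons[!codons %in% ORACLE_STOPS]
  sum(cp[codons]) / length(codons)
}

# hypergeometric upper tail by direct log-binomial summation
oracle_hyper <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# random complete ORF over sense codons (uniform codon usage)
random_cds <- function(n_internal) {
  paste0("ATG",
         paste(sample(ORACLE_SENSE, n_internal, replace = TRUE),
               collapse = ""),
         "TAA")
}

# data matrix whose sample covariance is exactly S (n rows)
exact_cov_data <- function(n, S) {
  p <- ncol(S)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  W <- chol(stats::cov(X))
  Xw <- X %*% solve(W)          # sample covariance = identity
  Xw %*% chol(S)
}
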