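# Expression discretization and mutual information, used by the mRMR ranker.

#' Discretize expression per gene
#'
#' `mean_std`: three states per gene, cut at mean - alpha*sd and
#' mean + alpha*sd (the canonical mRMR default with alpha = 1).
#' `equal_frequency`: `bins` states per gene at the empirical quantiles.
#' Constant genes collapse to a single state.
#'
#' @param x cells x genes numeric matrix.
#' @param method `"mean_std"` or `"equal_frequency"`.
#' @param alpha cut width in standard deviations (mean_std).
#' @param bins number of states (equal_frequency).
#' @return integer matrix of the same shape with states `1..k`.
#' @keywords internal
discretize_expression <- function(x, method = c("mean_std", "equal_frequency"),
                                  alpha = 1, bins = 3) {
  method <- match.arg(method)
  if (method == "mean_std") {
    m <- colMeans(x)
    s <- sqrt(pmax(0, colMeans(x^2) - m^2))
    lo <- rep(m - alpha * s, each = nrow(x))
    hi <- rep(m + alpha * s, each = nrow(x))
    out <- 1L + (x > lo) + (x > hi)
  } else {
    out <- apply(x, 2, function(col) {
      qs <- unique(stats::quantile(col, probs = seq_len(bins - 1) / bins,
                                   names = FALSE, type = 7))
      findInterval(col, qs, left.open = TRUE) + 1L
    })
  }
  storage.mode(out) <- "integer"
  out
}

# n x (k*p) sparse one-hot encoding of a discretized matrix (k states).
one_hot_states <- function(disc, k) {
  n <- nrow(disc); p <- ncol(disc)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), p),
    j = as.vector(disc) + k * rep(seq_len(p) - 1L, each = n),
    x = 1,
    dims = c(n, k * p)
  )
}

# Mutual information (nats) of every gene with a grouping, from the joint
# count matrix K (groups x k*p). Returns a numeric vector over genes.
mi_from_joint <- function(K, k) {
  K <- as.matrix(K)
  n <- sum(K[, seq_len(k)])
  p <- ncol(K) / k
  P <- array(K / n, dim = c(nrow(K), k, p))
  row_marg <- rowSums(P[, , 1, drop = FALSE])            # group marginal, same for all genes
  col_marg <- apply(P, c(2, 3), sum)                     # k x p state marginals
  mi <- numeric(p)
  for (g in seq_len(nrow(K))) {
    Pg <- matrix(P[g, , ], nrow = k)                     # k x p
    E <- row_marg[g] * col_marg
    term <- Pg * log(Pg / E)
    term[Pg == 0] <- 0
    mi <- mi + colSums(term)
  }
  pmax(0, mi)
}
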