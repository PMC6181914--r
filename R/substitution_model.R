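#' Amino-acid substitution model
#'
#' Builds a reversible 20-state amino-acid substitution model from an
#' exchangeability matrix and equilibrium frequencies. The rate matrix is
#' normalized so that the expected number of substitutions per site per unit
#' time equals one. Two parameterizations are packaged: the LG replacement
#' model (exchangeabilities and frequencies taken from \pkg{phangorn}) and a
#' Poisson model (uniform exchangeabilities and frequencies).
#'
#' @param name `"LG"` (default) or `"Poisson"`.
#' @return An object of class `cpa_model`: a list with elements `name`,
#'   `freq` (named equilibrium frequencies, summing to 1), `Q` (normalized
#'   20x20 rate matrix, rows sum to 0), and an eigendecomposition used to
#'   compute transition probabilities.
#' @examples
#' m <- cpa_model("LG")
#' rowSums(m$Q)            # ~0
#' sum(m$freq)             # 1
#' @export
cpa_model <- function(name = c("LG", "Poisson")) {
  name <- match.arg(name)
  if (name == "LG") {
    lg <- get(".LG", environment(phangorn::pml))
    ex <- matrix(0, 20, 20)
    ex[lower.tri(ex)] <- lg$Q
    ex <- ex + t(ex)
    freq <- as.numeric(lg$bf)
  } else {
    ex <- matrix(1, 20, 20)
    diag(ex) <- 0
    freq <- rep(1 / 20, 20)
  }
  names(freq) <- AA_ORDER
  dimnames(ex) <- list(AA_ORDER, AA_ORDER)
  Q <- ex %*% diag(freq)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # normalize to one expected substitution per site per unit branch length
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  # symmetric similarity transform for a numerically stable eigendecomposition
  d <- sqrt(freq)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    name = name,
    freq = freq,
    Q = Q,
    eigen = list(
      values = eig$values,
      U = diag(1 / d) %*% eig$vectors,     # right eigenvectors of Q
      Uinv = t(eig$vectors) %*% diag(d)
    )
  ), class = "cpa_model")
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Qt)` for a `cpa_model`, the probability of observing
#' amino acid j after evolutionary time (branch length) `t` given amino acid
#' i, in expected substitutions per site.
#'
#' @param model A [cpa_model()].
#' @param t Branch length (non-negative scalar).
#' @return A 20x20 stochastic matrix with rows summing to 1.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "cpa_model"), is.numeric(t), length(t) == 1L, t >= 0)
  e <- model$eigen
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  # clip tiny negative round-off and renormalize rows
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' @export
print.cpa_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("  states:", paste(AA_ORDER, collapse = ""), "\n")
  cat("  expected rate at equilibrium: ",
      format(-sum(x$freq * diag(x$Q)), digits = 6), "\n", sep = "")
  invisible(x)
}
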