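# Jones-Taylor-Thornton (1992) empirical amino-acid substitution model.
#
# Exchangeabilities of the symmetric 20x20 table, stored as the
# column-major lower triangle (the order lower.tri() assignment uses) in
# amino-acid order A R N D C Q E G H I L K M F P S T W Y V. Values and
# equilibrium frequencies are the reference ones distributed in PAML's
# jones.dat and reproduced unchanged by the major phylogenetics packages.
JTT_EXCH_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101,
  64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15,
  503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59,
  38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26,
  12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
  33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24,
  180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17,
  92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112,
  71, 25, 16
)

JTT_FREQS <- c(
  A = 0.076748, R = 0.051691, N = 0.042645, D = 0.051544, C = 0.019803,
  Q = 0.040752, E = 0.061830, G = 0.073152, H = 0.022944, I = 0.053761,
  L = 0.091904, K = 0.058676, M = 0.023826, F = 0.040126, P = 0.050901,
  S = 0.068765, T = 0.058565, W = 0.014261, Y = 0.032102, V = 0.066005
)

#' The JTT amino-acid substitution model
#'
#' Builds the Jones-Taylor-Thornton empirical model as a normalized
#' reversible rate matrix: `Q[i,j] = s[i,j] * pi[j]` off the diagonal,
#' diagonal set so rows sum to zero, and the whole matrix scaled so the
#' expected number of substitutions per site per unit time is 1
#' (`-sum(pi * diag(Q)) == 1`). The eigendecomposition of the
#' pi-symmetrized form is precomputed so transition probability matrices
#' `P(t) = expm(Q t)` are cheap to evaluate.
#'
#' @return An object of class `substitution_model` with elements
#'   `alphabet`, `pi`, `Q`, and the eigendecomposition used by
#'   [prob_matrix()].
#' @export
jtt_model <- function() {
  n <- 20L
  S <- matrix(0, n, n, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- JTT_EXCH_LOWER
  S <- S + t(S)
  pi <- JTT_FREQS / sum(JTT_FREQS)
  Q <- S * rep(pi, each = n)          # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrize: B = D^{1/2} Q D^{-1/2} is symmetric under detailed balance
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2                 # remove round-off asymmetry
  eig <- eigen(B, symmetric = TRUE)
  structure(list(alphabet = AA20, pi = pi, Q = Q,
                 values = eig$values,
                 vectors_left = eig$vectors * (1 / sq),      # D^{-1/2} V
                 vectors_right = t(eig$vectors * sq)),       # V' D^{1/2}
            class = "substitution_model")
}

#' Transition probability matrix P(t)
#'
#' @param model a [jtt_model()].
#' @param t branch length in expected substitutions per site (`t >= 0`).
#' @return 20x20 matrix with `P[a, b] = Pr(b at time t | a at time 0)`.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  P <- model$vectors_left %*% (exp(model$values * t) * model$vectors_right)
  # exact stochasticity can be perturbed at the 1e-16 level by the
  # eigendecomposition; clamp tiny negatives so sampling never sees them
  P[P < 0] <- 0
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}
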