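# Amino-acid substitution model: exchangeabilities + stationary frequencies
# -> reversible rate matrix Q with the usual mean-rate-1 normalization, plus
# discrete-gamma rate categories and transition probabilities.

#' Build a reversible substitution rate model
#'
#' Assembles `Q[i,j] = s[i,j] * freq[j]` from a symmetric exchangeability
#' matrix `s` and stationary frequencies, sets the diagonal so rows sum to
#' zero, and rescales so the expected substitution rate at stationarity,
#' `-sum(freq * diag(Q))`, is exactly 1 (branch lengths are then expected
#' substitutions per site).
#'
#' @param exchangeabilities Symmetric non-negative matrix with zero
#'   diagonal (S x S).
#' @param frequencies Length-S vector summing to 1.
#' @param alphabet Character vector of state labels (length S). Defaults
#'   to the 20 amino acids in PAML order.
#' @param name Model name.
#' @return A `rate_model`: list with `alphabet`, `S`, `exch`, `freq`, `Q`
#'   and a cached symmetric eigendecomposition used by
#'   [transition_matrix()].
#' @examples
#' m <- rate_model(matrix(c(0, 1, 1, 0), 2), c(0.5, 0.5), c("0", "1"))
#' m$Q
#' @export
rate_model <- function(exchangeabilities, frequencies,
                       alphabet = AA_ALPHABET, name = "custom") {
  s <- as.matrix(exchangeabilities)
  S <- length(alphabet)
  if (!all(dim(s) == S)) stop("exchangeability matrix must be S x S")
  if (max(abs(s - t(s))) > 1e-10) stop("exchangeabilities must be symmetric")
  if (any(s < 0)) stop("exchangeabilities must be non-negative")
  freq <- as.numeric(frequencies)
  if (length(freq) != S) stop("frequencies must have length S")
  if (any(freq <= 0)) stop("frequencies must be positive")
  if (abs(sum(freq) - 1) > 1e-8) stop("frequencies must sum to 1")
  freq <- freq / sum(freq)
  diag(s) <- 0
  Q <- s * rep(freq, each = S)   # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  if (mu <= 0) stop("degenerate model: zero overall rate")
  Q <- Q / mu
  # detailed balance makes D^(1/2) Q D^(-1/2) symmetric -> stable eigen
  sq <- sqrt(freq)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(alphabet = alphabet, S = S, exch = s, freq = freq, Q = Q,
                 name = name,
                 eig = list(values = eig$values,
                            U = eig$vectors / sq,        # row-scaled
                            Uinv = t(eig$vectors) * rep(sq, each = S))),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Reversible substitution model '%s' over %d states\n",
              x$name, x$S))
  cat(sprintf("  mean rate at stationarity: %.6f\n",
              -sum(x$freq * diag(x$Q))))
  invisible(x)
}

#' Read model constants in PAML text dialect
#'
#' Parses a whitespace-delimited file holding the strict lower triangle of
#' the exchangeability matrix (rows 2..S) followed by a line of S
#' stationary frequencies. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param alphabet State labels in file order.
#' @return List with `exchangeabilities` (symmetric S x S) and
#'   `frequencies`.
#' @export
read_paml_matrix <- function(path, alphabet = AA_ALPHABET) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  vals <- as.numeric(unlist(strsplit(trimws(paste(lines, collapse = " ")),
                                     "\\s+")))
  S <- length(alphabet)
  need <- S * (S - 1) / 2 + S
  if (length(vals) != need)
    stop(sprintf("expected %d numbers (lower triangle + frequencies), got %d",
                 need, length(vals)))
  ex <- matrix(0, S, S)
  k <- 1
  for (i in 2:S) {
    ex[i, 1:(i - 1)] <- vals[k:(k + i - 2)]
    k <- k + i - 1
  }
  ex <- ex + t(ex)
  list(exchangeabilities = ex, frequencies = vals[(need - S + 1):need])
}

.model_cache <- new.env(parent = emptyenv())

#' The LG amino-acid model
#'
#' The empirical LG replacement model (Le & Gascuel 2008), read from the
#' constants file shipped with the package. Model frequencies are used
#' as-is (no `+F` re-estimation from the data).
#'
#' @return A `rate_model`.
#' @export
lg_model <- function() {
  if (is.null(.model_cache$LG)) {
    path <- system.file("extdata", "lg_model.txt", package = "rarphylo",
                        mustWork = TRUE)
    cons <- read_paml_matrix(path)
    .model_cache$LG <- rate_model(cons$exchangeabilities, cons$frequencies,
                                  name = "LG")
  }
  .model_cache$LG
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of the mean-1 gamma distribution with
#' shape `alpha`; each category rate is the conditional mean within its
#' bin (mean-of-bin convention), rescaled so the weighted mean is exactly
#' 1.
#'
#' @param alpha Gamma shape (> 0). Small `alpha` = strong rate
#'   heterogeneity across sites; large `alpha` approaches rate homogeneity.
#' @param k Number of categories (>= 1).
#' @return A `gamma_rates`: list with `alpha`, `k`, `rates` (nondecreasing)
#'   and uniform `weights`.
#' @examples
#' discrete_gamma(0.5, 4)$rates
#' @export
discrete_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k == 1L) {
    rates <- 1
  } else {
    # E[X | q_{i} < X <= q_{i+1}] for X ~ Gamma(alpha, rate alpha) equals
    # k * (P(alpha+1, q_{i+1}) - P(alpha+1, q_i)) by the gamma identity.
    qb <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
    pb <- pgamma(qb, shape = alpha + 1, rate = alpha)
    rates <- k * diff(pb)
    rates <- rates / mean(rates)
  }
  structure(list(alpha = alpha, k = k, rates = rates,
                 weights = rep(1 / k, k)),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat(sprintf("Discrete gamma: alpha = %.4g, %d categories\n", x$alpha, x$k))
  cat("  rates:", paste(sprintf("%.4f", x$rates), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix P(t * r)
#'
#' `expm(Q * t * r)` via the cached symmetric eigendecomposition of the
#' reversible `Q`.
#'
#' @param model A [rate_model()].
#' @param t Branch length (>= 0, expected substitutions per site).
#' @param r Rate multiplier (>= 0), e.g. a discrete-gamma category rate.
#' @return S x S row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, r = 1) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  if (!is.finite(r) || r < 0) stop("rate multiplier r must be finite and >= 0")
  tau <- t * r
  if (tau == 0) return(diag(model$S))   # exact: impossible sites stay 0
  e <- model$eig
  P <- e$U %*% (exp(e$values * tau) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
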