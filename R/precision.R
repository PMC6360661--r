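#' Precision matrices for the separable spatio-temporal field
#'
#' The latent field S over counties k = 1..K and years t = 1..T has a
#' separable Gaussian Markov random field prior: a proper conditionally
#' autoregressive (CAR) structure in space times a stationary first-order
#' autoregressive (AR(1)) structure in time,
#' \deqn{Q_S = \sigma^{-2}_S \, (Q_{time}(\phi) \otimes Q_{space}(\rho)),}
#' with `Q_space = D - rho * W` (D the diagonal degree matrix, W the binary
#' adjacency) and `Q_time` the usual AR(1) tridiagonal precision with unit
#' innovation variance. Cells are ordered county-fastest: cell index
#' `(t - 1) * K + k`.
#'
#' @param graph a [u5m_graph].
#' @param rho_s spatial dependence in [0, 1).
#' @param phi_t temporal AR(1) coefficient in (-1, 1).
#' @param n_years number of years T >= 1.
#' @param sigma2_S marginal scale of the field (> 0).
#' @return `car_precision()` and `ar1_precision()` return dense base
#'   matrices; `build_precision()` returns a sparse symmetric
#'   [Matrix::Matrix] of dimension `K * T`.
#' @export
car_precision <- function(graph, rho_s) {
  stopifnot(inherits(graph, "u5m_graph"))
  if (!is.numeric(rho_s) || length(rho_s) != 1L || rho_s < 0 || rho_s >= 1)
    stop("rho_s must lie in [0, 1)")
  k <- length(graph$nodes)
  if (k == 1L) return(matrix(1, 1, 1, dimnames = list(graph$nodes, graph$nodes)))
  W <- adjacency_matrix(graph)
  d <- rowSums(W)
  if (any(d == 0)) stop("isolated node(s) in adjacency graph: ",
                        paste(graph$nodes[d == 0], collapse = ", "))
  diag(d) - rho_s * W
}

#' @rdname car_precision
#' @export
ar1_precision <- function(n_years, phi_t) {
  if (!is_count(n_years)) stop("n_years must be a positive integer")
  if (!is.numeric(phi_t) || length(phi_t) != 1L || abs(phi_t) >= 1)
    stop("phi_t must lie in (-1, 1)")
  if (n_years == 1L) return(matrix(1, 1, 1))
  Q <- diag(c(1, rep(1 + phi_t^2, n_years - 2L), 1))
  for (t in seq_len(n_years - 1L)) {
    Q[t, t + 1L] <- -phi_t
    Q[t + 1L, t] <- -phi_t
  }
  Q
}

#' @rdname car_precision
#' @export
build_precision <- function(graph, rho_s, phi_t, n_years, sigma2_S = 1) {
  if (!is.numeric(sigma2_S) || sigma2_S <= 0) stop("sigma2_S must be positive")
  Qs <- car_precision(graph, rho_s)
  Qt <- ar1_precision(n_years, phi_t)
  Matrix::Matrix(kronecker(Qt, Qs) / sigma2_S, sparse = TRUE)
}
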