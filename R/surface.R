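#' Sample a true spatio-temporal mortality surface
#'
#' Draws the latent logit-scale deviations S (a K x T matrix) from the
#' zero-mean separable CAR x AR(1) Gaussian field with scale `sigma2_S`,
#' then maps to true under-five mortality probabilities
#' `Q = invlogit(alpha + S)`. This is exactly the prior of the smoothing
#' model, so generator output can be used for well-specified recovery
#' studies.
#'
#' @param config a [sim_config].
#' @param graph a [u5m_graph]; must match `config$graph` in node count.
#' @param seed optional seed overriding `config$seed`.
#' @return an object of class `u5m_surface`: list with `S` and `Q`
#'   (K x T matrices, counties x years), `alpha`, `years`, `counties`.
#' @export
sample_true_surface <- function(config, graph = config$graph, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(graph, "u5m_graph"))
  if (length(graph$nodes) != config$K)
    stop("graph node count does not match config K")
  K <- config$K
  years <- seq.int(config$year_range[1L], config$year_range[2L])
  Tn <- length(years)
  if (config$sigma2_S == 0) {
    S <- matrix(0, K, Tn)
  } else {
    P0 <- kronecker(ar1_precision(Tn, config$phi_t),
                    car_precision(graph, config$rho_s))
    R <- chol(P0)  # P0 = R'R, so backsolve(R, z) ~ N(0, P0^{-1})
    z <- with_seed(if (is.null(seed)) config$seed else seed,
                   stats::rnorm(K * Tn))
    S <- matrix(backsolve(R, z) * sqrt(config$sigma2_S), K, Tn)
  }
  dimnames(S) <- list(graph$nodes, years)
  Q <- invlogit(config$alpha + S)
  structure(list(S = S, Q = Q, alpha = config$alpha, years = years,
                 counties = graph$nodes),
            class = "u5m_surface")
}

#' @export
print.u5m_surface <- function(x, ...) {
  cat("u5m_surface:", length(x$counties), "counties x", length(x$years),
      "years; U5M range",
      sprintf("%.1f-%.1f per 1000", 1000 * min(x$Q), 1000 * max(x$Q)), "\n")
  invisible(x)
}

## internal: true Q for (county id, calendar year), years clamped to the
## surface range so children born just outside it inherit the edge rates
surface_q <- function(surface, county, year) {
  yr <- pmin(pmax(year, surface$years[1L]), surface$years[length(surface$years)])
  surface$Q[cbind(match(county, surface$counties),
                  yr - surface$years[1L] + 1L)]
}
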