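#' Probabilists' Hermite polynomial
#'
#' Evaluates the probabilists' Hermite polynomial \eqn{He_n(x)} by the
#' three-term recurrence \eqn{He_{n+1}(x) = x He_n(x) - n He_{n-1}(x)},
#' with \eqn{He_0 = 1}, \eqn{He_1 = x}. These are the polynomials
#' orthogonal with respect to the weight \eqn{e^{-x^2/2}} (equivalently,
#' up to a constant, the standard normal density), as opposed to the
#' physicists' family (weight \eqn{e^{-x^2}}).
#'
#' @param x numeric vector of evaluation points (finite).
#' @param n integer polynomial order, \code{n >= 0}.
#' @return numeric vector, \code{He_n(x)} elementwise.
#' @examples
#' hermite_poly(2, 3)  # He_3(x) = x^3 - 3x -> 2
#' @export
hermite_poly <- function(x, n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer")
  if (any(!is.finite(x)))
    stop("'x' must be finite; offending index: ",
         which(!is.finite(x))[1L])
  h_prev <- rep(1, length(x))          # He_0
  if (n == 0L) return(h_prev)
  h <- x                               # He_1
  if (n >= 2L) {
    for (m in seq_len(n - 1L)) {       # He_{m+1} = x He_m - m He_{m-1}
      h_next <- x * h - m * h_prev
      h_prev <- h
      h <- h_next
    }
  }
  h
}

#' Normalization constant for Hermite basis functions
#'
#' The normalized basis functions used throughout the package are
#' \eqn{h_n(x) = He_n(x) / k_n}. Two conventions for \eqn{k_n} are
#' supported:
#' \describe{
#'   \item{\code{"simulation"}}{\eqn{k_n = (\sqrt{2\pi}\, n!)^{1/2}}:
#'     orthonormal with respect to the weight \eqn{e^{-x^2/2}}
#'     (the Gaussian kernel without its normalizing constant). This is
#'     the package default and the convention on which the synthetic
#'     validation coordinates are reported.}
#'   \item{\code{"unit"}}{\eqn{k_n = (n!)^{1/2}}: orthonormal with
#'     respect to the standard normal density
#'     \eqn{p(x) = e^{-x^2/2}/\sqrt{2\pi}}, i.e.
#'     \eqn{\int h_i h_j\, p\, dx = \delta_{ij}}.}
#' }
#' The two differ by the constant factor \eqn{(2\pi)^{1/4}} for every
#' order; which one is in force is recorded in every fitted object.
#'
#' @param n integer vector of orders, each \code{>= 0}.
#' @param convention \code{"simulation"} or \code{"unit"}.
#' @return positive numeric vector \code{k_n}.
#' @examples
#' hermite_norm_const(0, "simulation")  # (2*pi)^(1/4)
#' hermite_norm_const(2, "unit")        # sqrt(2)
#' @export
hermite_norm_const <- function(n, convention = c("simulation", "unit")) {
  convention <- match.arg(convention)
  if (any(is.na(n)) || any(n < 0) || any(n != round(n)))
    stop("'n' must contain non-negative integers")
  if (convention == "simulation") sqrt(sqrt(2 * pi) * factorial(n))
  else sqrt(factorial(n))
}

#' Basis specification for functional coordinates
#'
#' Bundles the truncation order and normalization convention of the
#' Hermite system \eqn{h_0, \ldots, h_{K-1}}.
#'
#' @param order integer \code{K >= 1}: the number of basis functions
#'   (polynomial orders \code{0..K-1}). Default 5.
#' @param convention normalization convention, see
#'   \code{\link{hermite_norm_const}}.
#' @return an object of class \code{"basis_spec"}.
#' @export
basis_spec <- function(order = 5L, convention = c("simulation", "unit")) {
  convention <- match.arg(convention)
  if (length(order) != 1L || is.na(order) || order < 1 || order != round(order))
    stop("'order' must be a single integer >= 1")
  structure(list(order = as.integer(order), convention = convention),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("Hermite basis: orders 0..%d, convention '%s'\n",
              x$order - 1L, x$convention))
  invisible(x)
}

#' Evaluate the normalized Hermite basis on a sample
#'
#' Builds the \eqn{T \times K} matrix with entries
#' \eqn{h_j(x_t) = He_j(x_t)/k_j}, the regressor columns of the
#' per-basis coordinate estimator.
#'
#' @param x numeric vector of \code{T >= 1} finite sample points.
#' @param spec a \code{\link{basis_spec}}, or an integer taken as the
#'   truncation order with the default convention.
#' @param convention used only when \code{spec} is given as an integer.
#' @return a \code{T x K} numeric matrix with the spec attached as
#'   attribute \code{"spec"}; column \code{j} holds order \code{j - 1}.
#' @examples
#' hermite_basis(c(0, 1), basis_spec(3, "unit"))
#' @export
hermite_basis <- function(x, spec = basis_spec(),
                          convention = c("simulation", "unit")) {
  if (is.numeric(spec))
    spec <- basis_spec(spec, match.arg(convention))
  if (!inherits(spec, "basis_spec")) stop("'spec' must be a basis_spec")
  if (length(x) < 1L) stop("'x' must have length >= 1")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite values in 'x' at index ", bad[1L])
  K <- spec$order
  k <- hermite_norm_const(0:(K - 1L), spec$convention)
  B <- vapply(0:(K - 1L), function(j) hermite_poly(x, j) / k[j + 1L],
              numeric(length(x)))
  B <- matrix(B, nrow = length(x), ncol = K,
              dimnames = list(NULL, paste0("h", 0:(K - 1L))))
  attr(B, "spec") <- spec
  B
}

#' Weighted inner product by Gauss--Hermite quadrature
#'
#' Approximates \eqn{\int g_1(x) g_2(x) w(x)\, dx} over the real line,
#' where \eqn{w} decays like a Gaussian (the standard normal density
#' \eqn{p}, or the kernel \eqn{e^{-x^2/2}}). Nodes and weights come from
#' the physicists' Gauss--Hermite rule (via \pkg{pracma}) with the
#' change of variable \eqn{x = \sqrt{2} u}; with \code{n_nodes} nodes
#' the rule is exact for polynomial integrands of degree up to
#' \code{2 * n_nodes - 1} against either Gaussian weight.
#'
#' @param g1,g2 vectorized functions of one numeric argument.
#' @param weight the weight function; defaults to the standard normal
#'   density \code{dnorm}. Use
#'   \code{function(x) exp(-x^2 / 2)} for the \code{"simulation"}
#'   convention's weight.
#' @param n_nodes number of quadrature nodes (default 60).
#' @return the scalar quadrature value.
#' @examples
#' h2 <- function(x) hermite_poly(x, 2) / hermite_norm_const(2, "unit")
#' inner_product(h2, h2)  # ~1
#' @export
inner_product <- function(g1, g2, weight = stats::dnorm, n_nodes = 60L) {
  gh <- pracma::gaussHermite(n_nodes)
  x <- sqrt(2) * gh$x
  # \int f(x) e^{-x^2/2} dx = sqrt(2) * sum w_i f(sqrt(2) u_i); generic
  # weights are folded in by multiplying out the Gaussian kernel.
  integrand <- g1(x) * g2(x) * weight(x) * exp(x^2 / 2)
  val <- sqrt(2) * sum(gh$w * integrand)
  if (!is.finite(val)) stop("quadrature produced a non-finite value")
  val
}

# Normalized basis function h_n under a convention, as a closure.
hermite_fun <- function(n, convention = "simulation") {
  k <- hermite_norm_const(n, convention)
  function(x) hermite_poly(x, n) / k
}

# Weight function the convention is orthonormal against.
convention_weight <- function(convention) {
  if (convention == "unit") stats::dnorm else function(x) exp(-x^2 / 2)
}
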