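# Regularised exact penalty enforcing u in [0,1]:
#   nu(u) = H(b(u)) * b(u),  b(u) = sqrt((2u-1)^2 + eps2) - 1,
#   H(x)  = (1 + (2/pi) atan(x / eps2)) / 2.
# nu is even about u = 1/2, negative in the interior well for eps2 < 1, and
# grows once u leaves [0,1], so adding alpha * nu(u) to the functional keeps
# the unconstrained minimiser close to the box.

#' Regularised exact penalty and its derivative
#'
#' Evaluates the penalty nu(u) that replaces the box constraint u in \[0,1\]
#' in the unconstrained formulation, together with its derivative nu'(u)
#' (exact chain rule). Both are vectorised.
#'
#' @param u numeric vector/matrix of label values.
#' @param eps2 positive smoothing parameter (default 0.1).
#' @return list with elements `nu` and `nu_prime`, shaped like `u`.
#' @export
penalty_value_and_derivative <- function(u, eps2 = 0.1) {
  if (eps2 <= 0) stop("'eps2' must be positive")
  t <- 2 * u - 1
  s <- sqrt(t^2 + eps2)
  b <- s - 1
  H <- 0.5 * (1 + (2 / pi) * atan(b / eps2))
  Hp <- (1 / (pi * eps2)) / (1 + (b / eps2)^2)
  bp <- 2 * t / s
  list(nu = H * b, nu_prime = (Hp * b + H) * bp)
}

.nu_prime <- function(u, eps2) penalty_value_and_derivative(u, eps2)$nu_prime

.nu_value <- function(u, eps2) penalty_value_and_derivative(u, eps2)$nu

# second derivative of nu, used for the Taylor coefficient
.nu_second <- function(u, eps2) {
  t <- 2 * u - 1
  s <- sqrt(t^2 + eps2)
  b <- s - 1
  H <- 0.5 * (1 + (2 / pi) * atan(b / eps2))
  Hp <- (1 / (pi * eps2)) / (1 + (b / eps2)^2)
  Hpp <- -(2 * b / (pi * eps2^3)) / (1 + (b / eps2)^2)^2
  bp <- 2 * t / s
  bpp <- 4 * eps2 / s^3
  (Hpp * b + 2 * Hp) * bp^2 + (Hp * b + H) * bpp
}

#' Linear Taylor coefficient of the penalty derivative
#'
#' The coefficient of the linear term in the Taylor expansion of nu'(u)
#' about u = 0, i.e. nu''(0). By the even symmetry of nu about u = 1/2 the
#' expansion about u = 1 has the same linear coefficient; this single scalar
#' drives the damping term of the modified AOS step.
#'
#' @param eps2 positive smoothing parameter.
#' @return positive scalar.
#' @export
taylor_b_coefficient <- function(eps2 = 0.1) {
  if (eps2 <= 0) stop("'eps2' must be positive")
  .nu_second(0, eps2)
}

#' Penalty-activation field
#'
#' Returns `b_coeff` at pixels whose label lies in the activation band
#' I_zeta = \[-zeta, zeta\] U \[1 - zeta, 1 + zeta\] (near the constraint
#' boundaries, where the penalty curvature matters) and 0 elsewhere.
#'
#' @param u numeric matrix of label values.
#' @param zeta positive half-width of the activation band.
#' @param b_coeff scalar from [taylor_b_coefficient()].
#' @return numeric matrix shaped like `u`.
#' @export
b_tilde_mask <- function(u, zeta, b_coeff) {
  if (zeta <= 0) stop("'zeta' must be positive")
  act <- (u >= -zeta & u <= zeta) | (u >= 1 - zeta & u <= 1 + zeta)
  out <- matrix(0, nrow(u), ncol(u))
  out[act] <- b_coeff
  out
}
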