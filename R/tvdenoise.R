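#' Exact 1-D fused-lasso (total-variation) denoising
#'
#' Solves
#' \deqn{\min_\beta \; \tfrac12 \sum_i (y_i - \beta_i)^2 +
#'   \lambda \sum_i |\beta_{i+1} - \beta_i|}
#' exactly with the direct non-iterative taut-string style algorithm of
#' Condat (2013). The solution is piecewise constant; maximal runs of equal
#' fitted values are the read-depth segments used downstream.
#'
#' @param y Numeric vector (the signal, e.g. GC-corrected bin depths).
#' @param lambda Non-negative fusion penalty. `lambda = 0` returns `y`
#'   unchanged; `lambda -> Inf` returns the global mean everywhere.
#' @return Numeric vector of fitted values, same length as `y`.
#' @examples
#' tv_denoise(c(1, 1, 5, 5), lambda = 0)     # identity
#' tv_denoise(c(1, 1, 5, 5), lambda = 1e6)   # all equal to the mean, 3
#' @export
tv_denoise <- function(y, lambda) {
  if (!is.numeric(y)) stop("'y' must be numeric", call. = FALSE)
  stopifnot_scalar_number(lambda, "lambda")
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  n <- length(y)
  if (n <= 1L || lambda == 0) return(as.numeric(y))
  y <- as.numeric(y)
  x <- numeric(n)

  # state of the running tube: [vmin, vmax] candidate segment values,
  # umin/umax accumulated slack, k0 start of the unresolved stretch
  k <- 1L; k0 <- 1L; kminus <- 1L; kplus <- 1L
  umin <- lambda; umax <- -lambda
  vmin <- y[1L] - lambda; vmax <- y[1L] + lambda

  repeat {
    while (k == n) {
      if (umin < 0) {
        x[k0:kminus] <- vmin
        k0 <- kminus + 1L
        k <- k0; kminus <- k0
        vmin <- y[k0]
        umin <- lambda
        umax <- vmin + umin - vmax
      } else if (umax > 0) {
        x[k0:kplus] <- vmax
        k0 <- kplus + 1L
        k <- k0; kplus <- k0
        vmax <- y[k0]
        umax <- -lambda
        umin <- vmax + umax - vmin
      } else {
        x[k0:k] <- vmin + umin / (k - k0 + 1)
        return(x)
      }
    }
    umin <- umin + y[k + 1L] - vmin
    if (umin < -lambda) {            # negative jump certified
      x[k0:kminus] <- vmin
      k0 <- kminus + 1L
      k <- k0; kminus <- k0; kplus <- k0
      vmin <- y[k0]
      vmax <- vmin + 2 * lambda
      umin <- lambda; umax <- -lambda
    } else {
      umax <- umax + y[k + 1L] - vmax
      if (umax > lambda) {           # positive jump certified
        x[k0:kplus] <- vmax
        k0 <- kplus + 1L
        k <- k0; kminus <- k0; kplus <- k0
        vmax <- y[k0]
        vmin <- vmax - 2 * lambda
        umin <- lambda; umax <- -lambda
      } else {
        k <- k + 1L
        if (umin >= lambda) {
          kminus <- k
          vmin <- vmin + (umin - lambda) / (kminus - k0 + 1L)
          umin <- lambda
        }
        if (umax <= -lambda) {
          kplus <- k
          vmax <- vmax + (umax + lambda) / (kplus - k0 + 1L)
          umax <- -lambda
        }
      }
    }
  }
}

#' Fused-lasso objective value
#'
#' @param y Data vector.
#' @param beta Fitted vector, same length as `y`.
#' @param lambda Fusion penalty.
#' @return The value \eqn{\frac12\sum (y_i-\beta_i)^2 + \lambda\sum|\beta_{i+1}-\beta_i|}.
#' @export
tv_objective <- function(y, beta, lambda) {
  stopifnot(length(y) == length(beta))
  0.5 * sum((y - beta)^2) + lambda * sum(abs(diff(beta)))
}
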