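# Restricted cubic spline basis (Harrell form, 3 knots).

#' Default spline knots
#'
#' Knots at the 10th, 50th and 90th percentiles of the exposure variable,
#' the placement used for the spline models in this package.
#'
#' @param x numeric data.
#' @return numeric vector of 3 knots.
#' @export
rcs_knots <- function(x) {
  k <- unname(quantile(x, c(0.10, 0.50, 0.90), na.rm = TRUE, type = 7))
  if (any(diff(k) <= 0))
    stop("degenerate knots: percentiles are not strictly increasing",
         call. = FALSE)
  k
}

#' Restricted cubic spline basis with 3 knots
#'
#' Returns the two-column Harrell basis: the linear term and one restricted
#' cubic term
#' \deqn{\frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2)
#'       + (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}.}
#' Any affine function of these columns is linear for `x <= t1` and
#' `x >= t3` (the restricted term is exactly zero below the first knot and
#' linear above the last).
#'
#' @param x numeric vector.
#' @param knots 3 strictly increasing knots; default [rcs_knots()] of `x`.
#' @return numeric matrix with columns `x` and `x_rcs1`; the knots are
#'   attached as attribute `"knots"`.
#' @export
rcs_basis <- function(x, knots = NULL) {
  if (is.null(knots)) knots <- rcs_knots(x)
  if (length(knots) != 3L || any(diff(knots) <= 0))
    stop("knots must be 3 strictly increasing values", call. = FALSE)
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  c2 <- (p3(x - t1) - p3(x - t2) * (t3 - t1) / (t3 - t2) +
           p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  out <- cbind(x = x, x_rcs1 = c2)
  attr(out, "knots") <- knots
  out
}
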