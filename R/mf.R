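#' Membership function specification
#'
#' Builds the parameter record for one fuzzy membership function. Five
#' families are supported: `triangular`, `trapezoidal`, `gaussian`,
#' `exponential_like` (rational decay \eqn{1/(1+\gamma (x-\beta)^2)}) and
#' `s_shape` (the standard smooth S-function; set `invert = TRUE` for the
#' complementary Z-shape used for "low" shoulder terms).
#'
#' Supports are closed intervals. Degenerate shoulders are allowed for
#' triangles and trapezoids (`alpha_min == beta` or `beta == alpha_max`),
#' giving left/right shoulder sets that hold membership 1 at the domain edge.
#'
#' @param family One of `"triangular"`, `"trapezoidal"`, `"gaussian"`,
#'   `"exponential_like"`, `"s_shape"`.
#' @param alpha_min,alpha_max Lower/upper support bounds (parameter units).
#' @param beta Peak (triangular), centre (gaussian, exponential_like).
#' @param beta1,beta2 Plateau start/end (trapezoidal only).
#' @param gamma Decay coefficient, > 0 (exponential_like only).
#' @param alpha_g Gaussian decay coefficient, > 0.
#' @param invert Logical; s_shape only. `TRUE` turns the monotone
#'   nondecreasing S into its nonincreasing complement.
#' @return An object of class `mf_spec`.
#' @export
#' @examples
#' mf <- mf_spec("triangular", alpha_min = 0, beta = 5, alpha_max = 10)
#' mf_eval(mf, c(0, 2.5, 5, 10))
mf_spec <- function(family = c("triangular", "trapezoidal", "gaussian",
                               "exponential_like", "s_shape"),
                    alpha_min = NA_real_, alpha_max = NA_real_,
                    beta = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                    gamma = NA_real_, alpha_g = NA_real_, invert = FALSE) {
  family <- match.arg(family)
  spec <- structure(
    list(family = family, alpha_min = alpha_min, alpha_max = alpha_max,
         beta = beta, beta1 = beta1, beta2 = beta2, gamma = gamma,
         alpha_g = alpha_g, invert = isTRUE(invert)),
    class = "mf_spec")
  validate_mf_spec(spec)
  spec
}

validate_mf_spec <- function(spec) {
  fam <- spec$family
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid mf_spec (", fam, "): ", msg, call. = FALSE)
  fin <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  switch(fam,
    triangular = {
      chk(fin(spec$alpha_min) && fin(spec$beta) && fin(spec$alpha_max),
          "alpha_min, beta, alpha_max must be finite")
      chk(spec$alpha_min <= spec$beta && spec$beta <= spec$alpha_max,
          "need alpha_min <= beta <= alpha_max")
      chk(spec$alpha_min < spec$alpha_max, "need alpha_min < alpha_max")
    },
    trapezoidal = {
      chk(fin(spec$alpha_min) && fin(spec$beta1) && fin(spec$beta2) && fin(spec$alpha_max),
          "alpha_min, beta1, beta2, alpha_max must be finite")
      chk(spec$alpha_min <= spec$beta1 && spec$beta1 <= spec$beta2 &&
            spec$beta2 <= spec$alpha_max,
          "need alpha_min <= beta1 <= beta2 <= alpha_max")
      chk(spec$alpha_min < spec$alpha_max, "need alpha_min < alpha_max")
    },
    gaussian = {
      chk(fin(spec$beta), "beta must be finite")
      chk(fin(spec$alpha_g) && spec$alpha_g > 0, "alpha_g must be > 0")
    },
    exponential_like = {
      chk(fin(spec$beta), "beta must be finite")
      chk(fin(spec$gamma) && spec$gamma > 0, "gamma must be > 0")
    },
    s_shape = {
      chk(fin(spec$alpha_min) && fin(spec$alpha_max), "alpha_min, alpha_max must be finite")
      chk(spec$alpha_min < spec$alpha_max, "need alpha_min < alpha_max")
    })
  invisible(spec)
}

check_x_finite <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("membership input x must be finite numeric", call. = FALSE)
  invisible(x)
}

# Rising/falling linear pieces with degenerate-shoulder handling. At exact
# breakpoints the larger adjacent piece wins (closed supports), which the
# pmin/pmax compositions below give for free.
.edge_up <- function(x, a, b) {
  if (b > a) (x - a) / (b - a) else ifelse(x >= a, Inf, -Inf)
}
.edge_down <- function(x, b, c) {
  if (c > b) (c - x) / (c - b) else ifelse(x <= c, Inf, -Inf)
}

#' Evaluate a triangular membership function
#'
#' Piecewise linear: 0 outside the closed support, rising linearly on
#' (`alpha_min`, `beta`), 1 at `beta`, falling linearly on (`beta`,
#' `alpha_max`).
#'
#' @param x Numeric vector of crisp input values (finite).
#' @param mf An `mf_spec` with `family = "triangular"`.
#' @return Membership degrees in \[0, 1\].
#' @export
eval_triangular <- function(x, mf) {
  stopifnot(inherits(mf, "mf_spec"), mf$family == "triangular")
  check_x_finite(x)
  pmax(0, pmin(.edge_up(x, mf$alpha_min, mf$beta),
               .edge_down(x, mf$beta, mf$alpha_max), 1))
}

#' Evaluate a trapezoidal membership function
#'
#' 0 outside the support, linear rise on (`alpha_min`, `beta1`), plateau 1 on
#' \[`beta1`, `beta2`\], linear fall on (`beta2`, `alpha_max`).
#'
#' @inheritParams eval_triangular
#' @param mf An `mf_spec` with `family = "trapezoidal"`.
#' @return Membership degrees in \[0, 1\].
#' @export
eval_trapezoidal <- function(x, mf) {
  stopifnot(inherits(mf, "mf_spec"), mf$family == "trapezoidal")
  check_x_finite(x)
  pmax(0, pmin(.edge_up(x, mf$alpha_min, mf$beta1),
               .edge_down(x, mf$beta2, mf$alpha_max), 1))
}

#' Evaluate a Gaussian membership function
#'
#' \eqn{\mu(x) = \exp(-\alpha (x-\beta)^2)}: symmetric about `beta`, equal to
#' 1 at `beta`, strictly positive everywhere.
#'
#' @inheritParams eval_triangular
#' @param mf An `mf_spec` with `family = "gaussian"`.
#' @return Membership degrees in (0, 1\].
#' @export
eval_gaussian <- function(x, mf) {
  stopifnot(inherits(mf, "mf_spec"), mf$family == "gaussian")
  if (!is.finite(mf$alpha_g) || mf$alpha_g <= 0)
    stop("gaussian mf requires alpha_g > 0", call. = FALSE)
  check_x_finite(x)
  exp(-mf$alpha_g * (x - mf$beta)^2)
}

#' Evaluate an exponential-like (rational decay) membership function
#'
#' \eqn{\mu(x) = 1/(1+\gamma (x-\beta)^2)}: equal to 1 at `beta`, strictly
#' decreasing in \eqn{|x-\beta|}, strictly positive everywhere.
#'
#' @inheritParams eval_triangular
#' @param mf An `mf_spec` with `family = "exponential_like"`.
#' @return Membership degrees in (0, 1\].
#' @export
eval_exponential_like <- function(x, mf) {
  stopifnot(inherits(mf, "mf_spec"), mf$family == "exponential_like")
  if (!is.finite(mf$gamma) || mf$gamma <= 0)
    stop("exponential_like mf requires gamma > 0", call. = FALSE)
  check_x_finite(x)
  1 / (1 + mf$gamma * (x - mf$beta)^2)
}

#' Evaluate an S-shape membership function
#'
#' The standard smooth S-function on \[`alpha_min`, `alpha_max`\]: 0 at or
#' below `alpha_min`, \eqn{2u^2} on the lower half, \eqn{1-2(1-u)^2} on the
#' upper half (with \eqn{u} the normalised position), 0.5 at the midpoint
#' inflection, and 1 at or above `alpha_max`. Monotone nondecreasing. With
#' `invert = TRUE` the complement (Z-shape) is returned.
#'
#' @inheritParams eval_triangular
#' @param mf An `mf_spec` with `family = "s_shape"`.
#' @return Membership degrees in \[0, 1\].
#' @export
eval_s_shape <- function(x, mf) {
  stopifnot(inherits(mf, "mf_spec"), mf$family == "s_shape")
  if (mf$alpha_min >= mf$alpha_max)
    stop("s_shape mf requires alpha_min < alpha_max", call. = FALSE)
  check_x_finite(x)
  a <- mf$alpha_min; c <- mf$alpha_max
  u <- (x - a) / (c - a)
  mu <- ifelse(u <= 0, 0,
        ifelse(u >= 1, 1,
        ifelse(u <= 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)))
  if (mf$invert) 1 - mu else mu
}

#' Evaluate any membership function
#'
#' Dispatches on `mf$family`.
#'
#' @param mf An `mf_spec`.
#' @param x Numeric vector of crisp values.
#' @return Membership degrees in \[0, 1\].
#' @export
mf_eval <- function(mf, x) {
  stopifnot(inherits(mf, "mf_spec"))
  switch(mf$family,
    triangular = eval_triangular(x, mf),
    trapezoidal = eval_trapezoidal(x, mf),
    gaussian = eval_gaussian(x, mf),
    exponential_like = eval_exponential_like(x, mf),
    s_shape = eval_s_shape(x, mf))
}

#' @export
print.mf_spec <- function(x, ...) {
  pars <- switch(x$family,
    triangular = sprintf("[%g, %g, %g]", x$alpha_min, x$beta, x$alpha_max),
    trapezoidal = sprintf("[%g, %g, %g, %g]", x$alpha_min, x$beta1, x$beta2, x$alpha_max),
    gaussian = sprintf("beta=%g, alpha=%g", x$beta, x$alpha_g),
    exponential_like = sprintf("beta=%g, gamma=%g", x$beta, x$gamma),
    s_shape = sprintf("[%g, %g]%s", x$alpha_min, x$alpha_max,
                      if (x$invert) " (inverted)" else ""))
  cat("<mf_spec ", x$family, " ", pars, ">\n", sep = "")
  invisible(x)
}
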