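#' Von Bertalanffy growth parameters
#'
#' Bundle the triple (L\eqn{\infty}, K, t0) that parameterizes the Von
#' Bertalanffy growth curve \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})}.
#'
#' @param l_inf Asymptotic total length (mm).
#' @param k Growth-rate coefficient (per day).
#' @param t0 Theoretical age at zero length (days); may be negative.
#'
#' @return An object of class `vb_params`: a named numeric vector with
#'   elements `l_inf`, `k`, `t0`.
#' @examples
#' p <- vb_params(30, 0.02, 0)
#' vb_length(p, c(50, 100, 350))
#' @export
vb_params <- function(l_inf, k, t0) {
  stopifnot(is.numeric(l_inf), is.numeric(k), is.numeric(t0),
            length(l_inf) == 1, length(k) == 1, length(t0) == 1)
  structure(c(l_inf = as.numeric(l_inf), k = as.numeric(k),
              t0 = as.numeric(t0)),
            class = "vb_params")
}

as_vb_params <- function(x) {
  if (inherits(x, "vb_params")) return(x)
  x <- unlist(x)
  nm <- names(x)
  if (!is.null(nm) && all(c("l_inf", "k", "t0") %in% nm)) {
    return(vb_params(x[["l_inf"]], x[["k"]], x[["t0"]]))
  }
  stopifnot(length(x) == 3)
  vb_params(x[[1]], x[[2]], x[[3]])
}

#' @export
print.vb_params <- function(x, ...) {
  cat(sprintf("Von Bertalanffy parameters: L_inf = %.4g mm, K = %.4g /day, t0 = %.4g days\n",
              x[["l_inf"]], x[["k"]], x[["t0"]]))
  invisible(x)
}

#' Length at age under Von Bertalanffy growth
#'
#' Evaluates \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})}. The value can be
#' negative for ages below `t0`; callers that need a positive size (for
#' instance to move to the log-size domain) must clamp or check, see
#' [age_to_size()].
#'
#' @param params A [vb_params()] object (or coercible named vector).
#' @param t Age in days (vectorized).
#' @return Predicted total length (mm), same length as `t`.
#' @seealso [vb_step()] for the one-day update form of the same curve.
#' @export
vb_length <- function(params, t) {
  p <- as_vb_params(params)
  p[["l_inf"]] * (1 - exp(-p[["k"]] * (t - p[["t0"]])))
}

#' One-day Von Bertalanffy size update
#'
#' Advances a length one time step (one day on the `K` time base):
#' \eqn{L_{t+1} = L_t e^{-K} + L_\infty (1 - e^{-K})}. Algebraically this is
#' the same curve as [vb_length()] advanced by one day, and the IPM growth
#' kernel uses it as the deterministic mean displacement.
#'
#' @inheritParams vb_length
#' @param l_t Current length (mm), vectorized.
#' @return Length after one day (mm).
#' @export
vb_step <- function(params, l_t) {
  p <- as_vb_params(params)
  l_t * exp(-p[["k"]]) + p[["l_inf"]] * (1 - exp(-p[["k"]]))
}

#' Log body size predicted at a given age
#'
#' Maps age to the log-size state variable of the IPM via the fitted growth
#' curve, `log(vb_length(params, age))`. Errors if the predicted length is
#' not positive (age at or below `t0`).
#'
#' @inheritParams vb_length
#' @param age Age in days (vectorized).
#' @return Natural log of predicted length, same length as `age`.
#' @export
age_to_size <- function(params, age) {
  len <- vb_length(params, age)
  if (any(len <= 0)) {
    stop("predicted length is non-positive at some ages (age too close to t0); ",
         "cannot map to log size", call. = FALSE)
  }
  log(len)
}
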