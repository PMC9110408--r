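#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis for a continuous covariate
#' (natural cubic spline: cubic between knots, constrained to be linear
#' beyond the boundary knots). With k knots the basis has k - 1 columns:
#' the identity plus k - 2 nonlinear terms
#' \deqn{B_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3\frac{t_k-t_j}{t_k-t_{k-1}}
#'   + (x-t_k)_+^3\frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2}}
#' the normalisation by the squared boundary-knot span keeping all columns
#' on the scale of x.
#'
#' @param x numeric vector (e.g. ages at diagnosis).
#' @param knots knot locations; if `NULL`, placed at standard quantiles of
#'   `x` (10/50/90th percentiles for the default 3 knots).
#' @param n_knots number of knots (>= 3) when `knots` is `NULL`.
#' @return numeric matrix with `length(knots) - 1` columns and attribute
#'   `"knots"`.
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 3) {
  if (is.null(knots)) {
    stopifnot(n_knots >= 3)
    if (length(unique(x[!is.na(x)])) < n_knots)
      stop("fewer distinct values than knots")
    probs <- default_knot_quantiles(n_knots)
    knots <- unname(stats::quantile(x, probs, type = 7, na.rm = TRUE))
  }
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3) stop("need at least 3 distinct knots; got ", k,
                  " (too few distinct values?)")
  pos3 <- function(u) pmax(u, 0)^3
  denom <- (knots[k] - knots[1])^2
  cols <- lapply(seq_len(k - 2), function(j) {
    (pos3(x - knots[j]) -
       pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
       pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
    ) / denom
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  attr(out, "knots") <- knots
  out
}

# Harrell's conventional outer quantiles by knot count.
default_knot_quantiles <- function(n_knots) {
  outer <- switch(as.character(n_knots),
                  "3" = 0.10, "4" = 0.05, "5" = 0.05, "6" = 0.05,
                  0.025)
  seq(outer, 1 - outer, length.out = n_knots)
}
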