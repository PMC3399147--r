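# Sensitivity statistics: correlation, partial correlation and PRCC,
# implemented directly from their defining covariance/residual
# construction rather than delegated to a correlation library, so the
# residual regressions (with intercept) and tie handling are explicit.

#' Pearson correlation coefficient
#'
#' `cov(x, y) / sqrt(var(x) var(y))`, computed from the defining sums.
#' Zero variance in either argument is an error, not a silent zero.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
#' @examples
#' correlation_coefficient(c(1, 2, 3), c(1, 3, 2))
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  vx <- sum(xc^2)
  vy <- sum(yc^2)
  if (vx == 0 || vy == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- sum(xc * yc) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Partial correlation coefficient
#'
#' Correlation between the residuals of `X[, j]` and of `y`, each regressed
#' (with intercept) on the remaining columns of `X`. This is the
#' residual-based construction of the partial correlation coefficient.
#'
#' @param X n x k numeric matrix of inputs.
#' @param j column index of the input of interest.
#' @param y numeric response, length n.
#' @param pseudo_inverse if `TRUE`, a rank-deficient design is handled by
#'   the minimum-norm least-squares solution instead of raising an error.
#' @return partial correlation in `[-1, 1]`.
#' @export
partial_corr <- function(X, j, y, pseudo_inverse = FALSE) {
  stopifnot(is.matrix(X), j >= 1, j <= ncol(X), length(y) == nrow(X))
  n <- nrow(X)
  if (n <= ncol(X) + 1)
    stop("need n > k + 1 observations", call. = FALSE)
  Z <- cbind(1, X[, -j, drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    if (!pseudo_inverse)
      stop("singular design in partial correlation ",
           "(set pseudo_inverse = TRUE to use the minimum-norm fit)",
           call. = FALSE)
    P <- svd_hat(Z)
    rx <- X[, j] - P %*% X[, j]
    ry <- y - P %*% y
  } else {
    rx <- qr.resid(qz, X[, j])
    ry <- qr.resid(qz, y)
  }
  correlation_coefficient(as.numeric(rx), as.numeric(ry))
}

svd_hat <- function(Z) {
  s <- svd(Z)
  keep <- s$d > max(dim(Z)) * .Machine$double.eps * s$d[1]
  u <- s$u[, keep, drop = FALSE]
  u %*% t(u)
}

#' Partial rank correlation coefficients
#'
#' Every input column and the response are replaced by their ranks
#' (average ranks for ties), then the partial correlation of each column
#' with the response is computed via the residual construction of
#' [partial_corr()]. PRCC measures monotone (not merely linear) influence
#' and is invariant under strictly increasing transforms of any variable.
#' A constant input column yields `NA` for that parameter (undefined, with
#' a warning) and the remaining parameters are still computed.
#'
#' @param X n x k matrix of inputs (or an `lhs_sample`).
#' @param y numeric response, length n.
#' @param output_name label carried into the result.
#' @return object of class `prcc_result`: list with `param_names`, `prcc`
#'   (named numeric, `NA` where undefined), `n`, `output_name`.
#' @export
#' @examples
#' X <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X[, 2]^3 + 0.01 * runif(100)
#' prcc(X, y)$prcc
prcc <- function(X, y, output_name = "") {
  if (inherits(X, "lhs_sample")) X <- X$values
  stopifnot(is.matrix(X), length(y) == nrow(X))
  k <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (stats::var(y) == 0)
    stop("undefined PRCC: response has zero variance", call. = FALSE)
  Xr <- apply(X, 2, rank)
  yr <- rank(y)
  out <- stats::setNames(rep(NA_real_, k), nm)
  if (any(const))
    warning("constant input column(s): ",
            paste(nm[const], collapse = ", "),
            "; PRCC undefined there", call. = FALSE)
  usable <- which(!const)
  Xu <- Xr[, usable, drop = FALSE]
  for (idx in seq_along(usable)) {
    out[usable[idx]] <- partial_corr(Xu, idx, yr)
  }
  structure(list(param_names = nm, prcc = out, n = nrow(X),
                 output_name = output_name),
            class = "prcc_result")
}

#' @export
print.prcc_result <- function(x, ...) {
  cat("PRCC (n =", x$n,
      if (nzchar(x$output_name)) paste0(", ", x$output_name) else "", ")\n")
  print(round(x$prcc, 3))
  invisible(x)
}

#' Rank parameters by importance
#'
#' Orders parameters by decreasing absolute PRCC. Ties in |PRCC| are broken
#' by sign (positive first) and then input order; the tie rule is cosmetic.
#'
#' @param result a [prcc()] result.
#' @return data.frame with columns `rank`, `parameter`, `prcc`
#'   (`NA` PRCCs sort last).
#' @export
rank_importance <- function(result) {
  stopifnot(inherits(result, "prcc_result"))
  v <- result$prcc
  ord <- order(-abs(v), -sign(v), seq_along(v), na.last = TRUE)
  data.frame(rank = seq_along(v), parameter = names(v)[ord],
             prcc = unname(v[ord]), row.names = NULL)
}

#' Per-grid-cell PRCC maps
#'
#' Computes the PRCC of every parameter against a per-cell scalar response
#' (typically the 2001-2100 mean FPC of one PFT) independently in each
#' cell. Cells in which the PFT never appears in any ensemble member (the
#' response is identically zero) are masked as `NA` rather than reported
#' as zero; cells with a present but constant response are likewise
#' undefined and masked.
#'
#' @param ensemble_fpc cell x sample matrix of the response.
#' @param samples an `lhs_sample` (rows aligned with the matrix columns).
#' @return matrix cell x parameter of PRCCs with `NA` where masked;
#'   attribute `masked` flags never-present cells. Warns if every cell is
#'   masked.
#' @export
prcc_map <- function(ensemble_fpc, samples) {
  X <- if (inherits(samples, "lhs_sample")) samples$values else samples
  stopifnot(is.matrix(ensemble_fpc), ncol(ensemble_fpc) == nrow(X))
  nc <- nrow(ensemble_fpc)
  out <- matrix(NA_real_, nc, ncol(X), dimnames = list(NULL, colnames(X)))
  masked <- logical(nc)
  for (i in seq_len(nc)) {
    y <- ensemble_fpc[i, ]
    if (all(y == 0)) {
      masked[i] <- TRUE
      next
    }
    if (stats::var(y) == 0) {
      masked[i] <- TRUE
      next
    }
    out[i, ] <- prcc(X, y)$prcc
  }
  if (all(masked)) warning("empty PRCC map: all cells masked", call. = FALSE)
  attr(out, "masked") <- masked
  out
}
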