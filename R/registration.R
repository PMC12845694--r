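#' Fiducial point sets
#'
#' A point set is a tibble with columns `label`, `x_mm`, `y_mm`, `z_mm` and a
#' `frame` attribute (e.g. `"ct"` or `"world"`). At least 3 non-collinear
#' points are required for registration.
#'
#' @param labels Character vector of marker labels.
#' @param xyz Numeric N x 3 matrix of coordinates \[mm\].
#' @param frame Coordinate-frame tag.
#' @return A tibble of class `point_set`.
#' @export
point_set <- function(labels, xyz, frame = "ct") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) < 1L) {
    abort("`xyz` must be an N x 3 matrix.")
  }
  if (anyDuplicated(labels)) {
    abort("duplicate point labels.")
  }
  structure(
    tibble::tibble(
      label = as.character(labels),
      x_mm = xyz[, 1L], y_mm = xyz[, 2L], z_mm = xyz[, 3L]
    ),
    frame = frame,
    class = c("point_set", class(tibble::tibble()))
  )
}

ps_matrix <- function(ps) {
  if (is.matrix(ps)) {
    return(ps)
  }
  as.matrix(ps[, c("x_mm", "y_mm", "z_mm")])
}

check_geometry <- function(X, tol = 1e-6) {
  if (nrow(X) < 3L) {
    abort("need at least 3 points.")
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  if (min(D) < 1e-9) {
    abort("coincident points in the source set.")
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[2L] < tol * sv[1L]) {
    abort("degenerate (collinear) point geometry.")
  }
}

#' Least-squares rigid registration of matched point sets (Umeyama)
#'
#' Closed-form SVD solution of the rotation `R` and translation `t`
#' minimising `sum_i || R src_i + t - dst_i ||^2` over matched
#' correspondences. Rigid by default (scale fixed to 1, both frames metric);
#' the similarity variant with an isotropic scale is available behind
#' `allow_scale`. A reflection in the SVD solution is corrected via the sign
#' of the determinant, so the returned `R` is always a proper rotation.
#'
#' @param src,dst [point_set()]s (or N x 3 matrices) with matching labels /
#'   row order; N >= 3, `src` non-collinear.
#' @param allow_scale Estimate an isotropic scale factor (default FALSE).
#' @return A list of class `rigid_transform`: `R` (3x3 rotation), `t`
#'   (length-3 translation \[mm\]), `scale`, `rmse` (post-fit fiducial RMSE
#'   \[mm\]), `n`.
#' @examples
#' src <- matrix(rnorm(15), 5, 3)
#' th <- pi / 3
#' Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
#' fit <- umeyama_rigid(src, src %*% t(Rz) + rep(1, 5) %o% c(10, -5, 2))
#' fit$rmse
#' @export
umeyama_rigid <- function(src, dst, allow_scale = FALSE) {
  X <- ps_matrix(src)
  Y <- ps_matrix(dst)
  if (nrow(X) != nrow(Y)) {
    abort("source and destination must have the same number of points.")
  }
  if (is.data.frame(src) && is.data.frame(dst)) {
    if (!identical(src$label, dst$label)) {
      if (!setequal(src$label, dst$label)) {
        abort("source and destination labels do not correspond.")
      }
      Y <- Y[match(src$label, dst$label), , drop = FALSE]
    }
  }
  check_geometry(X)

  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)  # covariance dst~src
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  Dfix <- diag(c(1, 1, d))
  R <- sv$u %*% Dfix %*% t(sv$v)
  s <- if (allow_scale) {
    sum(sv$d * c(1, 1, d)) / mean(rowSums(Xc^2))
  } else {
    1
  }
  t_vec <- unname(my - s * as.numeric(R %*% mx))
  fit <- structure(
    list(R = R, t = t_vec, scale = s, n = nrow(X)),
    class = "rigid_transform"
  )
  fit$rmse <- fiducial_rmse(fit, X, Y)
  fit
}

#' Apply a rigid transform to points
#'
#' `out_i = scale * R p_i + t`; the frame tag of a [point_set()] is flipped
#' between `"ct"` and `"world"`.
#'
#' @param transform A [umeyama_rigid()] result (or list with `R`, `t`).
#' @param pts A [point_set()] or N x 3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, pts) {
  X <- ps_matrix(pts)
  s <- transform$scale %||% 1
  Y <- s * X %*% t(transform$R) + rep(1, nrow(X)) %o% transform$t
  if (is.data.frame(pts)) {
    frame <- attr(pts, "frame") %||% "ct"
    point_set(pts$label, Y, frame = if (frame == "ct") "world" else "ct")
  } else {
    Y
  }
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return The inverse transform (`R'`, `-R' t / s`, `1/s`).
#' @export
invert_transform <- function(transform) {
  s <- transform$scale %||% 1
  structure(
    list(R = t(transform$R), t = -as.numeric(t(transform$R) %*% transform$t) / s,
         scale = 1 / s, n = transform$n),
    class = "rigid_transform"
  )
}

#' Euclidean distance between two 3-D points
#'
#' `sqrt((x1 - x2)^2 + (y1 - y2)^2 + (z1 - z2)^2)`, the alignment error
#' between a displayed (virtual) reference point and its physical reference.
#'
#' @param p,q Numeric length-3 coordinate vectors \[mm\].
#' @return Distance \[mm\].
#' @examples
#' point_error(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
point_error <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L || !all(is.finite(c(p, q)))) {
    abort("`p` and `q` must be finite length-3 coordinates.")
  }
  sqrt(sum((p - q)^2))
}

#' Post-fit fiducial RMSE of a transform over matched points
#'
#' `sqrt(mean_i || s R src_i + t - dst_i ||^2)`, a quality score for a fit.
#'
#' @param transform A `rigid_transform`.
#' @param src,dst Matched [point_set()]s or N x 3 matrices.
#' @return RMSE \[mm\].
#' @export
fiducial_rmse <- function(transform, src, dst) {
  X <- ps_matrix(src)
  Y <- ps_matrix(dst)
  if (nrow(X) != nrow(Y)) {
    abort("source and destination must have the same number of points.")
  }
  res <- apply_transform(transform, X) - Y
  sqrt(mean(rowSums(res^2)))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> n = %d points, scale = %.6g, fiducial RMSE = %.4g mm\n",
              x$n %||% NA_integer_, x$scale %||% 1, x$rmse %||% NA_real_))
  cat("R:\n")
  print(round(x$R, 6))
  cat("t: ", paste(round(x$t, 4), collapse = ", "), " mm\n")
  invisible(x)
}
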