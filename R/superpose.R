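#' Optimal rigid-body superposition (least-squares best fit)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mobile selection onto the reference selection, by the closed-form
#' SVD (Kabsch) solution with determinant correction so that reflections are
#' never returned.
#'
#' The transform maps mobile coordinates as
#' `x' = (x - centroid_mobile) %*% t(R) + centroid_reference + translation0`,
#' i.e. `rotation` is applied about the mobile centroid, which is then moved
#' onto the reference centroid.
#'
#' @param mobile coordinate matrix or `cg_structure` to be fitted.
#' @param reference coordinate matrix or `cg_structure` fitted onto.
#' @param selection backbone roles used for the fit when structures are given
#'   (default `"CA"`); ignored for bare matrices, which are used whole.
#' @return a list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom) such that
#'   `fitted = sweep(mobile, 2, cm) %*% t(R) + translation`, and `rmsd`
#'   (Angstrom, over the selection after fitting).
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  xm <- sel_coords(mobile, selection)
  xr <- sel_coords(reference, selection)
  if (nrow(xm) != nrow(xr))
    stop("selection atom counts differ: ", nrow(xm), " vs ", nrow(xr))
  if (nrow(xm) < 3L)
    stop("superposition needs at least 3 atoms")
  cm <- colMeans(xm); cr <- colMeans(xr)
  a <- sweep(xm, 2L, cm); b <- sweep(xr, 2L, cr)
  sv_a <- svd(a)$d
  if (sv_a[2L] < 1e-8 * max(sv_a[1L], 1))
    stop("degenerate (collinear) geometry: superposition ill-defined")
  h <- crossprod(a, b)                      # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps centered mobile -> ref
  fitted <- a %*% t(rot)
  rmsd_val <- sqrt(mean(rowSums((fitted - b)^2)))
  out <- list(rotation = rot, translation = cr, mobile_centroid = cm,
              rmsd = rmsd_val)
  class(out) <- "superposition"
  out
}

#' Apply a superposition transform to full coordinates
#' @param fit a `superposition` from [superpose()].
#' @param coords `n x 3` coordinate matrix (need not be the fit selection).
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(sweep(as.matrix(coords), 2L, fit$mobile_centroid) %*%
          t(fit$rotation), 2L, fit$translation, `+`)
}

sel_coords <- function(x, selection) {
  if (inherits(x, "cg_structure")) {
    x$coords[role_selection(x, selection), , drop = FALSE]
  } else as.matrix(x)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b `n x 3` coordinate matrices or `cg_structure`s with congruent
#'   selections.
#' @param fit if `TRUE` (default), superpose `a` onto `b` first (best-fit
#'   RMSD); if `FALSE`, raw deviation in the given frames.
#' @param selection backbone roles used when structures are given.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = TRUE, selection = "CA") {
  xa <- sel_coords(a, selection); xb <- sel_coords(b, selection)
  if (nrow(xa) != nrow(xb))
    stop("coordinate counts differ: ", nrow(xa), " vs ", nrow(xb))
  if (fit) return(superpose(xa, xb)$rmsd)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Gradient of the best-fit RMSD with respect to mobile coordinates
#'
#' The target selection is optimally superposed onto the mobile selection;
#' by stationarity of the optimal rotation and translation, the gradient of
#' the fitted RMSD with respect to mobile atom `i` is then
#' `(x_i - y'_i) / (N * RMSD)` for selected atoms (`y'` the fitted target)
#' and zero elsewhere. At RMSD below `eps` the gradient is defined as the
#' zero vector: the restraint force vanishes there too when the target RMSD
#' schedule has reached zero, and this avoids the non-differentiable point.
#'
#' @param mobile `n x 3` coordinate matrix (full system).
#' @param target target `cg_structure` (or coordinate matrix).
#' @param sel_idx integer indices of mobile atoms entering the RMSD; must
#'   match the target selection count.
#' @param target_sel roles selecting target atoms when `target` is a
#'   structure.
#' @param eps RMSD below which the zero-gradient convention applies.
#' @return list with `gradient` (`n x 3`, units 1/Angstrom per Angstrom
#'   displacement, i.e. dimensionless per-coordinate slope of an Angstrom
#'   quantity) and `rmsd` (Angstrom).
#' @export
rmsd_gradient <- function(mobile, target, sel_idx = NULL,
                          target_sel = "CA", eps = 1e-8) {
  mobile <- as.matrix(mobile)
  if (is.null(sel_idx)) sel_idx <- seq_len(nrow(mobile))
  xm <- mobile[sel_idx, , drop = FALSE]
  xt <- sel_coords(target, target_sel)
  if (nrow(xm) != nrow(xt))
    stop("selection atom counts differ: ", nrow(xm), " vs ", nrow(xt))
  n <- nrow(xm)
  fit <- superpose(xt, xm)              # target onto mobile
  yt <- apply_superposition(fit, xt)
  r <- sqrt(mean(rowSums((xm - yt)^2)))
  grad <- matrix(0, nrow(mobile), 3L)
  if (r > eps) grad[sel_idx, ] <- (xm - yt) / (n * r)
  list(gradient = grad, rmsd = r)
}
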