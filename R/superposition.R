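# Rigid-body superposition (Kabsch) and RMSD. Transforms use the row-vector
# convention: transformed coords = coords %*% rotation + translation.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` (paired rows). The rotation is obtained from the
#' SVD of the cross-covariance matrix, with reflections corrected through
#' the sign attached to the smallest singular value, so the result is always
#' a proper rotation (det = +1).
#'
#' @param mobile,reference R x 3 coordinate matrices, R >= 3, with matching
#'   row order.
#'
#' @return A `rigid_transform`: list with `rotation` (3 x 3, applied on the
#'   right of row vectors), `translation` (length-3) and `lrmsd`, the
#'   least RMSD (Angstrom) after applying the transform to `mobile`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions (",
         nrow(mobile), "x", ncol(mobile), " vs ",
         nrow(reference), "x", ncol(reference), ")")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m0 <- sweep(mobile, 2L, mc); r0 <- sweep(reference, 2L, rc)
  # degenerate configurations (all points coincident or collinear) leave the
  # rotation underdetermined
  if (point_rank(m0) < 2L || point_rank(r0) < 2L)
    stop("degenerate point configuration (coincident or collinear points); ",
         "superposition is underdetermined")
  s <- svd(crossprod(m0, r0))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- rc - drop(mc %*% rot)
  lrmsd <- rmsd_direct(m0 %*% rot, r0)
  structure(list(rotation = rot, translation = trans, lrmsd = lrmsd),
            class = "rigid_transform")
}

point_rank <- function(centered, tol = 1e-9) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv[1], 1))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> lRMSD = %.4f A\n", x$lrmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords R x 3 matrix (or length-3R vector, returned in kind).
#' @param transform a `rigid_transform` (or any list with `rotation` and
#'   `translation`).
#' @return Transformed coordinates with the shape of the input.
#' @export
apply_transform <- function(coords, transform) {
  vec <- is.null(dim(coords))
  if (vec) coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  out <- sweep(coords %*% transform$rotation, 2L, -transform$translation)
  if (vec) as.vector(t(out)) else out
}

#' Coordinate RMSD without re-superposition
#'
#' Root mean squared point-wise distance between two paired coordinate sets,
#' in the frame they are given (no alignment is performed).
#'
#' @param a,b R x 3 matrices or length-3R vectors with matching sizes.
#' @return RMSD in Angstrom.
#' @export
rmsd_direct <- function(a, b) {
  a <- as.numeric(if (is.null(dim(a))) a else t(a))
  b <- as.numeric(if (is.null(dim(b))) b else t(b))
  if (length(a) != length(b))
    stop("coordinate sets differ in length (", length(a), " vs ",
         length(b), ")")
  sqrt(sum((a - b)^2) / (length(a) / 3))
}

#' Superpose every trace of an ensemble onto a reference trace
#'
#' Each row is rigidly superposed (via [kabsch()]) onto the row named by
#' `reference_id`; the reference row itself is returned unchanged. This
#' removes arbitrary crystallographic poses so that the remaining row
#' variation is internal deformation.
#'
#' @param ensemble a `trace_ensemble`.
#' @param reference_id trace identifier `"ENTRY:CHAIN"`; default `"1GJO:A"`,
#'   the unphosphorylated wildtype FGFR2-TKD reference.
#' @return The ensemble with superposed coordinate rows and an added
#'   `reference_id` field.
#' @export
align_ensemble <- function(ensemble, reference_id = "1GJO:A") {
  i <- match(reference_id, ensemble$trace_ids)
  if (is.na(i))
    stop("unknown reference '", reference_id, "'; available: ",
         paste(ensemble$trace_ids, collapse = ", "))
  ref <- matrix(ensemble$matrix[i, ], ncol = 3L, byrow = TRUE)
  mat <- ensemble$matrix
  for (j in seq_len(nrow(mat))) {
    if (j == i) next
    mob <- matrix(mat[j, ], ncol = 3L, byrow = TRUE)
    tf <- kabsch(mob, ref)
    mat[j, ] <- as.vector(t(apply_transform(mob, tf)))
  }
  out <- ensemble
  out$matrix <- mat
  out$reference_id <- reference_id
  out
}
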