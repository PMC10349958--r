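# Rigid-body superposition and RMSD primitives. Every scoring stage
# (I-RMSD, L-RMSD, CDR RMSD, TM-score) reduces to these.

new_transform <- function(rotation, translation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "abag_transform")
}

#' Identity rigid transform
#' @return An `abag_transform` with identity rotation and zero translation.
#' @export
identity_transform <- function() new_transform(diag(3), c(0, 0, 0))

as_coord_matrix <- function(x) {
  if (inherits(x, "abag_structure")) x <- x$atoms[, c("x", "y", "z")]
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 3) stop("coordinates must be an n x 3 matrix")
  m
}

#' Root-mean-square deviation without superposition
#'
#' @param a,b n x 3 coordinate matrices with fixed correspondence.
#' @return RMSD in Angstroms.
#' @export
rmsd <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 1) stop("empty coordinate sets")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of `mobile`
#' onto `target`. Reflections are corrected by negating the axis of the
#' smallest singular value when the raw solution is improper.
#'
#' @param mobile,target equal-length n x 3 coordinate matrices, n >= 3.
#' @return list with `transform` (an `abag_transform`) and `rmsd` after
#'   applying it.
#' @export
kabsch_superpose <- function(mobile, target) {
  m <- as_coord_matrix(mobile); tg <- as_coord_matrix(target)
  if (nrow(m) != nrow(tg)) stop("coordinate sets differ in length")
  if (nrow(m) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(m); ct <- colMeans(tg)
  mc <- sweep(m, 2, cm); tc <- sweep(tg, 2, ct)
  if ((collinear(mc) || collinear(tc)) && !all(abs(mc) < 1e-12))
    stop("point sets are collinear; superposition is not unique")
  h <- crossprod(mc, tc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile -> target frame
  translation <- ct - as.numeric(r %*% cm)
  tr <- new_transform(r, translation)
  list(transform = tr, rmsd = rmsd(apply_transform(m, tr), tg))
}

collinear <- function(centered, tol = 1e-9) {
  if (nrow(centered) < 3) return(FALSE)
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' Apply a rigid transform
#'
#' @param x an n x 3 coordinate matrix or an `abag_structure` (returned as a
#'   transformed copy).
#' @param transform an `abag_transform`.
#' @return object of the same kind with mapped coordinates.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "abag_transform"))
  if (inherits(x, "abag_structure")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- apply_transform(xyz, transform)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  m <- as_coord_matrix(x)
  sweep(m %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform an `abag_transform`.
#' @return the inverse `abag_transform`.
#' @export
invert_transform <- function(transform) {
  r <- t(transform$rotation)
  new_transform(r, -as.numeric(r %*% transform$translation))
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `abag_transform` objects.
#' @return the composed `abag_transform`.
#' @export
compose_transforms <- function(a, b) {
  new_transform(a$rotation %*% b$rotation,
                as.numeric(a$rotation %*% b$translation) + a$translation)
}

# Rotation about an arbitrary unit axis by angle (degrees), Rodrigues form.
rotation_about_axis <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
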