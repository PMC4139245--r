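# Rigid-body transforms: proper rotations plus translations.

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (within 1e-9).
#' @param translation numeric vector of length 3 (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("validation error: rotation is not a proper orthonormal matrix",
         call. = FALSE)
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a numeric 3-vector", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about an arbitrary axis
#'
#' Convenience constructor: rotation by `angle` degrees about the axis
#' through `center` with direction `axis`, as a [rigid_transform()].
#'
#' @param axis direction vector (normalised internally).
#' @param angle rotation angle in degrees.
#' @param center a point on the rotation axis.
#' @return a `rigid_transform`.
#' @export
axis_rotation <- function(axis, angle, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

transform_points <- function(xyz, t) {
  sweep(xyz %*% t(t$rotation), 2L, t$translation, "+")
}

#' Apply a rigid transform to a structure
#'
#' All pairwise intra-model distances are preserved (rigid motion).
#'
#' @param model a [structure_model()].
#' @param t a [rigid_transform()].
#' @return the transformed `structure_model`.
#' @export
apply_transform <- function(model, t) {
  stopifnot(inherits(model, "structure_model"))
  if (!inherits(t, "rigid_transform"))
    stop("t must be a rigid_transform", call. = FALSE)
  set_coords(model, transform_points(coords(model), t))
}

# Kabsch superposition: optimal proper rotation + translation mapping
# moving -> fixed; returns the transform and its RMSD.
kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  H <- crossprod(sweep(moving, 2L, cm), sweep(fixed, 2L, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cf - R %*% cm)
  moved <- sweep(moving %*% t(R), 2L, t, "+")
  list(transform = rigid_transform(R, t),
       rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}
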