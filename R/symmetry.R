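# Cyclic-symmetry axis fitting and deviation scoring.
#
# A Cn-symmetric oligomer superposes onto itself when rotated by 360/n
# about its symmetry axis with chains cyclically permuted.  The deviation
# score is the minimised superposition RMSD divided by sqrt(2): the raw
# RMSD between two independently displaced copies double-counts both
# displacements, so the per-copy convention estimates the mean atomic
# departure from the ideal symmetric reference.

rotation_axis_of <- function(R) {
  ev <- eigen(R)
  k <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, k])
  ax / sqrt(sum(ax^2))
}

#' Fit a cyclic symmetry axis
#'
#' Finds the axis direction and centre minimising the mean squared
#' distance between the model and itself rotated by 360/order degrees
#' with chains cyclically permuted; the minimum is also taken over the
#' `order` cyclic chain pairings, so the rotational direction of the
#' chain labelling need not be known.  Chains must appear in rotational
#' order with consistent atom ordering (symmetry-expanded structures and
#' the synthetic generator satisfy this).
#'
#' @param model a [structure_model()] with exactly `order` chains of
#'   equal atom count.
#' @param order rotational order n (>= 2).
#' @return a `symmetry_fit`: list with `axis_direction` (unit 3-vector),
#'   `center` (point on the axis), `order`, `deviation_rmsd` (Angstrom,
#'   per-copy convention), and `per_chain_rmsd`.
#' @examples
#' fit <- fit_symmetry_axis(make_ideal_hexamer(), 6)
#' fit$deviation_rmsd
#' @export
fit_symmetry_axis <- function(model, order) {
  stopifnot(inherits(model, "structure_model"))
  if (is.na(order) || order < 2)
    stop("domain error: order must be at least 2", call. = FALSE)
  order <- as.integer(order)
  a <- model$atoms
  chains <- unique(a$chain)
  if (length(chains) != order)
    stop("input error: model has ", length(chains), " chain(s), need ",
         order, call. = FALSE)
  idx <- split(seq_len(nrow(a)), factor(a$chain, chains))
  sizes <- lengths(idx)
  if (length(unique(sizes)) != 1L)
    stop("input error: unequal chain sizes (",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  X <- coords(model)
  angle <- 360 / order
  best <- NULL
  for (s in seq_len(order - 1L)) {
    perm <- integer(nrow(X))
    for (cc in seq_len(order))
      perm[idx[[cc]]] <- idx[[(cc + s - 1L) %% order + 1L]]
    Y <- X[perm, , drop = FALSE]
    init <- kabsch(Y, X)
    ax0 <- rotation_axis_of(init$transform$rotation)
    # centre: least-squares fixed point of the fitted transform,
    # restricted to the plane through the centroid normal to the axis
    c0 <- colMeans(X)
    basis <- svd(diag(3) - tcrossprod(ax0))$u[, 1:2]
    A <- (diag(3) - init$transform$rotation) %*% basis
    rhs <- init$transform$translation -
      (diag(3) - init$transform$rotation) %*% c0
    p0 <- tryCatch(as.numeric(qr.solve(A, rhs)), error = function(e) c(0, 0))
    obj <- function(par) {
      th <- par[1L]; ph <- par[2L]
      ax <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      b <- svd(diag(3) - tcrossprod(ax))$u[, 1:2]
      ctr <- c0 + as.numeric(b %*% par[3:4])
      t <- axis_rotation(ax, angle, ctr)
      mean(rowSums((transform_points(X, t) - Y)^2))
    }
    th0 <- acos(max(-1, min(1, ax0[3L])))
    ph0 <- atan2(ax0[2L], ax0[1L])
    fit <- optim(c(th0, ph0, p0), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value)
      best <- list(value = fit$value, par = fit$par, perm = perm, Y = Y)
  }
  par <- best$par
  ax <- c(sin(par[1L]) * cos(par[2L]), sin(par[1L]) * sin(par[2L]),
          cos(par[1L]))
  if (ax[3L] < 0) ax <- -ax   # sign convention: positive z component
  b <- svd(diag(3) - tcrossprod(ax))$u[, 1:2]
  c0 <- colMeans(X)
  ctr <- as.numeric(c0 + b %*% par[3:4])
  t <- axis_rotation(ax, angle, ctr)
  resid2 <- rowSums((transform_points(X, t) - best$Y)^2)
  per_chain <- vapply(idx, function(i) sqrt(mean(resid2[i]) / 2),
                      numeric(1))
  structure(list(axis_direction = ax, center = ctr, order = order,
                 deviation_rmsd = sqrt(best$value / 2),
                 per_chain_rmsd = per_chain),
            class = "symmetry_fit")
}

#' @export
print.symmetry_fit <- function(x, ...) {
  cat(sprintf(
    "<symmetry_fit> C%d axis (%.3f, %.3f, %.3f), deviation %.4f A\n",
    x$order, x$axis_direction[1L], x$axis_direction[2L],
    x$axis_direction[3L], x$deviation_rmsd))
  invisible(x)
}

#' Cyclic-symmetry deviation score
#'
#' Convenience wrapper returning `deviation_rmsd` of
#' [fit_symmetry_axis()]: 0 for a strictly n-fold-symmetric model,
#' growing with symmetry breaking (e.g. coordinate perturbation).
#'
#' @inheritParams fit_symmetry_axis
#' @return deviation in Angstrom.
#' @export
symmetry_deviation <- function(model, order) {
  fit_symmetry_axis(model, order)$deviation_rmsd
}
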