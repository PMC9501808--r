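#' Rigid-body transform in homogeneous coordinates
#'
#' A 4x4 matrix whose upper-left block is a proper rotation, whose last
#' column holds the translation in Angstrom, and whose bottom row is
#' `0 0 0 1`. Points are carried with homogeneous weight 1 (rotated and
#' translated), direction vectors with weight 0 (rotated only), which makes
#' internuclear vectors translation-invariant.
#'
#' @param rotation proper orthogonal 3x3 matrix.
#' @param translation length-3 vector, Angstrom.
#' @return a 4x4 matrix of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || det(rotation) < 0)
    stop("rotation block must be proper orthogonal (tolerance 1e-9)")
  m <- rbind(cbind(rotation, translation), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  class(m) <- c("rigid_transform", "matrix")
  m
}

.as_transform <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(4, 4))) stop("expected a 4x4 transform")
  if (!all(m[4, ] == c(0, 0, 0, 1))) stop("bottom row must be exactly 0 0 0 1")
  m
}

#' @rdname rigid_transform
#' @param m a 4x4 transform.
#' @export
transform_rotation <- function(m) .as_transform(m)[1:3, 1:3]

#' @rdname rigid_transform
#' @export
transform_translation <- function(m) .as_transform(m)[1:3, 4]

#' Invert a rigid transform
#' @param m a 4x4 transform.
#' @return the inverse transform.
#' @export
transform_inverse <- function(m) {
  R <- transform_rotation(m)
  rigid_transform(t(R), -t(R) %*% transform_translation(m))
}

#' Least-squares rigid superposition
#'
#' Finds the transform (optimal rotation plus translation, via SVD) mapping a
#' reference domain's coordinates onto a conformer's coordinates.
#'
#' @param ref_coords,conf_coords matched n x 3 coordinate matrices
#'   (n >= 3, not collinear).
#' @return a [rigid_transform()] with the residual coordinate RMSD in
#'   attribute `"rmsd"`.
#' @export
superposition_transform <- function(ref_coords, conf_coords) {
  ref_coords <- as.matrix(ref_coords)
  conf_coords <- as.matrix(conf_coords)
  if (!all(dim(ref_coords) == dim(conf_coords)) || nrow(ref_coords) < 3)
    stop("need matched coordinate sets with at least 3 atoms")
  cr <- colMeans(ref_coords)
  cc <- colMeans(conf_coords)
  X <- sweep(ref_coords, 2, cr)
  Y <- sweep(conf_coords, 2, cc)
  if (qr(X)$rank < 2) stop("degenerate (collinear) reference coordinates")
  s <- svd(crossprod(X, Y))  # 3x3: t(X) %*% Y
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cc - drop(R %*% cr)
  out <- rigid_transform(R, t_vec)
  moved <- sweep(ref_coords %*% t(R), 2, t_vec, "+")
  attr(out, "rmsd") <- sqrt(mean(rowSums((moved - conf_coords)^2)))
  out
}

#' Apply a transform to points and direction vectors
#'
#' @param m a 4x4 transform.
#' @param points n x 3 matrix of positions (homogeneous weight 1), or NULL.
#' @param vectors n x 3 matrix of directions (weight 0), or NULL.
#' @return list with transformed `points` and `vectors`.
#' @export
map_geometry <- function(m, points = NULL, vectors = NULL) {
  R <- transform_rotation(m)
  t_vec <- transform_translation(m)
  out <- list(points = NULL, vectors = NULL)
  if (!is.null(points)) {
    p <- as.matrix(points)
    out$points <- sweep(p %*% t(R), 2, t_vec, "+")
  }
  if (!is.null(vectors)) out$vectors <- as.matrix(vectors) %*% t(R)
  out
}

#' Read or write a transform flat file
#'
#' One transform per line: 12 numbers, the row-major 3x4 block (rotation and
#' translation); `#` starts a comment.
#'
#' @param path file path.
#' @return `read_transforms()`: list of [rigid_transform()]s.
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    v <- as.numeric(strsplit(l, "[,[:space:]]+")[[1]])
    if (length(v) != 12 || anyNA(v)) stop("transform line must hold 12 numbers")
    m <- matrix(v, 3, 4, byrow = TRUE)
    rigid_transform(m[, 1:3], m[, 4])
  })
}

#' @rdname read_transforms
#' @param transforms list of transforms.
#' @export
write_transforms <- function(transforms, path) {
  lines <- vapply(transforms, function(m) {
    m <- .as_transform(m)
    paste(format(as.vector(t(m[1:3, ])), digits = 17), collapse = " ")
  }, character(1))
  writeLines(c("# rigid transforms: 12 numbers per line, row-major 3x4", lines),
             path)
  invisible(path)
}

# Pre-resolved mobile-domain geometry for fast matrix building: positions for
# PCS records, bond vectors and scales for RDCs, CSA deviators for RCSA.
.resolve_mobile_geometry <- function(structure, restraints, conditions, options) {
  n <- nrow(restraints)
  info <- list(
    kind = character(n), pos = matrix(NA_real_, n, 3),
    bond = matrix(NA_real_, n, 3), rdc_scale = rep(NA_real_, n),
    csa_dev = matrix(NA_real_, n, 9), csa_fac = rep(NA_real_, n),
    metal = restraints$metal, ok = rep(FALSE, n)
  )
  for (i in seq_len(n)) {
    type <- restraints$type[i]
    if (type == "PCS") {
      p <- .atom_xyz(structure, restraints$residue[i], restraints$atom1[i])
      if (is.null(p)) next
      info$kind[i] <- "PCS"
      info$pos[i, ] <- p
      info$ok[i] <- TRUE
      if (isTRUE(options$rcsa) && restraints$atom1[i] %in% c("N", "C")) {
        nuc <- restraints$atom1[i]
        fr <- .peptide_frame(structure, restraints$residue[i], nuc)
        if (!is.null(fr)) {
          csa <- options$csa[[nuc]]
          phi <- csa$in_plane_angle * pi / 180
          U <- cbind(cos(phi) * fr[, 1] + sin(phi) * fr[, 2],
                     -sin(phi) * fr[, 1] + cos(phi) * fr[, 2], fr[, 3])
          delta <- U %*% diag(csa$values) %*% t(U)
          info$csa_dev[i, ] <- as.vector(delta - diag(3) * sum(diag(delta)) / 3)
          cond <- .cond_for(conditions, "PCS")
          # alignment factor per unit chi; contraction with the CSA deviator
          # happens against the back-rotated alignment tensor below
          info$csa_fac[i] <- cond$B0^2 * 1e-32 /
            (15 * .pm_const$mu0 * .pm_const$kB * cond$temperature)
        }
      }
    } else if (grepl("^RDC", type)) {
      p1 <- .atom_xyz(structure, restraints$residue[i], restraints$atom1[i])
      p2 <- .atom_xyz(structure, restraints$residue[i], restraints$atom2[i])
      if (is.null(p1) || is.null(p2)) next
      v <- p2 - p1
      r <- sqrt(sum(v^2))
      eff <- options$effective_lengths[type]
      cond <- .cond_for(conditions, type)
      info$kind[i] <- "RDC"
      info$bond[i, ] <- v / r
      info$rdc_scale[i] <- .rdc_scale(.gamma_for_atom(restraints$atom1[i]),
                                      .gamma_for_atom(restraints$atom2[i]),
                                      cond$B0, cond$temperature,
                                      if (is.na(eff)) r else eff)
      info$ok[i] <- TRUE
    }
  }
  info
}

#' Build the conformer-by-restraint prediction matrix
#'
#' Row j holds the predicted mobile-domain observables for conformer j: the
#' reference mobile-domain structure is carried by transform j, PCS (+RCSA)
#' values are computed from the transformed positions and RDCs from the
#' rotated (translation-invariant) bond directions with effective lengths.
#' Tensors stay fixed in the metal-domain frame.
#'
#' @param pool list of [rigid_transform()]s.
#' @param chis named list of `chi_tensor`s keyed by metal.
#' @param metal_position metal coordinates in the reference frame, Angstrom.
#' @param structure reference mobile-domain atom table.
#' @param restraints mobile-domain restraint table.
#' @inheritParams predict_observables
#' @param max_entries refuse to allocate more than this many matrix entries
#'   unless `override = TRUE`.
#' @param override allow very large matrices.
#' @return n_conformer x n_restraint matrix; unresolvable records are dropped
#'   with their indices in attribute `"used"` (logical per input record).
#' @export
build_prediction_matrix <- function(pool, chis, metal_position, structure,
                                    restraints,
                                    conditions = default_conditions(),
                                    options = predict_options(),
                                    max_entries = 1e8, override = FALSE) {
  n_conf <- length(pool)
  info <- .resolve_mobile_geometry(structure, restraints, conditions, options)
  used <- info$ok
  n_data <- sum(used)
  if (as.double(n_conf) * n_data > max_entries && !override)
    stop("prediction matrix would exceed max_entries; set override = TRUE")
  kind <- info$kind[used]
  pos <- info$pos[used, , drop = FALSE]
  bond <- info$bond[used, , drop = FALSE]
  rdc_scale <- info$rdc_scale[used]
  csa_dev <- info$csa_dev[used, , drop = FALSE]
  csa_fac <- info$csa_fac[used]
  metals <- info$metal[used]
  is_pcs <- kind == "PCS"
  chim <- lapply(chis, as_chi_matrix)

  M <- matrix(NA_real_, n_conf, n_data)
  for (j in seq_len(n_conf)) {
    R <- transform_rotation(pool[[j]])
    t_vec <- transform_translation(pool[[j]])
    tp <- sweep(pos %*% t(R), 2, t_vec, "+")
    rvec <- sweep(tp, 2, metal_position)
    rr <- sqrt(rowSums(rvec^2))
    tb <- bond %*% t(R)
    row <- numeric(n_data)
    for (met in unique(metals)) {
      m3 <- chim[[met]]
      sel_p <- is_pcs & metals == met
      if (any(sel_p)) {
        quad <- rowSums((rvec[sel_p, , drop = FALSE] %*% m3) *
                          rvec[sel_p, , drop = FALSE]) / rr[sel_p]^2
        row[sel_p] <- .pcs_scale(rr[sel_p]) * quad
        hasc <- sel_p & !is.na(csa_fac)
        if (any(hasc)) {
          # sum(A o (R d R')) = sum((R' A R) o d): rotate the alignment
          # tensor back instead of every CSA deviator
          Bm <- t(R) %*% m3 %*% R
          row[hasc] <- row[hasc] +
            csa_fac[hasc] * drop(csa_dev[hasc, , drop = FALSE] %*% as.vector(Bm))
        }
      }
      sel_r <- !is_pcs & metals == met
      if (any(sel_r)) {
        quad <- rowSums((tb[sel_r, , drop = FALSE] %*% m3) *
                          tb[sel_r, , drop = FALSE])
        row[sel_r] <- rdc_scale[sel_r] * quad
      }
    }
    M[j, ] <- row
  }
  attr(M, "used") <- used
  M
}

#' Optimal pivot of rotation for an ensemble of transforms
#'
#' Shifts the origin so that the translational components of the ensemble's
#' transforms become as small as possible: minimizes
#' \eqn{\sum_i p_i \lVert t_i + (R_i - I) o \rVert^2} over the origin `o` by
#' linear least squares. If the residual translations vanish, the ensemble is
#' a set of pure rotations about a common pivot.
#'
#' @param transforms list of [rigid_transform()]s.
#' @param populations optional weights (default equal).
#' @return list with `origin`, per-member `residual_lengths` (Angstrom) and
#'   their population-weighted `mean_residual`.
#' @export
optimal_pivot <- function(transforms, populations = NULL) {
  k <- length(transforms)
  if (is.null(populations)) populations <- rep(1 / k, k)
  angles <- vapply(transforms, function(m) {
    .rotation_angle_deg(transform_rotation(m)) * pi / 180
  }, numeric(1))
  if (all(angles <= 1e-6)) stop("pivot indeterminate: all rotations are near identity")
  A <- do.call(rbind, lapply(seq_len(k), function(i) {
    sqrt(populations[i]) * (transform_rotation(transforms[[i]]) - diag(3))
  }))
  b <- unlist(lapply(seq_len(k), function(i) {
    -sqrt(populations[i]) * transform_translation(transforms[[i]])
  }))
  # minimum-norm least squares: (R - I) is singular along each rotation axis
  s <- svd(A)
  keep <- s$d > max(s$d) * 1e-10
  origin <- drop(s$v[, keep, drop = FALSE] %*%
                   ((t(s$u[, keep, drop = FALSE]) %*% b) / s$d[keep]))
  res <- vapply(seq_len(k), function(i) {
    sqrt(sum((transform_translation(transforms[[i]]) +
                drop((transform_rotation(transforms[[i]]) - diag(3)) %*% origin))^2))
  }, numeric(1))
  list(origin = origin, residual_lengths = res,
       mean_residual = sum(populations * res))
}
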