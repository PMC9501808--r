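#' Susceptibility-anisotropy tensor from five independent components
#'
#' A traceless symmetric 3x3 tensor \eqn{\Delta\chi} is parameterized by five
#' independent components `(ax, rh, xy, xz, yz)` in units of 1e-32 m^3. Two
#' tabulation conventions are supported for the first two components:
#'
#' * `"axial"`: `ax = 2*zz - xx - yy` (i.e. `zz = ax/3`) and `rh = xx - yy`.
#' * `"element"`: `ax` is the `zz` matrix element itself and `rh = xx - yy`.
#'
#' The off-diagonal components are matrix elements in both conventions. Which
#' convention a published component table uses must be known to recover the
#' matrix; see the vignette for how the two conventions affect comparative
#' statistics between tensors.
#'
#' @param ax,rh,xy,xz,yz tensor components, 1e-32 m^3.
#' @param frame_label text naming the coordinate frame the components refer to.
#' @param convention component convention, `"axial"` (default) or `"element"`.
#' @return an object of class `chi_tensor`.
#' @seealso [chi_from_components()], [components_from_chi()], [chi_eigen()]
#' @export
chi_tensor <- function(ax, rh, xy, xz, yz, frame_label = "",
                       convention = c("axial", "element")) {
  convention <- match.arg(convention)
  comp <- c(ax = ax, rh = rh, xy = xy, xz = xz, yz = yz)
  if (!all(is.finite(comp))) stop("tensor components must be finite")
  structure(list(components = comp, convention = convention,
                 frame_label = frame_label),
            class = "chi_tensor")
}

#' @export
print.chi_tensor <- function(x, ...) {
  cat(sprintf("chi_tensor (%s convention%s), components [1e-32 m^3]:\n",
              x$convention,
              if (nzchar(x$frame_label)) paste0(", frame ", x$frame_label) else ""))
  print(round(x$components, 4))
  invisible(x)
}

#' Build the traceless symmetric matrix from five components
#'
#' Inverse of [components_from_chi()]. With the `"axial"` convention
#' `zz = ax/3`; `xx` and `yy` follow from `xx + yy = -zz`, `xx - yy = rh`.
#'
#' @inheritParams chi_tensor
#' @return a 3x3 traceless symmetric matrix in the same units as the
#'   components (1e-32 m^3).
#' @examples
#' chi_from_components(3, 0, 0, 0, 0)  # diag(-0.5, -0.5, 1)
#' @export
chi_from_components <- function(ax, rh, xy, xz, yz,
                                convention = c("axial", "element")) {
  convention <- match.arg(convention)
  if (!all(is.finite(c(ax, rh, xy, xz, yz)))) stop("components must be finite")
  zz <- if (convention == "axial") ax / 3 else ax
  xx <- (-zz + rh) / 2
  yy <- (-zz - rh) / 2
  matrix(c(xx, xy, xz,
           xy, yy, yz,
           xz, yz, zz), nrow = 3, byrow = TRUE)
}

#' Recover the five components from a traceless symmetric matrix
#'
#' @param m a 3x3 symmetric matrix with negligible trace.
#' @param convention component convention, see [chi_tensor()].
#' @param tol relative tolerance on symmetry and trace (fraction of the
#'   Frobenius norm).
#' @return named numeric vector `(ax, rh, xy, xz, yz)`.
#' @export
components_from_chi <- function(m, convention = c("axial", "element"),
                                tol = 1e-8) {
  convention <- match.arg(convention)
  m <- as_chi_matrix(m)
  fro <- sqrt(sum(m^2))
  if (fro == 0) {
    return(c(ax = 0, rh = 0, xy = 0, xz = 0, yz = 0))
  }
  if (abs(sum(diag(m))) > tol * fro)
    stop("matrix is not traceless within tolerance")
  if (max(abs(m - t(m))) > tol * fro)
    stop("matrix is not symmetric within tolerance")
  ax <- if (convention == "axial") 3 * m[3, 3] else m[3, 3]
  c(ax = ax, rh = m[1, 1] - m[2, 2], xy = m[1, 2], xz = m[1, 3], yz = m[2, 3])
}

#' @export
as.matrix.chi_tensor <- function(x, ...) {
  cc <- x$components
  chi_from_components(cc[["ax"]], cc[["rh"]], cc[["xy"]], cc[["xz"]], cc[["yz"]],
                      convention = x$convention)
}

# Coerce chi_tensor | 3x3 matrix to a plain matrix.
as_chi_matrix <- function(x) {
  if (inherits(x, "chi_tensor")) return(as.matrix(x))
  if (is.matrix(x) && all(dim(x) == c(3, 3))) return(x)
  stop("expected a chi_tensor or a 3x3 matrix")
}

#' Eigen-decomposition with signed-value ordering
#'
#' Eigenvalues are sorted ascending by signed value (not absolute value) and
#' the eigenvector frame is made right-handed.
#'
#' @param x a `chi_tensor` or 3x3 symmetric matrix.
#' @return list with `values` (ascending) and `frame` (orthonormal columns,
#'   determinant +1), class `chi_eigen`.
#' @export
chi_eigen <- function(x) {
  m <- as_chi_matrix(x)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  frame <- e$vectors[, ord, drop = FALSE]
  if (det(frame) < 0) frame[, 3] <- -frame[, 3]
  structure(list(values = values, frame = frame), class = "chi_eigen")
}

#' Normalized scalar product between two tensors
#'
#' With `on = "components"` (default) the product is the Euclidean inner
#' product of the five-component vectors `(ax, rh, xy, xz, yz)`, the metric in
#' which tabulated anisotropy components are conventionally compared. With
#' `on = "matrix"` it is the Frobenius inner product of the 3x3 matrices. The
#' two metrics weight the axial/rhombic part differently and give slightly
#' different values.
#'
#' @param a,b `chi_tensor` objects (or, for `on = "matrix"`, 3x3 matrices).
#' @param on `"components"` or `"matrix"`.
#' @return a number in \[-1, 1\]; -1 means antiparallel tensors.
#' @export
normalized_scalar_product <- function(a, b, on = c("components", "matrix")) {
  on <- match.arg(on)
  if (on == "components") {
    if (!inherits(a, "chi_tensor") || !inherits(b, "chi_tensor"))
      stop("component scalar product needs chi_tensor inputs")
    if (a$convention != b$convention)
      stop("tensors use different component conventions")
    u <- a$components
    v <- b$components
  } else {
    u <- as.vector(as_chi_matrix(a))
    v <- as.vector(as_chi_matrix(b))
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("scalar product undefined for a zero tensor")
  sum(u * v) / (nu * nv)
}

# All 24 proper (det +1) signed permutation matrices: the symmetry operations
# relating equivalent right-handed eigenframes when axes may be re-paired.
.proper_signed_perms <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      m <- matrix(0, 3, 3)
      m[cbind(seq_len(3), p)] <- c(s1, s2, s3)
      if (abs(det(m) - 1) < 1e-12) out[[length(out) + 1]] <- m
    }
  }
  out
})

.rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Angle between the eigenframes of two tensors
#'
#' Both tensors are diagonalized with ascending signed-value eigenvalue order
#' and right-handed frames. `method = "rotation"` (default) reports the angle
#' of the single relative rotation between the frames, minimized over the
#' symmetry operations of an eigenframe; `method = "axes"` reports the mean of
#' the three per-axis angles under the best one-to-one axis pairing. With
#' `match_axes = TRUE` (default) axes may be re-paired (all 24 proper signed
#' permutations), which is required when comparing tensors of opposite sign
#' whose eigenvalue orders are reversed; with `FALSE` only the four proper
#' sign flips at fixed eigenvalue order are allowed.
#'
#' @param a,b `chi_tensor` objects or 3x3 matrices.
#' @param method `"rotation"` or `"axes"`.
#' @param match_axes allow axis re-pairing (see above).
#' @param degeneracy_tol relative eigenvalue-gap threshold below which the
#'   frame is considered undefined.
#' @return angle in degrees in \[0, 180\].
#' @export
eigenframe_angle <- function(a, b, method = c("rotation", "axes"),
                             match_axes = TRUE, degeneracy_tol = 1e-6) {
  method <- match.arg(method)
  ea <- chi_eigen(a)
  eb <- chi_eigen(b)
  for (e in list(ea, eb)) {
    scale <- max(abs(e$values))
    if (scale == 0 || min(diff(e$values)) < degeneracy_tol * scale)
      stop("eigenframe undefined: degenerate eigenvalue spectrum")
  }
  ops <- .proper_signed_perms
  if (!match_axes) {
    ops <- Filter(function(m) all(diag(abs(m)) == 1), ops)
  }
  if (method == "rotation") {
    angs <- vapply(ops, function(S) {
      .rotation_angle_deg(t(ea$frame) %*% (eb$frame %*% S))
    }, numeric(1))
    return(min(angs))
  }
  # mean per-axis angle over the best axis assignment
  dots <- abs(t(ea$frame) %*% eb$frame)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  if (!match_axes) perms <- perms[1]
  best <- Inf
  for (p in perms) {
    d <- dots[cbind(seq_len(3), p)]
    ang <- mean(acos(pmin(1, d)) * 180 / pi)
    if (ang < best) best <- ang
  }
  best
}

#' Order parameter from eigenvalue regression
#'
#' The least-squares slope `s` minimizing `sum((lambda_avg - s * lambda_ref)^2)`
#' over all size-ordered eigenvalue pairs, pooled across the supplied tensors
#' (one or several metals): `s = sum(l_ref * l_avg) / sum(l_ref^2)`. The slope
#' is 1 for a rigid system and shrinks toward 0 under isotropic motional
#' averaging.
#'
#' @param ref reference tensor(s): a `chi_tensor`/matrix or a list of them.
#' @param avg motionally averaged counterpart(s), matched to `ref`.
#' @return the pooled regression slope (may be negative for large-amplitude
#'   averaging).
#' @export
order_parameter <- function(ref, avg) {
  as_list <- function(x) if (inherits(x, "chi_tensor") || is.matrix(x)) list(x) else x
  ref <- as_list(ref)
  avg <- as_list(avg)
  if (length(ref) != length(avg)) stop("ref and avg must have equal length")
  lr <- unlist(lapply(ref, function(x) chi_eigen(x)$values))
  la <- unlist(lapply(avg, function(x) chi_eigen(x)$values))
  den <- sum(lr^2)
  if (den == 0) stop("order parameter undefined for zero reference tensor")
  sum(lr * la) / den
}

#' Population-weighted rotational average of a tensor
#'
#' Computes \eqn{\sum_i p_i R_i \Delta\chi R_i^T} and returns the result in
#' component form with the same convention as the input.
#'
#' @param chi a `chi_tensor`.
#' @param rotations list of proper 3x3 rotation matrices (or a 3x3xN array).
#' @param populations non-negative weights summing to 1; defaults to equal.
#' @return the averaged `chi_tensor`.
#' @export
average_tensor <- function(chi, rotations, populations = NULL) {
  if (is.array(rotations) && length(dim(rotations)) == 3) {
    rotations <- lapply(seq_len(dim(rotations)[3]), function(i) rotations[, , i])
  }
  n <- length(rotations)
  if (is.null(populations)) populations <- rep(1 / n, n)
  if (length(populations) != n) stop("one population per rotation required")
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-8)
    stop("populations must be non-negative and sum to 1 within 1e-8")
  for (R in rotations) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
      stop("rotations must be proper orthogonal")
  }
  m <- as_chi_matrix(chi)
  avg <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    avg <- avg + populations[i] * (rotations[[i]] %*% m %*% t(rotations[[i]]))
  }
  conv <- if (inherits(chi, "chi_tensor")) chi$convention else "axial"
  comp <- components_from_chi((avg + t(avg)) / 2, convention = conv, tol = 1e-6)
  lab <- if (inherits(chi, "chi_tensor")) chi$frame_label else ""
  chi_tensor(comp[["ax"]], comp[["rh"]], comp[["xy"]], comp[["xz"]], comp[["yz"]],
             frame_label = lab, convention = conv)
}

#' Uniform random rotations
#'
#' Drawn from random unit quaternions (exactly uniform on SO(3)), using R's
#' RNG stream so that `set.seed()` makes the draw reproducible.
#'
#' @param n number of rotations.
#' @return a 3x3xN array of rotation matrices.
#' @export
random_rotations <- function(n) {
  .random_rotations_cpp(as.integer(n))
}

#' Frequency of strongly unequal order parameters under random rotations
#'
#' For each trial, `n_rot` uniform random rotations (shared by both tensors)
#' define an equal-population rotational ensemble; each tensor is averaged
#' under it and its order parameter relative to its own unaveraged tensor is
#' computed via [order_parameter()]. The returned value is the fraction of
#' trials in which `|S_a| > ratio * |S_b|`. Order parameters are compared by
#' magnitude because the eigenvalue-regression slope can turn negative under
#' large-angle averaging.
#'
#' @param chi_a,chi_b `chi_tensor` objects or 3x3 matrices.
#' @param n_rot rotations per ensemble (>= 1).
#' @param ratio threshold ratio (>= 0).
#' @param n_trials Monte-Carlo trials (>= 1).
#' @param seed optional integer seed.
#' @return the frequency, with the raw trial count in attribute `"count"`.
#' @export
random_rotation_order_stat <- function(chi_a, chi_b, n_rot = 3, ratio = 3,
                                       n_trials = 10000, seed = NULL) {
  stopifnot(n_rot >= 1, n_trials >= 1, ratio >= 0)
  if (!is.null(seed)) set.seed(seed)
  count <- .rotation_order_stat_cpp(as_chi_matrix(chi_a), as_chi_matrix(chi_b),
                                    as.integer(n_rot), ratio, as.numeric(n_trials))
  structure(count / n_trials, count = count)
}

#' Read or write a tensor component table
#'
#' Whitespace- or comma-delimited text with header
#' `metal ax rh xy xz yz`, values in 1e-32 m^3.
#'
#' @param path file path.
#' @return `read_chi_table()`: a data.frame with those columns.
#' @export
read_chi_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("metal", "ax", "rh", "xy", "xz", "yz")
  if (!all(need %in% names(df))) {
    stop("tensor table must have columns: ", paste(need, collapse = " "))
  }
  df[, need]
}

#' @param df data.frame with columns `metal ax rh xy xz yz`.
#' @rdname read_chi_table
#' @export
write_chi_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a tensor table into a list of `chi_tensor` objects
#'
#' @param df table as returned by [read_chi_table()].
#' @inheritParams chi_tensor
#' @return named list of `chi_tensor`, one per metal.
#' @export
chi_table_tensors <- function(df, convention = c("axial", "element"),
                              frame_label = "") {
  convention <- match.arg(convention)
  out <- lapply(seq_len(nrow(df)), function(i) {
    chi_tensor(df$ax[i], df$rh[i], df$xy[i], df$xz[i], df$yz[i],
               frame_label = frame_label, convention = convention)
  })
  stats::setNames(out, df$metal)
}

#' Reference lanthanide tensors for the CaM/Munc13-1 complex
#'
#' Five-component susceptibility-anisotropy tensors of six lanthanides
#' (Dy, Er, Ho, Tb, Tm, Yb) bound in the N-terminal calcium site of
#' calmodulin in complex with the Munc13-1 peptide, expressed in the
#' N-terminal-domain reference frame, units 1e-32 m^3. `"N"` holds the
#' tensors fitted to metal-domain PCS+RDC data; `"C"` the effective
#' (motionally reduced) tensors fitted to mobile-domain RDCs.
#'
#' The bundled components reproduce the published inter-tensor statistics
#' (scalar products, eigenframe angles, eigenvalue-regression order
#' parameter) when interpreted with the `"element"` convention, which is
#' therefore the default; see the vignette section on component conventions.
#'
#' @param domain `"N"` or `"C"`.
#' @inheritParams chi_tensor
#' @return named list of `chi_tensor` objects.
#' @export
lanthanide_tensors <- function(domain = c("N", "C"),
                               convention = c("element", "axial")) {
  domain <- match.arg(domain)
  convention <- match.arg(convention)
  path <- system.file("extdata",
                      sprintf("cam_munc13_chi_%s.tsv", domain),
                      package = "paramotion", mustWork = TRUE)
  chi_table_tensors(read_chi_table(path), convention = convention,
                    frame_label = "CaM N-terminal domain (2BE6/B)")
}
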