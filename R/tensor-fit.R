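#' Q factor of agreement between experimental and back-calculated data
#'
#' \eqn{Q = \sqrt{\sum w^2 (x_{exp}-x_{calc})^2 / \sum w^2 x_{exp}^2}}; 0 is a
#' perfect fit, 1 corresponds to predicting zeros.
#'
#' @param x_exp,x_calc experimental and back-calculated values.
#' @param w per-record weights (defaults to 1).
#' @return the Q factor.
#' @export
q_factor <- function(x_exp, x_calc, w = rep(1, length(x_exp))) {
  sqrt(sum(w^2 * (x_exp - x_calc)^2) / sum(w^2 * x_exp^2))
}

# Default grouping: PCS together; RDCs per type only when every type present
# has at least `split_rdc_min` records, else pooled.
.restraint_groups <- function(restraints, split_rdc_min = 15) {
  if (!is.null(restraints$group)) return(restraints$group)
  g <- ifelse(restraints$type == "PCS", "PCS", "RDC")
  rdc_types <- table(restraints$type[restraints$type != "PCS"])
  if (length(rdc_types) > 0 && all(rdc_types >= split_rdc_min)) {
    g[restraints$type != "PCS"] <- restraints$type[restraints$type != "PCS"]
  }
  g
}

#' Assemble the linear system for tensor fitting
#'
#' PCS, RDC and RCSA predictions are all linear in the five tensor
#' components, so each resolvable restraint contributes one row whose dot
#' product with the component vector equals the predicted observable. The
#' RCSA terms are folded into the same rows.
#'
#' @inheritParams predict_observables
#' @param convention component convention of the unknowns (see [chi_tensor()]).
#' @return list with `A` (n x 5 coefficient matrix), `b` (observed values),
#'   `w` (weights), `groups`, `used` (logical index of resolvable records).
#' @export
assemble_linear_system <- function(structure, metal_position, restraints,
                                   conditions = default_conditions(),
                                   options = predict_options(),
                                   convention = "element") {
  if (nrow(restraints) == 0) stop("empty restraint set")
  info <- .resolve_mobile_geometry(structure, restraints, conditions, options)
  A <- matrix(NA_real_, nrow(restraints), 5,
              dimnames = list(NULL, c("ax", "rh", "xy", "xz", "yz")))
  A[info$ok, ] <- .linear_rows(info, metal_position, convention)
  used <- info$ok
  w <- if (is.null(restraints$weight)) rep(1, nrow(restraints)) else restraints$weight
  if (any(w[used] <= 0)) stop("weights must be positive")
  list(A = A[used, , drop = FALSE], b = restraints$value[used], w = w[used],
       groups = .restraint_groups(restraints)[used], used = used)
}

# Coefficient rows for the resolved records at a given metal position:
# column k is the prediction under the k-th unit component tensor. Geometry
# resolution is done once in .resolve_mobile_geometry, so the metal-position
# optimizer can rebuild rows cheaply.
.linear_rows <- function(info, metal_position, convention) {
  ok <- info$ok
  kind <- info$kind[ok]
  pos <- info$pos[ok, , drop = FALSE]
  bond <- info$bond[ok, , drop = FALSE]
  rdc_scale <- info$rdc_scale[ok]
  csa_dev <- info$csa_dev[ok, , drop = FALSE]
  csa_fac <- info$csa_fac[ok]
  is_pcs <- kind == "PCS"
  rvec <- sweep(pos, 2, metal_position)
  rr <- sqrt(rowSums(rvec^2))
  A <- matrix(0, sum(ok), 5)
  for (k in 1:5) {
    comp <- numeric(5)
    comp[k] <- 1
    Ek <- chi_from_components(comp[1], comp[2], comp[3], comp[4], comp[5],
                              convention = convention)
    col <- numeric(nrow(A))
    if (any(is_pcs)) {
      quad <- rowSums((rvec[is_pcs, , drop = FALSE] %*% Ek) *
                        rvec[is_pcs, , drop = FALSE]) / rr[is_pcs]^2
      col[is_pcs] <- .pcs_scale(rr[is_pcs]) * quad
      hasc <- is_pcs & !is.na(csa_fac)
      if (any(hasc)) {
        col[hasc] <- col[hasc] +
          csa_fac[hasc] * drop(csa_dev[hasc, , drop = FALSE] %*% as.vector(Ek))
      }
    }
    if (any(!is_pcs)) {
      quad <- rowSums((bond[!is_pcs, , drop = FALSE] %*% Ek) *
                        bond[!is_pcs, , drop = FALSE])
      col[!is_pcs] <- rdc_scale[!is_pcs] * quad
    }
    A[, k] <- col
  }
  A
}

.wls_solve <- function(A, b, w) {
  qa <- qr(A * w)
  if (qa$rank < ncol(A)) {
    stop(sprintf("rank-deficient system (rank %d of %d): %s",
                 qa$rank, ncol(A),
                 "restraint geometry does not determine all tensor components"))
  }
  drop(qr.coef(qa, b * w))
}

#' Fit a susceptibility-anisotropy tensor by weighted least squares
#'
#' Solves the weighted linear system for the five tensor components and
#' reports Q factors overall and per data group, per-record residuals and
#' per-group residual RMSDs.
#'
#' @inheritParams assemble_linear_system
#' @param weights optional per-record weights overriding the `weight` column
#'   (recycled if length 1).
#' @return object of class `chi_fit`: the fitted `chi_tensor`, `Q`,
#'   `Q_group`, `residuals`, `fitted`, `sigma` (per-group residual RMSD),
#'   plus the system used.
#' @export
fit_tensor <- function(structure, metal_position, restraints,
                       conditions = default_conditions(), weights = NULL,
                       options = predict_options(), convention = "element") {
  sys <- assemble_linear_system(structure, metal_position, restraints,
                                conditions, options, convention)
  if (!is.null(weights)) {
    w_full <- rep_len(weights, nrow(restraints))
    sys$w <- w_full[sys$used]
  }
  if (nrow(sys$A) < 5) stop("need at least 5 informative restraints")
  coef <- .wls_solve(sys$A, sys$b, sys$w)
  fitted <- drop(sys$A %*% coef)
  res <- sys$b - fitted
  qg <- vapply(split(seq_along(res), sys$groups), function(i) {
    q_factor(sys$b[i], fitted[i], sys$w[i])
  }, numeric(1))
  sig <- vapply(split(res, sys$groups), function(r) sqrt(mean(r^2)), numeric(1))
  chi <- chi_tensor(coef[["ax"]], coef[["rh"]], coef[["xy"]], coef[["xz"]],
                    coef[["yz"]], convention = convention)
  structure(list(chi = chi, coefficients = coef,
                 Q = q_factor(sys$b, fitted, sys$w), Q_group = qg,
                 residuals = res, fitted = fitted, values = sys$b,
                 weights = sys$w, groups = sys$groups, sigma = sig,
                 metal_position = metal_position, used = sys$used,
                 convention = convention),
            class = "chi_fit")
}

#' @export
print.chi_fit <- function(x, ...) {
  cat(sprintf("chi_fit: Q = %.4f (%s)\n", x$Q,
              paste(sprintf("%s %.4f", names(x$Q_group), x$Q_group), collapse = ", ")))
  print(x$chi)
  invisible(x)
}

#' Iterative estimation of per-group data scatter
#'
#' Alternates fitting and reweighting: each group's scatter is estimated by
#' the RMSD of its residuals and the next fit weights records by the inverse
#' of that scatter (inverse-standard-deviation rather than inverse-variance
#' weighting, which is less aggressive for heavy-tailed errors). Iterates to
#' a fixed point.
#'
#' @inheritParams fit_tensor
#' @param groups optional explicit group label per record.
#' @param tol relative change in group RMSDs at convergence.
#' @param max_iter maximum iterations.
#' @return list with `sigma` (per-group scatter, data units), `weights`
#'   (final per-record weights `1/sigma`), `fit` (final `chi_fit`),
#'   `iterations`, and the iteration `trace`.
#' @export
estimate_group_scales <- function(structure, metal_position, restraints,
                                  conditions = default_conditions(),
                                  groups = NULL, tol = 1e-4, max_iter = 50,
                                  options = predict_options(),
                                  convention = "element") {
  sys <- assemble_linear_system(structure, metal_position, restraints,
                                conditions, options, convention)
  if (!is.null(groups)) sys$groups <- groups[sys$used]
  cnt <- table(sys$groups)
  if (any(cnt < 10)) {
    stop("each group needs at least 10 records (got: ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), ")")
  }
  glev <- sort(unique(sys$groups))
  gidx <- split(seq_along(sys$groups), sys$groups)[glev]
  sigma <- stats::setNames(rep(1, length(glev)), glev)
  trace <- list()
  for (it in seq_len(max_iter)) {
    w <- 1 / sigma[sys$groups]
    coef <- .wls_solve(sys$A, sys$b, w)
    res <- sys$b - drop(sys$A %*% coef)
    new_sigma <- vapply(gidx, function(i) sqrt(mean(res[i]^2)), numeric(1))
    trace[[it]] <- new_sigma
    rel <- max(abs(new_sigma - sigma) / new_sigma)
    sigma <- new_sigma
    if (it > 1 && rel < tol) {
      restraints$weight <- unname(1 / sigma[.restraint_groups(restraints)])
      if (!is.null(groups)) restraints$weight <- unname(1 / sigma[groups])
      fit <- fit_tensor(structure, metal_position, restraints, conditions,
                        options = options, convention = convention)
      return(list(sigma = sigma, weights = 1 / sigma[sys$groups], fit = fit,
                  iterations = it, trace = do.call(rbind, trace)))
    }
  }
  stop("group-scale iteration did not converge in ", max_iter,
       " iterations; trace: ",
       paste(vapply(trace, function(s) paste(signif(s, 4), collapse = "/"),
                    character(1)), collapse = " -> "))
}

#' Refine the metal position by minimizing the PCS Q factor
#'
#' Gradient-free simplex search over the 3D metal position, refitting the
#' tensor at every trial point; the objective is the Q factor of the PCS
#' group. Intended for small corrections of a metal placed at a
#' crystallographic ion site.
#'
#' @inheritParams fit_tensor
#' @param init_position starting metal coordinates, Angstrom.
#' @param max_shift error if the refined position moves farther than this
#'   from the start (Angstrom); larger shifts are considered unphysical.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return list with `position`, `displacement` (Angstrom), final `fit`,
#'   `q_pcs_init` and `q_pcs_final`.
#' @export
optimize_metal_position <- function(structure, restraints,
                                    conditions = default_conditions(),
                                    init_position, weights = NULL,
                                    options = predict_options(),
                                    convention = "element", max_shift = 5,
                                    control = list(maxit = 400, reltol = 1e-10)) {
  if (!any(restraints$type == "PCS")) stop("PCS records required")
  info <- .resolve_mobile_geometry(structure, restraints, conditions, options)
  ok <- info$ok
  b <- restraints$value[ok]
  w <- if (is.null(weights)) {
    if (is.null(restraints$weight)) rep(1, nrow(restraints)) else restraints$weight
  } else rep_len(weights, nrow(restraints))
  w <- w[ok]
  pcs_sel <- info$kind[ok] == "PCS"
  qpcs <- function(pos) {
    A <- .linear_rows(info, pos, convention)
    coef <- .wls_solve(A, b, w)
    fitted <- drop(A %*% coef)
    q_factor(b[pcs_sel], fitted[pcs_sel], w[pcs_sel])
  }
  q0 <- qpcs(init_position)
  opt <- stats::optim(init_position, qpcs, method = "Nelder-Mead",
                      control = control)
  disp <- sqrt(sum((opt$par - init_position)^2))
  if (disp > max_shift) {
    stop(sprintf("metal position diverged %.2f A from start (> %.1f A)",
                 disp, max_shift))
  }
  fit <- fit_tensor(structure, opt$par, restraints, conditions, weights,
                    options, convention)
  list(position = opt$par, displacement = disp, fit = fit,
       q_pcs_init = q0, q_pcs_final = opt$value)
}

#' Bootstrap uncertainties of the tensor components
#'
#' Records are resampled with replacement to the original size and refitted;
#' the per-component uncertainty is the RMSD of the resampled estimates about
#' the full-data estimate. Rank-deficient resamples are redrawn (capped at
#' ten times the number of resamples).
#'
#' @inheritParams fit_tensor
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @param seed optional integer seed.
#' @return named vector of per-component uncertainties, with the resample
#'   matrix in attribute `"resamples"` and the redraw count in `"redraws"`.
#' @export
bootstrap_tensor <- function(structure, metal_position, restraints,
                             conditions = default_conditions(),
                             n_resamples = 1000, seed = NULL, weights = NULL,
                             options = predict_options(),
                             convention = "element") {
  if (n_resamples < 100) stop("n_resamples must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  sys <- assemble_linear_system(structure, metal_position, restraints,
                                conditions, options, convention)
  if (!is.null(weights)) {
    w_full <- rep_len(weights, nrow(restraints))
    sys$w <- w_full[sys$used]
  }
  n <- nrow(sys$A)
  coef0 <- .wls_solve(sys$A, sys$b, sys$w)
  coefs <- matrix(NA_real_, n_resamples, 5,
                  dimnames = list(NULL, names(coef0)))
  redraws <- 0L
  cap <- 10L * n_resamples
  k <- 1L
  while (k <= n_resamples) {
    idx <- sample.int(n, n, replace = TRUE)
    ck <- tryCatch(.wls_solve(sys$A[idx, , drop = FALSE], sys$b[idx], sys$w[idx]),
                   error = function(e) NULL)
    if (is.null(ck)) {
      redraws <- redraws + 1L
      if (redraws > cap) stop("too many degenerate bootstrap resamples")
      next
    }
    coefs[k, ] <- ck
    k <- k + 1L
  }
  sig <- sqrt(colMeans(sweep(coefs, 2, coef0)^2))
  structure(sig, resamples = coefs, redraws = redraws)
}
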