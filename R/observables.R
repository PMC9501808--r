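#' Magnetic field and temperature conditions
#'
#' @param mhz proton Larmor frequency in MHz (converted to Tesla), or
#' @param B0 static field in Tesla (one of the two must be given).
#' @param temperature sample temperature in Kelvin.
#' @return list with `B0` (Tesla) and `temperature` (K).
#' @export
field_conditions <- function(mhz = NULL, B0 = NULL, temperature = 298) {
  if (is.null(B0)) {
    if (is.null(mhz)) stop("give either mhz or B0")
    B0 <- mhz * 1e6 * 2 * pi / .pm_const$gamma[["1H"]]
  }
  if (B0 <= 0 || temperature <= 0) stop("B0 and temperature must be positive")
  list(B0 = B0, temperature = temperature)
}

#' Default per-observable field conditions
#'
#' Amide and H-C' couplings measured at 950 MHz, Calpha couplings at 900 MHz,
#' shifts referenced to the 950 MHz field; 298 K throughout. Override any
#' entry by passing a modified copy to the prediction functions.
#'
#' @param temperature sample temperature in Kelvin.
#' @return named list of [field_conditions()] keyed by restraint type.
#' @export
default_conditions <- function(temperature = 298) {
  list(
    "PCS"      = field_conditions(mhz = 950, temperature = temperature),
    "RDC_NH"   = field_conditions(mhz = 950, temperature = temperature),
    "RDC_HC'"  = field_conditions(mhz = 950, temperature = temperature),
    "RDC_CaHa" = field_conditions(mhz = 900, temperature = temperature),
    "RDC_C'Ca" = field_conditions(mhz = 900, temperature = temperature)
  )
}

.cond_for <- function(conditions, type) {
  if (!is.null(conditions$B0)) return(conditions)  # a single field_conditions
  if (!is.null(conditions[[type]])) return(conditions[[type]])
  stop("no field conditions for restraint type ", type)
}

# ---- prefactors -----------------------------------------------------------
# Each observable's physical prefactor lives in exactly one function below so
# that unit conventions are auditable in one place. Tensor components are in
# 1e-32 m^3 and distances in Angstrom throughout the package.

# PCS in ppm per unit tensor contraction: delta = scale * (rhat' Dchi rhat),
# from delta = (1 / (4 pi r^3)) rhat' Dchi rhat with Dchi in m^3, r in m.
.pcs_scale <- function(r_ang) {
  1e6 * 1e-32 / (4 * pi * (r_ang * 1e-10)^3)
}

# RDC in Hz per unit tensor contraction:
# D = -(B0^2 g1 g2 hbar / (40 pi^2 kB T r^3)) * (rhat' Dchi rhat),
# the static dipolar splitting -(mu0 g1 g2 hbar / (4 pi^2 r^3)) <P2(cos th)>
# with the orientational average <P2> = (3/2) rhat' A rhat under the
# field-induced alignment A = B0^2 Dchi / (15 mu0 kB T). The prefactor is
# pinned by a Boltzmann orientational-average oracle in the test suite.
.rdc_scale <- function(gamma1, gamma2, B0, temperature, r_ang) {
  -(B0^2 * gamma1 * gamma2 * .pm_const$hbar * 1e-32) /
    (40 * pi^2 * .pm_const$kB * temperature * (r_ang * 1e-10)^3)
}

# Dimensionless molecular alignment tensor induced by the susceptibility
# anisotropy: A = B0^2 Dchi / (15 mu0 kB T), Dchi in m^3.
.alignment_tensor <- function(chi_m, B0, temperature) {
  B0^2 * chi_m * 1e-32 / (15 * .pm_const$mu0 * .pm_const$kB * temperature)
}

# ---- single-record observables --------------------------------------------

#' Pseudocontact shift of a nucleus
#'
#' \eqn{\delta = \frac{1}{4\pi r^3}\,\hat r^T \Delta\chi\, \hat r}, with the
#' metal at the origin.
#'
#' @param chi `chi_tensor` or 3x3 matrix, 1e-32 m^3.
#' @param r_vec metal-to-nucleus vector, Angstrom.
#' @return shift in ppm.
#' @export
pcs_shift <- function(chi, r_vec) {
  r <- sqrt(sum(r_vec^2))
  if (r < 0.1) stop("nucleus unphysically close to the metal (< 0.1 A)")
  u <- r_vec / r
  m <- as_chi_matrix(chi)
  .pcs_scale(r) * drop(u %*% m %*% u)
}

#' Field-induced residual dipolar coupling
#'
#' Magnetic alignment by the susceptibility anisotropy partially averages the
#' dipolar coupling; the residual scales with the square of the field.
#'
#' @param chi `chi_tensor` or 3x3 matrix, 1e-32 m^3.
#' @param bond_vec internuclear vector, Angstrom (direction and, unless
#'   `effective_length` is given, length are used).
#' @param gamma1,gamma2 gyromagnetic ratios, rad s^-1 T^-1
#'   (see [gyromagnetic_ratio()]).
#' @param conditions [field_conditions()].
#' @param effective_length optional effective bond length in Angstrom that
#'   replaces the geometric length (librational correction).
#' @return coupling in Hz.
#' @export
rdc_coupling <- function(chi, bond_vec, gamma1, gamma2, conditions,
                         effective_length = NULL) {
  r <- sqrt(sum(bond_vec^2))
  if (r == 0) stop("zero internuclear vector")
  u <- bond_vec / r
  if (!is.null(effective_length)) r <- effective_length
  m <- as_chi_matrix(chi)
  .rdc_scale(gamma1, gamma2, conditions$B0, conditions$temperature, r) *
    drop(u %*% m %*% u)
}

#' Chemical-shift anisotropy tensor for RCSA prediction
#'
#' Principal shift values and the orientation of the principal axes in a local
#' peptide-plane frame. The frame convention is: `e1` = in-plane reference
#' bond direction (N->H for amide nitrogen, C'->O for carbonyl carbon),
#' `e3` = peptide-plane normal, `e2 = e3 x e1`. The first principal axis lies
#' in the plane at `in_plane_angle` degrees from `e1` (rotated toward `e2`),
#' the second is its in-plane perpendicular, the third is along `e3`.
#'
#' Defaults approximate solid-state/liquid-crystal consensus values for
#' backbone carbonyl and amide nuclei; both are configurable.
#'
#' @param nucleus `"C"` (carbonyl carbon) or `"N"` (amide nitrogen); other
#'   nucleus classes are not supported.
#' @param values three principal shift values in ppm
#'   (in-plane 1, in-plane 2, out-of-plane).
#' @param in_plane_angle orientation of the first principal axis, degrees.
#' @return object of class `csa_tensor`.
#' @export
csa_tensor <- function(nucleus = c("C", "N"), values = NULL,
                       in_plane_angle = NULL) {
  nucleus <- match.arg(nucleus)
  if (is.null(values)) {
    values <- if (nucleus == "C") c(244, 178, 90) else c(223, 55, 79)
  }
  if (is.null(in_plane_angle)) in_plane_angle <- if (nucleus == "C") 90 else 19
  if (length(values) != 3 || !all(is.finite(values)))
    stop("three finite principal values required")
  structure(list(nucleus = nucleus, values = values,
                 in_plane_angle = in_plane_angle), class = "csa_tensor")
}

#' Residual chemical shift anisotropy
#'
#' Alignment-induced shift contribution
#' \eqn{\delta_{rcsa} = \sum_{ij} A_{ij}\,\delta_{ij}} with the alignment
#' tensor \eqn{A = B_0^2 \Delta\chi / (15 \mu_0 k_B T)} and the traceless
#' part of the shift tensor, both in the molecular frame (the orientational
#' average \eqn{\langle \hat b^T \delta \hat b\rangle - \delta_{iso}} under
#' field-induced alignment). Additive to the PCS.
#'
#' @param chi `chi_tensor` or 3x3 matrix, 1e-32 m^3.
#' @param csa a [csa_tensor()].
#' @param peptide_frame 3x3 matrix whose columns are the local frame
#'   `(e1, e2, e3)` expressed in molecular coordinates (see [csa_tensor()]).
#' @param conditions [field_conditions()].
#' @return shift contribution in ppm.
#' @export
rcsa_shift <- function(chi, csa, peptide_frame, conditions) {
  if (!inherits(csa, "csa_tensor")) stop("csa must be a csa_tensor")
  if (max(abs(crossprod(peptide_frame) - diag(3))) > 1e-6)
    stop("peptide_frame must be orthonormal")
  phi <- csa$in_plane_angle * pi / 180
  u1 <- cos(phi) * peptide_frame[, 1] + sin(phi) * peptide_frame[, 2]
  u2 <- -sin(phi) * peptide_frame[, 1] + cos(phi) * peptide_frame[, 2]
  u3 <- peptide_frame[, 3]
  U <- cbind(u1, u2, u3)
  delta <- U %*% diag(csa$values) %*% t(U)
  dev <- delta - diag(3) * sum(diag(delta)) / 3
  A <- .alignment_tensor(as_chi_matrix(chi), conditions$B0,
                         conditions$temperature)
  sum(A * dev)
}

# ---- structure helpers -----------------------------------------------------

# Position of one atom (resno, name) in a structure data.frame; NULL if absent.
.atom_xyz <- function(structure, resno, name) {
  i <- which(structure$resno == resno & structure$elety == name)
  if (length(i) != 1) return(NULL)
  c(structure$x[i], structure$y[i], structure$z[i])
}

.gamma_for_atom <- function(name) {
  el <- substr(gsub("^[0-9]+", "", name), 1, 1)
  switch(el,
         H = .pm_const$gamma[["1H"]],
         N = .pm_const$gamma[["15N"]],
         C = .pm_const$gamma[["13C"]],
         stop("no gyromagnetic ratio for atom ", name))
}

# Local peptide-plane frame for RCSA at an amide N or carbonyl C.
.peptide_frame <- function(structure, resno, nucleus) {
  if (nucleus == "N") {
    p0 <- .atom_xyz(structure, resno, "N")
    p1 <- .atom_xyz(structure, resno, "H")
    p2 <- .atom_xyz(structure, resno, "CA")
  } else {
    p0 <- .atom_xyz(structure, resno, "C")
    p1 <- .atom_xyz(structure, resno, "O")
    p2 <- .atom_xyz(structure, resno, "CA")
  }
  if (is.null(p0) || is.null(p1) || is.null(p2)) return(NULL)
  e1 <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  aux <- p2 - p0
  n <- c(e1[2] * aux[3] - e1[3] * aux[2],
         e1[3] * aux[1] - e1[1] * aux[3],
         e1[1] * aux[2] - e1[2] * aux[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) return(NULL)
  e3 <- n / nn
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

#' Default prediction options
#'
#' @param rcsa include the RCSA contribution in chemical-shift predictions
#'   (carbonyl C and amide N only).
#' @param effective_lengths named vector of effective bond lengths in Angstrom
#'   by RDC type; listed types use only the bond orientation from the
#'   structure.
#' @param csa named list of [csa_tensor()]s keyed by nucleus class.
#' @return list of options for [predict_observables()].
#' @export
predict_options <- function(rcsa = TRUE,
                            effective_lengths = c(RDC_NH = 1.041,
                                                  RDC_CaHa = 1.117),
                            csa = list(C = csa_tensor("C"),
                                       N = csa_tensor("N"))) {
  list(rcsa = rcsa, effective_lengths = effective_lengths, csa = csa)
}

#' Forward-predict paramagnetic observables for a restraint table
#'
#' Each restraint row is resolved against the structure and predicted from
#' the tensor(s): PCS (with optional RCSA for amide N and carbonyl C), and
#' RDCs of types `RDC_NH`, `RDC_CaHa`, `RDC_HC'` and `RDC_C'Ca`. Records that
#' cannot be resolved yield `NA` and are listed in the `"skipped"` attribute
#' rather than silently dropped.
#'
#' @param structure atom table with columns `resno`, `elety`, `x`, `y`, `z`
#'   (see [read_structure()]).
#' @param metal_position metal coordinates, Angstrom.
#' @param chi a `chi_tensor`, or a named list of them keyed by the `metal`
#'   column of `restraints`.
#' @param restraints restraint table (see [read_restraints()]); only the
#'   geometry columns are used.
#' @param conditions a single [field_conditions()] or a named list per type
#'   as from [default_conditions()].
#' @param options [predict_options()].
#' @return numeric vector of predictions (ppm for shifts, Hz for couplings),
#'   with attributes `"skipped"` (data.frame of unresolved records) and
#'   `"rcsa_part"` (the RCSA share of each predicted shift, 0 for couplings).
#' @export
predict_observables <- function(structure, metal_position, chi, restraints,
                                conditions = default_conditions(),
                                options = predict_options()) {
  n <- nrow(restraints)
  out <- rep(NA_real_, n)
  rcsa_part <- numeric(n)
  skipped <- list()
  single_chi <- inherits(chi, "chi_tensor") || is.matrix(chi)
  for (i in seq_len(n)) {
    type <- restraints$type[i]
    chi_i <- if (single_chi) chi else chi[[restraints$metal[i]]]
    if (is.null(chi_i)) {
      skipped[[length(skipped) + 1]] <- data.frame(row = i, reason = "unknown metal")
      next
    }
    m <- as_chi_matrix(chi_i)
    if (type == "PCS") {
      p <- .atom_xyz(structure, restraints$residue[i], restraints$atom1[i])
      if (is.null(p)) {
        skipped[[length(skipped) + 1]] <- data.frame(row = i, reason = "atom not found")
        next
      }
      val <- pcs_shift(m, p - metal_position)
      if (isTRUE(options$rcsa)) {
        nuc <- substr(restraints$atom1[i], 1, 1)
        if (nuc %in% c("N", "C") && restraints$atom1[i] %in% c("N", "C")) {
          fr <- .peptide_frame(structure, restraints$residue[i], nuc)
          if (!is.null(fr)) {
            rc <- rcsa_shift(m, options$csa[[nuc]], fr, .cond_for(conditions, "PCS"))
            val <- val + rc
            rcsa_part[i] <- rc
          }
        }
      }
      out[i] <- val
    } else if (grepl("^RDC", type)) {
      p1 <- .atom_xyz(structure, restraints$residue[i], restraints$atom1[i])
      p2 <- .atom_xyz(structure, restraints$residue[i], restraints$atom2[i])
      if (is.null(p1) || is.null(p2)) {
        skipped[[length(skipped) + 1]] <- data.frame(row = i, reason = "atom not found")
        next
      }
      eff <- options$effective_lengths[type]
      out[i] <- rdc_coupling(m, p2 - p1,
                             .gamma_for_atom(restraints$atom1[i]),
                             .gamma_for_atom(restraints$atom2[i]),
                             .cond_for(conditions, type),
                             effective_length = if (is.na(eff)) NULL else eff)
    } else {
      skipped[[length(skipped) + 1]] <- data.frame(row = i, reason = paste("unknown type", type))
    }
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(row = integer(), reason = character())
  attr(out, "rcsa_part") <- rcsa_part
  out
}
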