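#' Read a PDB-format structure into an atom table
#'
#' Thin wrapper around [bio3d::read.pdb()] returning a plain data.frame.
#' Multi-model files expose a `model` column; selectors subset models,
#' chains and residues.
#'
#' @param path PDB file.
#' @param model model number(s) to keep (default all).
#' @param chain chain identifier(s) to keep.
#' @param resno residue numbers to keep.
#' @return data.frame with columns `model`, `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` (coordinates in Angstrom, author residue
#'   numbering).
#' @export
read_structure <- function(path, model = NULL, chain = NULL, resno = NULL) {
  lines <- readLines(path)
  coord <- grep("^(ATOM  |HETATM)", lines)
  for (i in coord) {
    fields <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed coordinate line at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nat <- nrow(pdb$atom)
  n_model <- nrow(pdb$xyz)
  out <- do.call(rbind, lapply(seq_len(n_model), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(model = m, chain = pdb$atom$chain, resno = pdb$atom$resno,
               resid = pdb$atom$resid, elety = pdb$atom$elety,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(model)) out <- out[out$model %in% model, , drop = FALSE]
  if (!is.null(chain)) out <- out[out$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) out <- out[out$resno %in% resno, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an atom table to PDB format
#'
#' @param structure atom table as from [read_structure()] (single model).
#' @param path output file.
#' @export
write_structure <- function(structure, path) {
  n <- nrow(structure)
  resid <- if (is.null(structure$resid)) rep("ALA", n) else structure$resid
  chain <- if (is.null(structure$chain)) rep("A", n) else structure$chain
  chain[is.na(chain)] <- "A"
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
                   resno = structure$resno, eleno = seq_len(n),
                   resid = resid, elety = structure$elety, chain = chain)
  invisible(path)
}

.restraint_types <- c("PCS", "RDC_NH", "RDC_CaHa", "RDC_HC'", "RDC_C'Ca")

#' Read or write a paramagnetic restraint table
#'
#' Tab- or whitespace-delimited text with header columns
#' `metal residue atom1 atom2 type value unit` and optionally `error`;
#' `atom2` is `.` for single-atom records. Shifts given in ppb are converted
#' to ppm on reading. Restraint types must be one of
#' `PCS, RDC_NH, RDC_CaHa, RDC_HC', RDC_C'Ca`.
#'
#' @param path file path.
#' @return `read_restraints()`: a restraint data.frame with values in
#'   ppm (shifts) or Hz (couplings).
#' @export
read_restraints <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          quote = "")
  need <- c("metal", "residue", "atom1", "atom2", "type", "value")
  if (!all(need %in% names(df)))
    stop("restraint table must have columns: ", paste(need, collapse = " "))
  if (nrow(df) == 0) {
    df$unit <- character(0)
    return(df)
  }
  bad <- setdiff(unique(df$type), .restraint_types)
  if (length(bad)) stop("unknown restraint type(s): ", paste(bad, collapse = ", "))
  df$atom2[df$atom2 %in% c(".", "")] <- NA
  key <- paste(df$metal, df$residue, df$atom1, df$atom2, df$type)
  if (anyDuplicated(key))
    stop("duplicated restraint keys: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  if (is.null(df$unit)) {
    df$unit <- ifelse(df$type == "PCS", "ppm", "Hz")
  }
  ppb <- df$unit == "ppb"
  df$value[ppb] <- df$value[ppb] / 1000
  df$unit[ppb] <- "ppm"
  df
}

#' @rdname read_restraints
#' @param restraints restraint data.frame.
#' @export
write_restraints <- function(restraints, path) {
  df <- restraints
  df$atom2[is.na(df$atom2)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
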