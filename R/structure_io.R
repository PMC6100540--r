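#' Anchor specification for the attack-geometry frame
#'
#' Names the two receptor atoms that define the attack geometry: the
#' catalytic-serine O-gamma and the phosphorus of the organophosphate
#' adduct. In human AChE the catalytic serine is residue 203; in human BChE
#' it is residue 198 (standard numbering).
#'
#' @param serine_residue_id Residue number of the catalytic serine.
#' @param serine_atom_name Atom name of its side-chain oxygen (default
#'   `"OG"`).
#' @param op_residue Residue selector for the phosphorus-bearing group:
#'   either a residue name (e.g. `"POX"`) or a residue number.
#' @param op_atom_name Atom name of the phosphorus (default `"P"`).
#' @return An object of class `anchor_spec`.
#' @export
anchor_spec <- function(serine_residue_id, serine_atom_name = "OG",
                        op_residue, op_atom_name = "P") {
  stopifnot(length(serine_residue_id) == 1L, length(op_residue) == 1L)
  structure(list(serine_residue_id = as.integer(serine_residue_id),
                 serine_atom_name = serine_atom_name,
                 op_residue = op_residue,
                 op_atom_name = op_atom_name),
            class = "anchor_spec")
}

#' Default anchors per enzyme
#'
#' Convenience constructor: catalytic serine 203 for AChE, 198 for BChE,
#' phosphorus taken from a residue named `"POX"` by default.
#'
#' @param enzyme `"AChE"` or `"BChE"`.
#' @param op_residue Residue selector for the organophosphate (default
#'   `"POX"`).
#' @return An `anchor_spec`.
#' @export
default_anchors <- function(enzyme = c("AChE", "BChE"), op_residue = "POX") {
  enzyme <- match.arg(enzyme)
  anchor_spec(serine_residue_id = if (enzyme == "AChE") 203L else 198L,
              op_residue = op_residue)
}

#' Oxime reactivator specification
#'
#' Describes one reactivator for geometry analysis: which ligand atoms are
#' the nucleophilic oxime oxygens (one for mono-oximes such as pralidoxime,
#' two for bis-oximes such as obidoxime), plus ionization metadata carried
#' through to reports but never interpreted.
#'
#' @param name Reactivator name.
#' @param oxime_oxygen_atoms Non-empty character vector of atom names, or
#'   integer vector of 1-based atom indices, locating the oxime oxygen(s).
#' @param ionization_label Free-text label (e.g. `"oximate"`, `"neutral"`).
#' @param net_charge Integer net charge (metadata only).
#' @return An object of class `oxime_spec`.
#' @export
oxime_spec <- function(name, oxime_oxygen_atoms, ionization_label = "",
                       net_charge = 0L) {
  if (length(oxime_oxygen_atoms) < 1L)
    stop("oxime_spec: at least one oxime oxygen atom is required")
  structure(list(name = name, oxime_oxygen_atoms = oxime_oxygen_atoms,
                 ionization_label = ionization_label,
                 net_charge = as.integer(net_charge)),
            class = "oxime_spec")
}

# Resolve one anchor in the receptor atom table; errors name the selector.
resolve_anchor <- function(atoms, residue_sel, atom_name, what) {
  hit <- if (is.numeric(residue_sel)) {
    atoms$residue_id == as.integer(residue_sel)
  } else {
    atoms$residue_name == residue_sel
  }
  hit <- hit & atoms$name == atom_name
  n <- sum(hit)
  sel_str <- paste(residue_sel, atom_name)
  if (n == 0L)
    stop(sprintf("anchor not found: %s (%s)", sel_str, what))
  if (n > 1L)
    stop(sprintf("ambiguous anchor: %s (%s) matches %d atoms",
                 sel_str, what, n))
  as.numeric(unlist(atoms[hit, c("x", "y", "z")]))
}

#' Read a receptor/adduct structure and resolve the attack anchors
#'
#' Parses a PDB file (via bio3d), drops waters and alternate locations
#' other than blank/"A", warns on insertion codes, and resolves the two
#' anchor atoms named by the `anchor_spec`. Coordinates are used in the PDB
#' frame as stored; no superposition is performed, since docking output
#' shares the receptor frame.
#'
#' @param path Path to a PDB file.
#' @param anchors An [anchor_spec()].
#' @param enzyme_label `"AChE"`, `"BChE"`, or any label carried to reports.
#' @return An object of class `receptor_complex`: list with `enzyme_label`,
#'   `atoms` (data.frame: name, element, x, y, z, residue_name, residue_id,
#'   chain), `serine_O` and `op_P` (3-vectors, Angstrom).
#' @export
read_receptor_complex <- function(path, anchors, enzyme_label = "AChE") {
  stopifnot(inherits(anchors, "anchor_spec"))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("could not parse PDB file '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  keep <- !(at$resid %in% c("HOH", "WAT", "DOD")) &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins & keep)) {
    warning("dropping ", sum(ins & keep), " atom(s) with insertion codes")
    keep <- keep & !ins
  }
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(name = at$elety, element = at$elesy,
                      x = at$x, y = at$y, z = at$z,
                      residue_name = at$resid, residue_id = at$resno,
                      chain = at$chain, stringsAsFactors = FALSE)
  serine_O <- resolve_anchor(atoms, anchors$serine_residue_id,
                             anchors$serine_atom_name, "catalytic serine O")
  op_P <- resolve_anchor(atoms, anchors$op_residue, anchors$op_atom_name,
                         "OP phosphorus")
  if (isTRUE(all.equal(serine_O, op_P)))
    stop("anchor atoms coincide; check the anchor specification")
  structure(list(enzyme_label = enzyme_label, atoms = atoms,
                 serine_O = serine_O, op_P = op_P),
            class = "receptor_complex")
}

#' @export
print.receptor_complex <- function(x, ...) {
  cat(sprintf("receptor_complex %s: %d atoms\n", x$enzyme_label,
              nrow(x$atoms)))
  cat(sprintf("  serine O: (%.3f, %.3f, %.3f)  OP P: (%.3f, %.3f, %.3f)\n",
              x$serine_O[1], x$serine_O[2], x$serine_O[3],
              x$op_P[1], x$op_P[2], x$op_P[3]))
  invisible(x)
}

# ---- pose ensembles -------------------------------------------------------

make_pose_ensemble <- function(complex_label, oxime, atom_names, elements,
                               coords_list, energy_total, energy_hbond) {
  n <- length(coords_list)
  stopifnot(n >= 1L)
  nat <- nrow(coords_list[[1L]])
  for (m in coords_list)
    if (nrow(m) != nat)
      stop("poses differ in atom count")
  if (!all(is.finite(energy_total)))
    stop("non-finite pose energies")
  poses <- lapply(seq_len(n), function(i) {
    list(pose_index = i, coords = coords_list[[i]],
         energy_total = energy_total[i],
         energy_hbond = if (length(energy_hbond)) energy_hbond[i] else NULL)
  })
  structure(list(complex_label = complex_label, oxime = oxime,
                 atom_names = atom_names, elements = elements,
                 poses = poses),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("pose_ensemble: %s in %s, %d poses x %d atoms\n",
              x$oxime$name, x$complex_label, length(x$poses),
              length(x$atom_names)))
  invisible(x)
}

# Parse our multi-model pose PDB dialect: MODEL blocks with per-model
# "REMARK 250 ENERGY_TOTAL <x>" / "ENERGY_HBOND <x>" lines and HETATM
# coordinates.  Column positions follow the PDB fixed-width convention.
read_pose_pdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1L] - 1L, length(lines))
  models <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    atom_lines <- blk[grepl("^(ATOM  |HETATM)", blk)]
    if (length(atom_lines) == 0L) stop("model without atom records")
    coords <- cbind(as.numeric(substr(atom_lines, 31, 38)),
                    as.numeric(substr(atom_lines, 39, 46)),
                    as.numeric(substr(atom_lines, 47, 54)))
    nm <- trimws(substr(atom_lines, 13, 16))
    el <- trimws(substr(atom_lines, 77, 78))
    et <- grep("REMARK 250 ENERGY_TOTAL", blk, value = TRUE)
    eh <- grep("REMARK 250 ENERGY_HBOND", blk, value = TRUE)
    num_from <- function(x) as.numeric(sub(".*ENERGY_\\w+\\s+", "", x))
    models[[k]] <- list(coords = coords, names = nm, elements = el,
                        e_total = if (length(et)) num_from(et[1]) else NA_real_,
                        e_hbond = if (length(eh)) num_from(eh[1]) else NA_real_)
  }
  models
}

# Parse an SDF pose file through ChemmineR.  Atom names are rebuilt from the
# element symbols with per-element counters (O, C, N, C, O -> O1 C1 N1 C2
# O2), matching the naming used by the PDB pose writer.
read_pose_sdf <- function(path, energy_tag) {
  sdf <- ChemmineR::read.SDFset(path)
  models <- vector("list", length(sdf))
  for (k in seq_along(models)) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    coords <- unname(ab[, 1:3, drop = FALSE])
    el <- sub("_.*$", "", rownames(ab))
    nm <- paste0(el, stats::ave(seq_along(el), el, FUN = seq_along))
    db <- ChemmineR::datablock(sdf[[k]])
    e_total <- if (energy_tag %in% names(db))
      as.numeric(db[[energy_tag]]) else NA_real_
    e_hbond <- if ("ENERGY_HBOND" %in% names(db))
      as.numeric(db[["ENERGY_HBOND"]]) else NA_real_
    models[[k]] <- list(coords = coords, names = nm, elements = el,
                        e_total = e_total, e_hbond = e_hbond)
  }
  models
}

#' Read a docking pose ensemble
#'
#' Reads a multi-model PDB file (energies in per-model
#' `REMARK 250 ENERGY_TOTAL` / `ENERGY_HBOND` records) or an SDF file
#' (energies in named SD tags, default `ENERGY`), optionally overriding
#' energies from a sidecar CSV with columns
#' `pose_index,energy_total[,energy_hbond]`. Poses keep file order; all
#' models must share atom count and order.
#'
#' @param path Pose file (`.pdb` or `.sdf`; format inferred from the
#'   extension).
#' @param oxime An [oxime_spec()].
#' @param complex_label Label of the receptor complex the poses belong to.
#' @param energy_csv Optional sidecar CSV with per-pose energies.
#' @param energy_tag SD tag holding the total energy in SDF input.
#' @param no_energy If `TRUE`, missing energies are tolerated and set to 0
#'   (every pose is then low-energy under any finite window).
#' @return A `pose_ensemble`.
#' @export
read_pose_ensemble <- function(path, oxime, complex_label = "complex",
                               energy_csv = NULL, energy_tag = "ENERGY",
                               no_energy = FALSE) {
  stopifnot(inherits(oxime, "oxime_spec"))
  if (!file.exists(path)) stop("pose file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  models <- switch(ext,
    sdf = read_pose_sdf(path, energy_tag),
    pdb = read_pose_pdb(path),
    stop("unsupported pose file extension: ", ext))
  if (length(models) == 0L) stop("no poses in file: ", path)
  nat <- vapply(models, function(m) nrow(m$coords), 0L)
  if (length(unique(nat)) != 1L)
    stop("models differ in atom count: ", paste(unique(nat), collapse = ", "))
  e_total <- vapply(models, function(m) m$e_total, 0)
  e_hbond <- vapply(models, function(m) m$e_hbond, 0)
  if (!is.null(energy_csv)) {
    side <- utils::read.csv(energy_csv, stringsAsFactors = FALSE)
    need <- c("pose_index", "energy_total")
    if (!all(need %in% names(side)))
      stop("energy sidecar lacks columns: ",
           paste(setdiff(need, names(side)), collapse = ", "))
    m <- match(seq_along(models), side$pose_index)
    if (anyNA(m)) stop("energy sidecar does not cover every pose")
    e_total <- side$energy_total[m]
    e_hbond <- if ("energy_hbond" %in% names(side))
      side$energy_hbond[m] else rep(NA_real_, length(models))
  }
  if (anyNA(e_total)) {
    if (!no_energy)
      stop("missing pose energies; supply a sidecar CSV or set no_energy")
    e_total[is.na(e_total)] <- 0
  }
  make_pose_ensemble(complex_label, oxime, models[[1L]]$names,
                     models[[1L]]$elements,
                     lapply(models, function(m) m$coords),
                     e_total, e_hbond)
}

#' Write a pose ensemble
#'
#' Writes the multi-model PDB or SDF dialect that [read_pose_ensemble()]
#' accepts. PDB coordinates are stored to three decimals (the format's
#' resolution); energies round-trip exactly through the REMARK/SD-tag text.
#'
#' @param ensemble A `pose_ensemble`.
#' @param path Output file (`.pdb` or `.sdf`).
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") write_pose_pdb(ensemble, path)
  else if (ext == "sdf") write_pose_sdf(ensemble, path)
  else stop("unsupported pose file extension: ", ext)
  invisible(path)
}

write_pose_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- ensemble$atom_names
  el <- ensemble$elements
  for (p in ensemble$poses) {
    writeLines(sprintf("MODEL %8d", p$pose_index), con)
    # full double precision so energies round-trip exactly
    writeLines(sprintf("REMARK 250 ENERGY_TOTAL %.17g", p$energy_total), con)
    if (!is.null(p$energy_hbond) && is.finite(p$energy_hbond))
      writeLines(sprintf("REMARK 250 ENERGY_HBOND %.17g", p$energy_hbond),
                 con)
    for (i in seq_len(nrow(p$coords))) {
      writeLines(sprintf(
        "HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, substr(nm[i], 1, 4), " ", "LIG", "A", 1L, " ",
        p$coords[i, 1], p$coords[i, 2], p$coords[i, 3], 1, 0, el[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_pose_sdf <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- ensemble$elements
  nat <- length(el)
  # chain bonds keep readers that dislike bond-free molecules happy
  nb <- max(0L, nat - 1L)
  for (p in ensemble$poses) {
    writeLines(c(ensemble$oxime$name, "  nacscan", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nat, nb),
               con)
    for (i in seq_len(nat))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         p$coords[i, 1], p$coords[i, 2], p$coords[i, 3],
                         el[i]), con)
    for (i in seq_len(nb))
      writeLines(sprintf("%3d%3d  1  0  0  0  0", i, i + 1L), con)
    writeLines("M  END", con)
    writeLines(c("> <ENERGY>", sprintf("%.17g", p$energy_total), ""), con)
    if (!is.null(p$energy_hbond) && is.finite(p$energy_hbond))
      writeLines(c("> <ENERGY_HBOND>",
                   sprintf("%.17g", p$energy_hbond), ""), con)
    writeLines("$$$$", con)
  }
}

#' Read a per-pose geometry table
#'
#' Reads a CSV of precomputed pose geometries (columns `pose_index`,
#' `d_op`, `theta_opo`, `energy`), validating that distances are
#' non-negative and angles lie in \[0, 180\] degrees. This allows published
#' per-pose geometry to enter the NAC pipeline without coordinates.
#'
#' @param path CSV file path.
#' @return A data.frame with the four columns, rows in file order.
#' @export
read_geometry_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pose_index", "d_op", "theta_opo", "energy")
  if (!all(need %in% names(tab)))
    stop("geometry table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  bad_d <- which(!is.finite(tab$d_op) | tab$d_op < 0)
  if (length(bad_d))
    stop("invalid d_op at row ", bad_d[1L], ": ", tab$d_op[bad_d[1L]])
  bad_t <- which(!is.finite(tab$theta_opo) |
                   tab$theta_opo < 0 | tab$theta_opo > 180)
  if (length(bad_t))
    stop("invalid theta_opo at row ", bad_t[1L], ": ",
         tab$theta_opo[bad_t[1L]])
  tab[, need]
}
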