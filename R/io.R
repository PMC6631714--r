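# File I/O: Mol2/PDB sites (bio3d), SDF/Mol2 pose ensembles (ChemmineR /
# bio3d), CSV node tables and key-atom lists.  All structures are assumed
# pre-aligned in one common site frame; no superposition is ever performed.

#' @importClassesFrom ChemmineR SDF SDFset
NULL

mol2_element <- function(elety) sub("\\..*$", "", elety)

# bio3d mol2 reader with the benign bond-less warning muffled.
read_mol2_quiet <- function(path) {
  withCallingHandlers(bio3d::read.mol2(path),
    warning = function(w) {
      if (grepl("No BOND records", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Read a protein site structure
#'
#' Mol2 input must carry partial charges (an all-zero charge column is
#' accepted with a warning).  PDB input has no charges: a Gasteiger-type
#' fallback assignment is run through OpenBabel and recorded in the
#' provenance (`charge_source = "gasteiger-openbabel"`), with a warning.
#'
#' @param path input file.
#' @param format `"mol2"` or `"pdb"`.
#' @return a [site_model()] with radii and H-bond roles assigned and an
#'   empty key-atom list (run [select_key_atoms()] to fill it).
#' @export
read_site <- function(path, format = c("mol2", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("site file not found: %s", path)
  prov <- list(path = path, format = format, charge_source = "file")
  if (format == "pdb") {
    # fallback charge assigner: obabel PDB -> Mol2 with Gasteiger charges
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp), add = TRUE)
    ok <- suppressWarnings(system2("obabel",
      c("-ipdb", shQuote(path), "-omol2", "-O", shQuote(tmp),
        "--partialcharge", "gasteiger"),
      stdout = FALSE, stderr = FALSE))
    if (ok != 0 || !file.exists(tmp) || !file.size(tmp))
      stopf("PDB conversion/charge assignment failed for %s", path)
    warnf("PDB input '%s' has no partial charges: Gasteiger-type fallback assignment applied",
          basename(path))
    prov$charge_source <- "gasteiger-openbabel"
    path <- tmp
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("@<TRIPOS>ATOM", lines, fixed = TRUE)))
      stopf("format error in %s: no @<TRIPOS>ATOM record (line %d reached end of header)",
            path, length(lines))
  }
  m <- tryCatch(read_mol2_quiet(path),
                error = function(e) stopf("format error parsing %s: %s", path,
                                          conditionMessage(e)))
  if (all(is.na(m$atom$charge)))
    stopf("charges absent in Mol2 file %s", path)
  if (all(m$atom$charge == 0))
    warnf("all partial charges are zero in %s", path)
  atoms <- atom_table(element = mol2_element(m$atom$elety),
                      coords = cbind(m$atom$x, m$atom$y, m$atom$z),
                      partial_charge = m$atom$charge,
                      name = m$atom$elena)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0)
    bonds <- data.frame(i = m$bond$origin, j = m$bond$target,
                        order = m$bond$type, stringsAsFactors = FALSE)
  atoms <- assign_hbond_roles(atoms, bonds)
  site_model(atoms, provenance = prov)
}

#' Read docked ligand poses
#'
#' SDF records carry their energy in a data field (default tag `"energy"`).
#' Mol2 has no standard tag, so energies come from a sidecar CSV with
#' columns `conformer_id, energy`.
#'
#' @param path multi-record SDF or Mol2 file.
#' @param format `"sdf"` or `"mol2"`.
#' @param energy_tag SDF data-field name holding the pose energy.
#' @param energy_csv sidecar CSV path (required for Mol2).
#' @param ligand_id ligand identifier; defaults to the first record's name.
#' @param run_id docking-run identifier attached to every pose.
#' @return list of [pose()] objects in file order.
#' @export
read_poses <- function(path, format = c("sdf", "mol2"), energy_tag = "energy",
                       energy_csv = NULL, ligand_id = NULL, run_id = "run1") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("pose file not found: %s", path)
  if (!file.size(path) || !length(readLines(path, warn = FALSE, n = 1))) {
    warnf("empty pose file: %s", path)
    return(list())
  }
  if (format == "sdf") {
    sdfs <- ChemmineR::read.SDFset(path)
    poses <- vector("list", length(sdfs))
    for (i in seq_along(sdfs)) {
      rec <- sdfs[[i]]
      ab <- ChemmineR::atomblock(rec)
      db <- ChemmineR::datablock(rec)
      if (!(energy_tag %in% names(db)))
        stopf("record %d of %s is missing energy tag '%s'", i, path, energy_tag)
      lid <- if (!is.null(ligand_id)) ligand_id
             else if ("ligand_id" %in% names(db)) unname(db[["ligand_id"]])
             else unname(ChemmineR::header(rec)["Molecule_Name"])
      cid <- if ("conformer_id" %in% names(db)) unname(db[["conformer_id"]])
             else sprintf("%s_c%03d", lid, i)
      poses[[i]] <- pose(lid, cid, ab[, 1:3, drop = FALSE],
                         as.numeric(db[[energy_tag]]), run_id = run_id)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    starts <- grep("@<TRIPOS>MOLECULE", txt, fixed = TRUE)
    if (!length(starts)) stopf("format error in %s: no @<TRIPOS>MOLECULE record", path)
    if (is.null(energy_csv))
      stopf("Mol2 pose input requires an energy sidecar CSV (conformer_id, energy)")
    etab <- utils::read.csv(energy_csv, stringsAsFactors = FALSE)
    ends <- c(starts[-1] - 1, length(txt))
    poses <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      tmp <- tempfile(fileext = ".mol2")
      writeLines(txt[starts[i]:ends[i]], tmp)
      m <- read_mol2_quiet(tmp)
      unlink(tmp)
      cid <- m$name
      lid <- if (!is.null(ligand_id)) ligand_id else sub("_c[0-9]+$", "", cid)
      row <- match(cid, etab$conformer_id)
      if (is.na(row)) stopf("record %d ('%s') of %s has no energy in %s",
                            i, cid, path, energy_csv)
      poses[[i]] <- pose(lid, cid, cbind(m$atom$x, m$atom$y, m$atom$z),
                         etab$energy[row], run_id = run_id)
    }
  }
  # atom-count consistency per ligand: RMSD would be ill-defined otherwise
  lids <- vapply(poses, function(p) p$ligand_id, "")
  for (l in unique(lids)) {
    cnt <- vapply(poses[lids == l], function(p) nrow(p$coords), 0L)
    if (length(unique(cnt)) != 1)
      stopf("ligand '%s' in %s has records with differing atom counts (%s)",
            l, path, paste(unique(cnt), collapse = ","))
  }
  poses
}

#' Write a site to Mol2
#'
#' @param site a [site_model()].
#' @param path output path.
#' @param bonds optional bond data.frame (i, j, order).
#' @export
write_site_mol2 <- function(site, path, bonds = NULL) {
  a <- site$atoms
  n <- nrow(a)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  m <- structure(list(
    atom = data.frame(eleno = seq_len(n), elena = a$name, x = a$x, y = a$y,
                      z = a$z, elety = a$element, resno = 1, resid = "SITE",
                      charge = a$partial_charge, statbit = NA,
                      stringsAsFactors = FALSE),
    bond = if (nb) data.frame(id = seq_len(nb), origin = bonds$i,
                              target = bonds$j, type = as.character(bonds$order),
                              statbit = NA, stringsAsFactors = FALSE) else NULL,
    substructure = NULL,
    xyz = as.numeric(t(atom_coords(a))),
    info = c(n, nb, 1, NA, NA), name = "site"), class = "mol2")
  bio3d::write.mol2(m, file = path)
  invisible(path)
}

# Build a ChemmineR SDF object for one pose of a ligand.
pose_to_sdf <- function(p, lig, extra = character(0)) {
  a <- lig$atoms
  n <- nrow(a)
  ab <- cbind(p$coords, 0)
  rownames(ab) <- paste(a$element, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", "C5")
  bb <- as.matrix(lig$bonds[, c("i", "j", "order")])
  colnames(bb) <- c("C1", "C2", "C3")
  hd <- c(Molecule_Name = p$ligand_id, Source = "gtmdock", Comment = "",
          Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                n, nrow(bb)))
  db <- c(energy = fmt_num(p$energy), conformer_id = p$conformer_id,
          ligand_id = p$ligand_id, run_id = p$run_id, extra)
  methods::new("SDF", header = hd, atomblock = ab, bondblock = bb,
               datablock = db)
}

#' Write a pose ensemble to SDF
#'
#' One V2000 record per pose, energy and identifiers stored as data fields.
#'
#' @param pool a [pose_pool()] (or list of poses).
#' @param lig the [ligand()] supplying elements and bonds.
#' @param path output path.
#' @export
write_poses_sdf <- function(pool, lig, path) {
  poses <- if (inherits(pool, "PosePool")) pool$poses else pool
  sdfl <- lapply(poses, pose_to_sdf, lig = lig)
  ids <- vapply(poses, function(p) p$conformer_id, "")
  set <- methods::new("SDFset", SDF = sdfl, ID = ids)
  ChemmineR::write.SDF(set, file = path, cid = TRUE)
  invisible(path)
}

#' Write a landscape node table to CSV
#'
#' Columns: node_index, grid_x, grid_y, density, then `value` (regression /
#' fuzzy landscapes) or one `density_<class>` column per class.  Undefined
#' node values are written as empty cells; densities are always written.
#' Finite values round-trip bit-exact through [read_node_table()].
#'
#' @param landscape a colored [color_regression()] / [color_class()] landscape.
#' @param path output CSV path.
#' @export
write_node_table <- function(landscape, path) {
  if (!inherits(landscape, "Landscape")) stopf("not a Landscape object")
  grid <- landscape$model$nodes
  df <- data.frame(node_index = seq_len(nrow(grid)),
                   grid_x = fmt_num(grid[, 1], 17),
                   grid_y = fmt_num(grid[, 2], 17),
                   density = fmt_num(landscape$node_density, 17),
                   stringsAsFactors = FALSE)
  if (landscape$type == "class") {
    for (cl in colnames(landscape$class_density))
      df[[paste0("density_", cl)]] <- fmt_num(landscape$class_density[, cl], 17)
  }
  v <- landscape$node_values
  v[!landscape$defined] <- NA
  df$value <- fmt_num(v, 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a node table written by [write_node_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns; empty cells become `NA`.
#' @export
read_node_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the key-atom list of a site
#'
#' Plain text, one 1-based atom index per line.
#'
#' @param site a [site_model()] with key atoms selected.
#' @param path output path.
#' @export
write_key_atoms <- function(site, path) {
  writeLines(as.character(site$key_atom_indices), path)
  invisible(path)
}

#' Write a CF/Hy matrix to CSV
#'
#' Rows are poses (`conformer_id` column first), columns are slot names.
#'
#' @param X descriptor matrix with rownames = conformer ids.
#' @param path output path.
#' @export
write_cf_csv <- function(X, path) {
  df <- data.frame(conformer_id = rownames(X), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- fmt_num(X[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CF/Hy matrix written by [write_cf_csv()]
#' @param path CSV path.
#' @return numeric matrix with conformer ids as rownames.
#' @export
read_cf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Write a descriptor matrix in SVM-light sparse format
#'
#' `<label> <col>:<value> ...` with zero entries omitted; labels default 0.
#'
#' @param X descriptor matrix.
#' @param path output path.
#' @param labels optional numeric labels (length nrow).
#' @export
write_svmlight <- function(X, path, labels = NULL) {
  if (is.null(labels)) labels <- rep(0, nrow(X))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(X))) {
    nz <- which(X[i, ] != 0)
    writeLines(paste(fmt_num(labels[i]),
                     paste(nz, fmt_num(X[i, nz]), sep = ":", collapse = " ")),
               con)
  }
  invisible(path)
}
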