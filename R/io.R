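#' Read a crystal structure from file
#'
#' Dispatches on format: small-molecule CIF (core dialect: `_cell_*`,
#' `_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`,
#' `_atom_site_*` loops) or PDB (ATOM/HETATM/CRYST1).  Fractional CIF
#' coordinates are retained as read; conversion is deferred to
#' [as_cartesian()] or [coords()].
#'
#' @param path File path.
#' @param format `"cif"`, `"pdb"`, or `"auto"` (by extension).
#' @return A [crystal_structure()].
#' @export
read_structure <- function(path, format = c("auto", "cif", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, cif = read_cif(path), pdb = read_pdb(path))
}

# ---- CIF ------------------------------------------------------------------

# Tokenise one CIF data line, honouring single/double quotes.
cif_tokens <- function(line) {
  toks <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

cif_number <- function(s) {
  # strip an appended esd such as 15.435(2), tolerate '.' and '?'
  s <- gsub("\\([0-9]+\\)$", "", s)
  if (s %in% c(".", "?")) return(NA_real_)
  suppressWarnings(as.numeric(s))
}

#' Read a small-molecule CIF file
#'
#' @param path File path.
#' @return A [crystal_structure()] in fractional coordinates (or Cartesian
#'   if the file carries `_atom_site_Cartn_*`).
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  items <- list()      # single tag -> value
  loops <- list()      # list of (tags, rows)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (tolower(line) == "loop_") {
      tags <- character(0)
      i <- i + 1L
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, tolower(trimws(strsplit(trimws(lines[i]), "\\s+")[[1]][1])))
        i <- i + 1L
      }
      vals <- character(0)
      first_row <- i
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (l2 == "" || startsWith(l2, "#")) { i <- i + 1L; next }
        if (grepl("^(_|loop_|data_)", l2, ignore.case = TRUE)) break
        if (l2 == ";") {  # multi-line text field: swallow
          i <- i + 1L
          while (i <= n && trimws(lines[i]) != ";") i <- i + 1L
          i <- i + 1L
          vals <- c(vals, "?")
          next
        }
        vals <- c(vals, cif_tokens(l2))
        i <- i + 1L
      }
      if (length(tags) && length(vals)) {
        if (length(vals) %% length(tags) != 0)
          stop(sprintf("malformed CIF loop starting near line %d (%s): %d values for %d tags",
                       first_row, tags[1], length(vals), length(tags)))
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tags
        loops[[length(loops) + 1L]] <- m
      }
      next
    }
    if (startsWith(line, "_")) {
      toks <- cif_tokens(line)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        items[[tag]] <- paste(toks[-1], collapse = " ")
      } else if (i + 1L <= n && trimws(lines[i + 1L]) == ";") {
        i <- i + 1L
        while (i <= n && !(trimws(lines[i]) == ";" && i > 1)) {
          i <- i + 1L
          if (i <= n && trimws(lines[i]) == ";") break
        }
        items[[tag]] <- "?"
      } else if (i + 1L <= n) {
        items[[tag]] <- trimws(lines[i + 1L])
        i <- i + 1L
      }
      i <- i + 1L
      next
    }
    i <- i + 1L  # data_ block headers and anything else
  }

  cell <- NULL
  cl <- unname(vapply(
    c("_cell_length_a", "_cell_length_b", "_cell_length_c",
      "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"),
    function(t) if (is.null(items[[t]])) NA_real_ else cif_number(items[[t]]),
    numeric(1)))
  if (all(is.finite(cl)))
    cell <- unit_cell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])

  symops <- list()
  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  for (lp in loops) {
    hit <- intersect(sym_tags, colnames(lp))
    if (length(hit))
      symops <- c(symops, lapply(lp[, hit[1]], parse_symop))
  }
  for (t in sym_tags)   # non-loop single operator
    if (!is.null(items[[t]])) symops <- c(symops, list(parse_symop(items[[t]])))

  sg <- items[["_symmetry_space_group_name_h-m"]]
  if (is.null(sg)) sg <- items[["_space_group_name_h-m_alt"]]
  if (is.null(sg)) sg <- NA_character_

  atom_loop <- NULL
  for (lp in loops)
    if ("_atom_site_label" %in% colnames(lp) &&
        !any(grepl("aniso", colnames(lp)))) { atom_loop <- lp; break }
  if (is.null(atom_loop))
    stop("malformed CIF: no _atom_site_ loop with _atom_site_label found in ", path)

  getcol <- function(tag) if (tag %in% colnames(atom_loop)) atom_loop[, tag] else NULL
  lab <- getcol("_atom_site_label")
  frac <- cbind(x = vapply(getcol("_atom_site_fract_x"), cif_number, 0),
                y = vapply(getcol("_atom_site_fract_y"), cif_number, 0),
                z = vapply(getcol("_atom_site_fract_z"), cif_number, 0))
  coord_system <- "fractional"
  if (!length(frac) || is.null(getcol("_atom_site_fract_x"))) {
    frac <- cbind(x = vapply(getcol("_atom_site_cartn_x"), cif_number, 0),
                  y = vapply(getcol("_atom_site_cartn_y"), cif_number, 0),
                  z = vapply(getcol("_atom_site_cartn_z"), cif_number, 0))
    coord_system <- "cartesian"
  }
  if (is.null(frac) || !nrow(frac))
    stop("malformed CIF: _atom_site_ loop has no coordinates (", path, ")")
  el <- getcol("_atom_site_type_symbol")
  if (is.null(el)) el <- gsub("[^A-Za-z].*$", "", lab)
  el <- gsub("[0-9+-]+$", "", el)
  occ <- getcol("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, length(lab)) else {
    v <- vapply(occ, cif_number, 0); v[!is.finite(v)] <- 1; v
  }
  alt <- getcol("_atom_site_disorder_group")
  alt <- if (is.null(alt)) rep(NA_character_, length(lab)) else {
    a <- as.character(alt); a[a %in% c(".", "?")] <- NA_character_; a
  }
  atoms <- data.frame(label = as.character(lab), element = as.character(el),
                      x = unname(frac[, 1]), y = unname(frac[, 2]),
                      z = unname(frac[, 3]),
                      occupancy = unname(pmin(occ, 1)), residue_id = 1L,
                      alt_site = alt, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  crystal_structure(atoms, cell = cell, symops = symops, space_group = sg,
                    coord_system = coord_system)
}

# ---- PDB ------------------------------------------------------------------

#' Read a PDB file as a crystal structure
#'
#' Atom records are parsed with bio3d; the CRYST1 record (if any) supplies
#' the unit cell.  Coordinates are Cartesian Angstrom.
#'
#' @param path File path.
#' @return A [crystal_structure()].
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- trimws(at$elesy)
  missing_el <- is.na(el) | el == ""
  el[missing_el] <- gsub("[0-9'*]+.*$", "", trimws(at$elety[missing_el]))
  atoms <- data.frame(label = trimws(at$elety), element = el,
                      x = at$x, y = at$y, z = at$z,
                      occupancy = ifelse(is.na(at$o) | at$o <= 0, 1, pmin(at$o, 1)),
                      residue_id = at$resno,
                      alt_site = ifelse(is.na(at$alt) | at$alt == "", NA_character_, at$alt),
                      stringsAsFactors = FALSE)
  cell <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    f <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                      substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
    if (all(is.finite(f)) && all(f[1:3] > 0) && !all(f[1:3] == 1))
      cell <- unit_cell(f[1], f[2], f[3], f[4], f[5], f[6])
  }
  crystal_structure(atoms, cell = cell, coord_system = "cartesian")
}

#' Write a structure to PDB
#'
#' Atom names longer than the four characters the PDB format allows are
#' replaced by `<element><serial>`; elements, coordinates, occupancies and
#' residue numbers survive a round trip.
#'
#' @param structure A [crystal_structure()]; converted to Cartesian first.
#' @param path Output path.
#' @export
write_structure <- function(structure, path) {
  structure <- as_cartesian(structure)
  xyz <- coords(structure)
  lab <- structure$atoms$label
  long <- nchar(lab) > 4
  lab[long] <- paste0(structure$atoms$element[long], which(long))
  lab <- substr(lab, 1, 4)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = rep("HETATM", nrow(xyz)),
                   resno = structure$atoms$residue_id,
                   resid = rep("CDU", nrow(xyz)),
                   elety = lab,
                   elesy = structure$atoms$element,
                   o = structure$atoms$occupancy)
  invisible(path)
}

# ---- trajectories ---------------------------------------------------------

#' Trajectory container
#'
#' Ordered coordinate frames over a fixed atom set.
#'
#' @param frames An `n_atoms x 3 x n_frames` array, or a list of `n x 3`
#'   matrices, Cartesian Angstrom.
#' @param timestep Time per frame in ps (> 0).
#' @param atoms Optional atom metadata data.frame (shared by all frames).
#' @return An object of class `"cd_trajectory"`.
#' @export
trajectory <- function(frames, timestep = 1, atoms = NULL) {
  if (is.list(frames)) {
    ns <- vapply(frames, nrow, 0L)
    if (length(unique(ns)) > 1)
      stop("inconsistent atom count across frames (first mismatch at frame ",
           which(ns != ns[1])[1], ")")
    frames <- array(unlist(lapply(frames, t)), dim = c(3, ns[1], length(ns)))
    frames <- aperm(frames, c(2, 1, 3))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3)
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be > 0")
  structure(list(coords = frames, timestep = timestep, atoms = atoms),
            class = "cd_trajectory")
}

#' @export
print.cd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms, %g ps/frame\n", d[3], d[1],
              x$timestep))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return An `n x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a trajectory from a text format
#'
#' Multi-model PDB (MODEL/ENDMDL) or multi-frame XYZ.  Neither format
#' carries a timestep, so it is taken from the argument.
#'
#' @param path File path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param timestep ps per frame (default 1).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            timestep = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), xyz = "xyz", "pdb")
  if (format == "xyz") return(read_xyz_trajectory(path, timestep))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3, byrow = TRUE))
  atoms <- data.frame(label = trimws(pdb$atom$elety),
                      element = trimws(pdb$atom$elesy),
                      residue_id = pdb$atom$resno, stringsAsFactors = FALSE)
  if (nrow(atoms) != nat) atoms <- atoms[seq_len(nat), , drop = FALSE]
  trajectory(frames, timestep = timestep, atoms = atoms)
}

read_xyz_trajectory <- function(path, timestep = 1) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elements <- NULL
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    k <- k + 1L
    block <- lines[(i + 2L):(i + 1L + nat)]
    if (length(block) < nat || any(is.na(block)))
      stop("inconsistent atom count: frame ", k, " is truncated")
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("inconsistent atom count across frames (frame ", k, ")")
    frames[[k]] <- xyz
    i <- i + 2L + nat
  }
  trajectory(frames, timestep = timestep,
             atoms = data.frame(label = paste0(elements, seq_along(elements)),
                                element = elements, stringsAsFactors = FALSE))
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are printed with six decimals; reading the file back
#' reproduces them exactly at that precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  el <- if (!is.null(traj$atoms)) traj$atoms$element else
    rep("C", dim(traj$coords)[1])
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, k)
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", el,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
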