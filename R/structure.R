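#' Unit cell
#'
#' Construct a crystallographic unit cell from its six lattice parameters.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `"unit_cell"`: a named list with the six
#'   parameters and the cell volume in cubic Angstrom.
#' @examples
#' unit_cell(10, 10, 10)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  vol2 <- 1 - sum(ca^2) + 2 * prod(ca)
  if (vol2 <= 0) stop("degenerate unit cell: non-positive volume")
  cell <- list(a = a, b = b, c = c,
               alpha = alpha, beta = beta, gamma = gamma,
               volume = a * b * c * sqrt(vol2))
  class(cell) <- "unit_cell"
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Orthogonalisation matrix of a unit cell
#'
#' Matrix `M` such that `cart = M %*% frac`.  Convention: the `a` axis lies
#' along Cartesian x and `b` lies in the xy-plane (the standard PDB/Cambridge
#' setting), which fixes the representation uniquely.
#'
#' @param cell A [unit_cell()].
#' @return A 3 x 3 numeric matrix (Angstrom).
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac A length-3 vector or an n x 3 matrix of fractional
#'   coordinates.
#' @return Cartesian coordinates (Angstrom), same shape as the input.
#' @seealso [cart_to_frac()]
#' @export
frac_to_cart <- function(cell, frac) {
  M <- orthogonalization_matrix(cell)
  if (is.matrix(frac)) t(M %*% t(frac)) else as.numeric(M %*% frac)
}

#' Cartesian to fractional coordinates
#'
#' Inverse of [frac_to_cart()] under the same orthogonalisation convention.
#'
#' @inheritParams frac_to_cart
#' @param cart A length-3 vector or n x 3 matrix of Cartesian coordinates.
#' @export
cart_to_frac <- function(cell, cart) {
  Mi <- solve(orthogonalization_matrix(cell))
  if (is.matrix(cart)) t(Mi %*% t(cart)) else as.numeric(Mi %*% cart)
}

#' Symmetry operator
#'
#' A crystallographic symmetry operation `x' = R x + t` in fractional
#' coordinates.  Translations are stored exactly as integer twelfths to keep
#' screw/glide components drift-free under repeated application.
#'
#' @param rotation Integer 3 x 3 matrix with determinant +1 or -1.
#' @param translation Length-3 translation; each component must be an
#'   integer multiple of 1/12.
#' @param label Optional text form (e.g. `"-x,y+1/2,-z"`).
#' @return An object of class `"symop"`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0), label = NULL) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(abs(det(rotation)) - 1) > 1e-9)
    stop("symmetry rotation must have determinant +1 or -1")
  t12 <- round(translation * 12)
  if (max(abs(translation * 12 - t12)) > 1e-6)
    stop("symmetry translations must be multiples of 1/12")
  op <- list(rotation = rotation, translation_12 = as.integer(t12),
             label = label)
  class(op) <- "symop"
  op
}

#' @export
print.symop <- function(x, ...) {
  cat("Symmetry operation:", if (!is.null(x$label)) x$label else
    paste(deparse(symop_translation(x)), collapse = ""), "\n")
  invisible(x)
}

#' @rdname symop
#' @param op A `"symop"`.
#' @export
symop_translation <- function(op) op$translation_12 / 12

#' Parse a symmetry operator string
#'
#' Converts a CIF-style operator such as `"-x, y+1/2, -z"` into a [symop()].
#'
#' @param text Operator string; three comma-separated terms in x, y, z.
#' @return A `"symop"`.
#' @examples
#' parse_symop("-x, y+1/2, -z")
#' @export
parse_symop <- function(text) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(text)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have 3 components: ", text)
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenise into signed terms: x/y/z with coefficient, or rational numbers
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (grepl("[xyz]", body)) {
        axis <- match(regmatches(body, regexpr("[xyz]", body)), c("x", "y", "z"))
        coef <- sub("\\*?[xyz]", "", body)
        coefv <- if (coef == "") 1 else parse_rational(coef)
        R[i, axis] <- R[i, axis] + sign * coefv
      } else {
        tr[i] <- tr[i] + sign * parse_rational(body)
      }
    }
  }
  symop(R, tr, label = gsub(" ", "", text))
}

parse_rational <- function(s) {
  if (grepl("/", s)) {
    nd <- as.numeric(strsplit(s, "/")[[1]])
    nd[1] / nd[2]
  } else as.numeric(s)
}

#' Crystal structure
#'
#' The common container for all geometry operations: an atom table plus
#' optional unit cell and symmetry.  Atom coordinates are either Cartesian
#' Angstrom or fractional (flagged by `coord_system`); fractional
#' coordinates require a cell.
#'
#' @param atoms A data.frame with columns `label`, `element`, `x`, `y`, `z`
#'   and optionally `occupancy` (default 1), `residue_id` (default 1) and
#'   `alt_site` (default `NA`).
#' @param cell A [unit_cell()] or `NULL` for non-crystal models.
#' @param symops List of [symop()] objects.
#' @param space_group Space-group symbol (text).
#' @param coord_system `"cartesian"` or `"fractional"`.
#' @return An object of class `"crystal_structure"`.
#' @export
crystal_structure <- function(atoms, cell = NULL, symops = list(),
                              space_group = NA_character_,
                              coord_system = c("cartesian", "fractional")) {
  coord_system <- match.arg(coord_system)
  req <- c("label", "element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$residue_id)) atoms$residue_id <- 1L
  if (is.null(atoms$alt_site)) atoms$alt_site <- NA_character_
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$occupancy <= 0 | atoms$occupancy > 1))
    stop("occupancies must lie in (0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a chemical element symbol")
  key <- paste(atoms$residue_id, atoms$alt_site, atoms$label)
  if (anyDuplicated(key))
    stop("atom labels must be unique within (residue_id, alt_site)")
  if (coord_system == "fractional" && is.null(cell))
    stop("fractional coordinates require a unit cell")
  structure(list(atoms = atoms, cell = cell, symops = symops,
                 space_group = space_group, coord_system = coord_system),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("Crystal structure: %d atoms (%s coordinates)\n",
              nrow(x$atoms), x$coord_system))
  if (!is.null(x$cell)) print(x$cell)
  if (length(x$symops))
    cat(sprintf("%d symmetry operation(s); space group %s\n",
                length(x$symops), x$space_group))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param structure A [crystal_structure()].
#' @param cartesian If `TRUE` (default) fractional coordinates are converted
#'   to Cartesian Angstrom first.
#' @return An n x 3 matrix, rownames = atom labels.
#' @export
coords <- function(structure, cartesian = TRUE) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  rownames(xyz) <- structure$atoms$label
  if (cartesian && structure$coord_system == "fractional")
    xyz <- frac_to_cart(structure$cell, xyz)
  xyz
}

#' Convert a structure to Cartesian coordinates in place
#'
#' @inheritParams coords
#' @return The structure with `coord_system = "cartesian"`.
#' @export
as_cartesian <- function(structure) {
  if (structure$coord_system == "cartesian") return(structure)
  xyz <- frac_to_cart(structure$cell, as.matrix(structure$atoms[, c("x", "y", "z")]))
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure$coord_system <- "cartesian"
  structure
}

#' Apply a symmetry operation to a structure
#'
#' Returns a copy of the structure with one symmetry operator (plus an
#' optional integer lattice shift) applied to every atom, the standard way
#' of generating a symmetry-related host from the asymmetric unit.
#'
#' @param structure A [crystal_structure()] holding fractional coordinates
#'   (or a cell so they can be recovered).
#' @param op A [symop()]; if it is not among `structure$symops` a warning is
#'   raised and the operator is applied anyway.
#' @param cell_shift Integer length-3 lattice translation, default `c(0,0,0)`.
#' @param tag Suffix appended to the atom labels of the image (default
#'   `"_sym"`); the identity operation with zero shift leaves labels alone.
#' @return A new `"crystal_structure"` in fractional coordinates.
#' @export
expand_symmetry <- function(structure, op, cell_shift = c(0L, 0L, 0L),
                            tag = "_sym") {
  stopifnot(inherits(op, "symop"))
  if (structure$coord_system != "fractional") {
    if (is.null(structure$cell))
      stop("symmetry expansion needs fractional coordinates (no cell present)")
    xyz <- cart_to_frac(structure$cell, coords(structure, cartesian = FALSE))
    structure$atoms[, c("x", "y", "z")] <- xyz
    structure$coord_system <- "fractional"
  }
  known <- any(vapply(structure$symops, function(o)
    isTRUE(all.equal(o$rotation, op$rotation)) &&
      all(o$translation_12 == op$translation_12), logical(1)))
  if (length(structure$symops) && !known)
    warning("operator not among the structure's symmetry list; applying anyway")
  frac <- as.matrix(structure$atoms[, c("x", "y", "z")])
  newf <- t(op$rotation %*% t(frac)) +
    matrix(symop_translation(op) + cell_shift, nrow(frac), 3, byrow = TRUE)
  out <- structure
  out$atoms[, c("x", "y", "z")] <- newf
  is_ident <- isTRUE(all.equal(op$rotation, diag(3))) &&
    all(op$translation_12 == 0L) && all(cell_shift == 0L)
  if (!is_ident) out$atoms$label <- paste0(out$atoms$label, tag)
  out
}

# Rigidly transform a Cartesian structure (rotation then translation);
# shared by the builders and the property tests.
#' Rigid-body transform of a Cartesian structure
#'
#' @param structure A Cartesian [crystal_structure()].
#' @param R 3 x 3 proper rotation matrix.
#' @param t Length-3 translation (Angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  structure <- as_cartesian(structure)
  xyz <- coords(structure)
  structure$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, `+`)
  structure
}
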