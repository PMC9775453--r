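# MM/GBSA bookkeeping.  Components and identities (all kcal/mol):
#   dE_MM        = dE_vdW + dE_ele
#   dG_solvation = dG_GB + dG_nonpolar,  dG_nonpolar = gamma*SASA + b
#   dH           = dE_MM + dG_solvation
#   dG_binding   = dH - TdS
# TdS is a normal-mode analysis output consumed as data (scalar or
# per-frame); it is never computed here.  TdS is stored exactly as
# published tables print it, and dG_binding = dH - TdS with that sign.

ENERGY_BASE <- c("dE_vdW", "dE_ele", "dG_GB", "dG_nonpolar")
ENERGY_DERIVED <- c("dE_MM", "dG_solvation", "dH", "dG_binding")

#' Per-frame energy-component table
#'
#' @param frames A data.frame with numeric columns `dE_vdW`, `dE_ele`,
#'   `dG_GB` and either `dG_nonpolar` or `SASA` (converted through
#'   [nonpolar_from_sasa()]); optionally a per-frame `TdS` column.
#' @param gamma,b Surface-tension coefficient (kcal/mol/A^2) and offset
#'   (kcal/mol) used when `SASA` is supplied (defaults 0.0072 and 0).
#' @return Object of class `"energy_frames"` (a validated data.frame).
#' @export
energy_frames <- function(frames, gamma = 0.0072, b = 0) {
  frames <- as.data.frame(frames)
  if (!nrow(frames)) stop("energy table needs at least one frame")
  if (!"dG_nonpolar" %in% names(frames)) {
    if (!"SASA" %in% names(frames))
      stop("missing required column: dG_nonpolar (or SASA)")
    frames$dG_nonpolar <- nonpolar_from_sasa(frames$SASA,
                                             nonpolar_params(gamma, b))
  }
  for (col in ENERGY_BASE)
    if (!col %in% names(frames)) stop("missing required column: ", col)
  num <- frames[intersect(c(ENERGY_BASE, "TdS"), names(frames))]
  if (any(!vapply(num, is.numeric, TRUE)) || any(!is.finite(as.matrix(num))))
    stop("energy components must be finite numerics")
  class(frames) <- c("energy_frames", "data.frame")
  frames
}

#' Read a per-frame MM/GBSA CSV
#'
#' @param path CSV with the columns of [energy_frames()].
#' @inheritParams energy_frames
#' @export
read_energy_csv <- function(path, gamma = 0.0072, b = 0) {
  energy_frames(utils::read.csv(path), gamma = gamma, b = b)
}

#' Nonpolar solvation parameters
#'
#' @param gamma kcal/mol/A^2 (default 0.0072).
#' @param b kcal/mol offset (default 0).
#' @export
nonpolar_params <- function(gamma = 0.0072, b = 0) {
  if (!is.finite(gamma) || !is.finite(b)) stop("gamma and b must be finite")
  structure(list(gamma = gamma, b = b), class = "nonpolar_params")
}

#' Nonpolar solvation energy from SASA
#'
#' `dG_nonpolar = gamma * SASA + b`, per frame.
#'
#' @param sasa Solvent-accessible surface areas, A^2 (non-negative).
#' @param params A [nonpolar_params()].
#' @return kcal/mol per frame.
#' @export
nonpolar_from_sasa <- function(sasa, params = nonpolar_params()) {
  if (any(sasa < 0)) stop("SASA must be non-negative")
  params$gamma * sasa + params$b
}

#' Combine per-frame components into a binding summary
#'
#' Derived quantities are computed per frame and then averaged, so the
#' reported standard deviations are SDs of the per-frame sums (the MM/GBSA
#' convention) rather than quadrature sums of component SDs — the two agree
#' only for uncorrelated components.
#'
#' @param table An [energy_frames()] table.
#' @param tds Scalar TdS (kcal/mol, as printed by normal-mode analysis)
#'   used when the table carries no per-frame `TdS` column; `NULL` leaves
#'   the entropic term and `dG_binding` unset and reports
#'   `dG_binding_no_entropy = mean(dH)` only.
#' @return Object of class `"binding_summary"`: a data.frame with one row
#'   per quantity and columns `mean`, `sd`.
#' @export
combine_frames <- function(table, tds = NULL) {
  table <- energy_frames(table)
  dE_MM <- table$dE_vdW + table$dE_ele
  dG_solv <- table$dG_GB + table$dG_nonpolar
  dH <- dE_MM + dG_solv
  cols <- list(dE_vdW = table$dE_vdW, dE_ele = table$dE_ele, dE_MM = dE_MM,
               dG_GB = table$dG_GB, dG_nonpolar = table$dG_nonpolar,
               dG_solvation = dG_solv, dH = dH)
  tds_col <- if ("TdS" %in% names(table)) table$TdS else
    if (!is.null(tds)) rep(tds, nrow(table)) else NULL
  if (!is.null(tds_col)) {
    cols$TdS <- tds_col
    cols$dG_binding <- dH - tds_col
  }
  cols$dG_binding_no_entropy <- dH
  sdv <- function(v) if (length(v) > 1) stats::sd(v) else 0
  out <- data.frame(quantity = names(cols),
                    mean = vapply(cols, mean, 0),
                    sd = vapply(cols, sdv, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("binding_summary", "data.frame"),
            n_frames = nrow(table))
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("MM/GBSA binding summary (kcal/mol",
      if (!is.null(attr(x, "n_frames")))
        sprintf(", %d frames", attr(x, "n_frames")), "):\n", sep = "")
  df <- as.data.frame(x)
  df$mean <- sprintf("%8.2f", df$mean)
  df$sd <- sprintf("%.2f", df$sd)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Binding summary from component means
#'
#' Pure arithmetic on published component means — the tool for recomputing
#' a printed MM/GBSA table's derived rows from its base rows.
#'
#' @param means Named list/vector with `dE_vdW`, `dE_ele`, `dG_GB`,
#'   `dG_nonpolar` and optionally `TdS` (kcal/mol, printed sign
#'   convention).
#' @return A `"binding_summary"` (means only; SDs are `NA`).
#' @export
summarize_means <- function(means) {
  means <- as.list(means)
  for (col in ENERGY_BASE)
    if (is.null(means[[col]])) stop("missing component mean: ", col)
  v <- list(dE_vdW = means$dE_vdW, dE_ele = means$dE_ele)
  v$dE_MM <- v$dE_vdW + v$dE_ele
  v$dG_GB <- means$dG_GB; v$dG_nonpolar <- means$dG_nonpolar
  v$dG_solvation <- v$dG_GB + v$dG_nonpolar
  v$dH <- v$dE_MM + v$dG_solvation
  if (!is.null(means$TdS)) {
    v$TdS <- means$TdS
    v$dG_binding <- v$dH - v$TdS
  }
  v$dG_binding_no_entropy <- v$dH
  structure(data.frame(quantity = names(v), mean = unlist(v), sd = NA_real_,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("binding_summary", "data.frame"))
}

summary_value <- function(summary, quantity) {
  i <- match(quantity, summary$quantity)
  if (is.na(i)) NA_real_ else summary$mean[i]
}

#' Check a published binding summary for internal consistency
#'
#' Evaluates each additive identity from the published operands and flags
#' residuals beyond a tolerance — the natural check that a printed MM/GBSA
#' table is internally consistent up to rounding.
#'
#' @param published Named list/vector of published means: the four base
#'   components plus any of `dE_MM`, `dG_solvation`, `dH`, `TdS`,
#'   `dG_binding`.
#' @param tolerance kcal/mol (default 0.015, half a unit in the last
#'   printed digit of a two-decimal table).
#' @return Data.frame with one row per checkable identity: `identity`,
#'   `expected` (from the operands), `published`, `residual`, `pass`.
#' @export
consistency_check <- function(published, tolerance = 0.015) {
  p <- as.list(published)
  g <- function(k) if (is.null(p[[k]])) NA_real_ else p[[k]]
  rows <- list(
    c("dE_MM = dE_vdW + dE_ele", g("dE_vdW") + g("dE_ele"), g("dE_MM")),
    c("dG_solvation = dG_GB + dG_nonpolar",
      g("dG_GB") + g("dG_nonpolar"), g("dG_solvation")),
    c("dH = dE_MM + dG_solvation", g("dE_MM") + g("dG_solvation"), g("dH")),
    c("dG_binding = dH - TdS", g("dH") - g("TdS"), g("dG_binding")))
  out <- data.frame(identity = vapply(rows, `[`, "", 1),
                    expected = as.numeric(vapply(rows, `[`, "", 2)),
                    published = as.numeric(vapply(rows, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  out$residual <- out$published - out$expected
  out$pass <- !is.na(out$residual) & abs(out$residual) <= tolerance
  out[!is.na(out$expected) & !is.na(out$published), , drop = FALSE]
}
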