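#' Shape tables
#'
#' A shape table is a plain data.frame describing per-condition or per-cell
#' bacterial shape measurements, one row per cell or condition, with columns
#'
#' * `condition` — text label (growth medium, strain, treatment);
#' * `length_um`, `width_um` — pole-to-pole length and width (diameter), um;
#' * `growth_rate_per_h` — population growth rate kappa, 1/h (optional);
#' * `surface_um2`, `volume_um3` — surface area and volume (optional if the
#'   dimensions are given);
#' * `geometry` — `"rod"` (spherocylinder; `length_um`/`width_um` are
#'   pole-to-pole length and diameter) or `"spheroid"` (prolate spheroid;
#'   `length_um`/`width_um` are the full major and minor **axes**, i.e.
#'   twice the semi-axes).
#'
#' Every row must carry either both dimensions or both `surface_um2` and
#' `volume_um3`; all numeric fields must be positive. Missing cells are `NA`.
#'
#' @param df A data.frame to validate as a shape table.
#' @return `validate_shape_table()` returns `df` invisibly after checking the
#'   invariants, stopping with the offending row index otherwise.
#' @seealso [complete_shape_table()], [read_shape_table()]
#' @export
validate_shape_table <- function(df) {
  if (!is.data.frame(df)) stop("shape table must be a data.frame", call. = FALSE)
  needed <- c("length_um", "width_um", "surface_um2", "volume_um3")
  for (col in setdiff(
    c("condition", needed, "growth_rate_per_h", "geometry"),
    names(df)
  )) {
    df[[col]] <- rep(
      if (col %in% c("condition", "geometry")) NA_character_ else NA_real_,
      nrow(df)
    )
  }
  if (nrow(df) == 0L) {
    return(invisible(df))
  }
  num <- df[needed]
  for (col in c(needed, "growth_rate_per_h")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive %s in shape table row %d", col, bad[1]),
        call. = FALSE
      )
    }
  }
  has_dims <- !is.na(num$length_um) & !is.na(num$width_um)
  has_sv <- !is.na(num$surface_um2) & !is.na(num$volume_um3)
  bad <- which(!(has_dims | has_sv))
  if (length(bad)) {
    stop(sprintf(
      "shape table row %d has neither (length_um, width_um) nor (surface_um2, volume_um3)",
      bad[1]
    ), call. = FALSE)
  }
  invisible(df)
}

#' Fill in surface, volume and aspect ratio for every shape-table row
#'
#' Applies the closed-form geometry row-wise: rows with dimensions get
#' `surface_um2`, `volume_um3` (spherocylinder or prolate-spheroid formulas
#' according to `geometry`; missing geometry defaults to `"rod"`) and
#' `eta = length/width`; rows that already carry surface and volume keep
#' their values untouched and get `eta` by inverting the spherocylinder
#' prefactor at \eqn{S/V^{2/3}}.
#'
#' @param table A shape table (see [validate_shape_table()]).
#' @return The completed table with columns `surface_um2`, `volume_um3`,
#'   `eta` populated on every row.
#' @examples
#' tab <- data.frame(condition = "glucose", length_um = 4, width_um = 1)
#' complete_shape_table(tab)
#' @export
complete_shape_table <- function(table) {
  table <- validate_shape_table(table)
  if (!"eta" %in% names(table)) table$eta <- rep(NA_real_, nrow(table))
  if (nrow(table) == 0L) {
    return(table)
  }
  geom <- ifelse(is.na(table$geometry), "rod", table$geometry)
  if (!all(geom %in% c("rod", "spheroid"))) {
    stop("geometry must be 'rod' or 'spheroid'", call. = FALSE)
  }
  has_dims <- !is.na(table$length_um) & !is.na(table$width_um)
  for (i in which(has_dims)) {
    L <- table$length_um[i]
    w <- table$width_um[i]
    if (geom[i] == "rod") {
      S <- rod_surface(L, w)
      V <- rod_volume(L, w)
    } else {
      # spheroid rows store full axes; the formulas take semi-axes
      S <- spheroid_surface(w / 2, L / 2)
      V <- spheroid_volume(w / 2, L / 2)
    }
    if (is.na(table$surface_um2[i])) table$surface_um2[i] <- S
    if (is.na(table$volume_um3[i])) table$volume_um3[i] <- V
    table$eta[i] <- L / w
  }
  sv_only <- !has_dims
  if (any(sv_only)) {
    g <- table$surface_um2[sv_only] / table$volume_um3[sv_only]^(2 / 3)
    table$eta[sv_only] <- eta_from_gamma_rod(pmax(g, gamma_sphere))
  }
  table
}

#' Read and write shape tables as CSV
#'
#' The on-disk dialect is plain CSV with a header row, UTF-8, `.` decimal
#' separator, and empty cells for missing numerics. Units are encoded in
#' column names (`_um`, `_um2`, `_um3`, `_per_h`).
#'
#' @param path File path.
#' @param table A shape table.
#' @return `read_shape_table()` returns a validated shape table;
#'   `write_shape_table()` returns `path` invisibly.
#' @export
read_shape_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_shape_table(df)
  df
}

#' @rdname read_shape_table
#' @export
write_shape_table <- function(table, path) {
  validate_shape_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
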