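# StDev*Coeff contour maps: computation, OpenDX export, region summaries.

#' StDev*Coeff contour map
#'
#' For every retained lattice column of the chosen field, the map value is
#' the column standard deviation times the PLS coefficient of that column;
#' masked columns are exactly zero. Contour levels default to the 80th
#' (favored) and 20th (disfavored) percentiles of the values over retained
#' columns, the conventional display levels.
#'
#' @param model A [pls_model][fit_pls] fitted on a block-labelled
#'   descriptor matrix.
#' @param fm The [field_matrix][build_field_matrix] the model was built
#'   from.
#' @param field `"steric"` or `"electrostatic"`.
#' @param levels Quantiles for the favored/disfavored level pair
#'   (default `c(0.8, 0.2)`).
#' @return Object of class `contour_map`: list with `grid`, `field`,
#'   `values` (one per lattice point), `favored_level`, `disfavored_level`.
#' @export
stdev_coeff_map <- function(model, fm, field = c("steric", "electrostatic"),
                            levels = c(0.8, 0.2)) {
  field <- match.arg(field)
  if (is.null(model$blocks))
    stop("model was not fitted on a block-labelled descriptor matrix")
  n_pts <- prod(fm$grid$dims)
  values <- numeric(n_pts)
  sel <- model$blocks == field
  if (any(sel))
    values[model$points[sel]] <-
      model$x_sd[sel] * model$coefficients[sel]
  retained <- values[model$points[sel]]
  lev <- if (length(retained)) quantile(retained, levels, names = FALSE)
         else c(0, 0)
  structure(list(grid = fm$grid, field = field, values = values,
                 favored_level = lev[1], disfavored_level = lev[2]),
            class = "contour_map")
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("<%s StDev*Coeff map on %dx%dx%d grid; levels [%.3g, %.3g]>\n",
              x$field, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$disfavored_level, x$favored_level))
  invisible(x)
}

#' Export a contour map as an OpenDX scalar field
#'
#' Writes the regular-grid ASCII OpenDX format readable by PyMOL, VMD and
#' Chimera. Data values follow the OpenDX convention of the last grid index
#' (z) varying fastest.
#'
#' @param map A [contour_map][stdev_coeff_map].
#' @param path Output file.
#' @export
export_dx <- function(map, path) {
  g <- map$grid
  n <- g$dims
  # reorder from x-fastest (internal) to z-fastest (OpenDX)
  arr <- array(map$values, dim = n)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  pad <- (3 - length(vals) %% 3) %% 3
  vals_pad <- c(vals, rep(NA_real_, pad))
  rows <- matrix(vals_pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals)),
    data_lines,
    sprintf("attribute \"dep\" string \"positions\""),
    sprintf("object \"%s StDev*Coeff\" class field", map$field),
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [export_dx()]
#'
#' @param path OpenDX file.
#' @return List with `grid` (a [grid_spec]) and `values` in the package's
#'   x-fastest point order.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cnt <- regmatches(lines[1], regexec(
    "gridpositions counts (\\d+) (\\d+) (\\d+)", lines[1]))[[1]]
  if (length(cnt) != 4) stop("not an OpenDX gridpositions file: ", path)
  n <- as.integer(cnt[2:4])
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[2])),
                                "\\s+")[[1]])
  d1 <- as.numeric(strsplit(trimws(sub("delta", "", lines[3])), "\\s+")[[1]])
  spacing <- d1[1]
  data_start <- grep("data follows", lines) + 1L
  data_end <- grep("^attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[data_start:data_end]),
                                     "\\s+")))
  if (length(vals) != prod(n)) stop("value count mismatch in ", path)
  arr <- array(vals, dim = rev(n))      # z-fastest on disk
  values <- as.vector(aperm(arr, c(3, 2, 1)))
  list(grid = grid_spec(origin, spacing, n), values = values)
}

#' Summarize contour maps over named lattice regions
#'
#' @param maps List of [contour_map][stdev_coeff_map] objects (same grid).
#' @param regions Named list of lattice point index vectors.
#' @return Data frame with one row per (map, region): mean map value and
#'   the fraction of region points at or above the favored level and at or
#'   below the disfavored level.
#' @export
region_report <- function(maps, regions) {
  if (inherits(maps, "contour_map")) maps <- list(maps)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  n_pts <- prod(maps[[1]]$grid$dims)
  rows <- list()
  for (map in maps) {
    for (rn in names(regions)) {
      idx <- regions[[rn]]
      if (!length(idx)) stop("empty region: ", rn)
      if (any(idx < 1 | idx > n_pts)) stop("region '", rn,
                                           "' exceeds grid bounds")
      v <- map$values[idx]
      rows[[length(rows) + 1L]] <- data.frame(
        field = map$field, region = rn, n_points = length(idx),
        mean_value = mean(v),
        frac_favored = mean(v >= map$favored_level),
        frac_disfavored = mean(v <= map$disfavored_level))
    }
  }
  do.call(rbind, rows)
}

#' Lattice indices inside an axis-aligned box
#'
#' Convenience for defining [region_report()] regions from coordinates.
#'
#' @param grid A [grid_spec].
#' @param lower,upper Numeric length-3 box corners, Angstrom.
#' @return Integer vector of lattice point indices.
#' @export
box_region <- function(grid, lower, upper) {
  pts <- grid_points(grid)
  which(pts[, 1] >= lower[1] & pts[, 1] <= upper[1] &
        pts[, 2] >= lower[2] & pts[, 2] <= upper[2] &
        pts[, 3] >= lower[3] & pts[, 3] <= upper[3])
}
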