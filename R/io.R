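FORMAT_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)   # round-trips IEEE doubles

#' Write a snapshot deck as a delimited table
#'
#' Long format, tab-separated, one row per (frame, entity): columns
#' `frame` (1-based), `id` (1-based entity), `c1`, `c2`, `c3`.  A sidecar
#' JSON file `<path>.meta.json` records `dt`, `kind`, the flow-rate
#' parameter and the format version.  Region masks and coordinates, if
#' present, go to `<path>.geom.tsv` via [write_geometry_table()].
#'
#' @param set a [snapshot_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot_table <- function(set, path) {
  stopifnot(inherits(set, "snapshot_set"))
  d <- dim(set$values)
  df <- data.frame(
    frame = rep(seq_len(d[3]), each = d[2]),
    id = rep(seq_len(d[2]), times = d[3]),
    c1 = fmt_num(as.vector(set$values[1, , ])),
    c2 = fmt_num(as.vector(set$values[2, , ])),
    c3 = fmt_num(as.vector(set$values[3, , ])))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(format_version = FORMAT_VERSION, dt = set$dt,
               kind = set$kind, n_entities = d[2], n_frames = d[3],
               t0 = set$times[1], flow_rate = set$flow_rate)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(set$coords))
    write_geometry_table(set, paste0(path, ".geom.tsv"))
  invisible(path)
}

#' Read a snapshot deck written by [write_snapshot_table()]
#'
#' Non-finite values are rejected at load time.
#'
#' @param path table path (sidecar `<path>.meta.json` must exist).
#' @return A [snapshot_set()].
#' @export
read_snapshot_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "numeric",
                                         "numeric", "numeric"))
  n <- meta$n_entities; nt <- meta$n_frames
  if (nrow(df) != n * nt) stop("table size disagrees with metadata")
  ord <- order(df$frame, df$id)
  df <- df[ord, ]
  vals <- array(0, c(3, n, nt))
  vals[1, , ] <- df$c1; vals[2, , ] <- df$c2; vals[3, , ] <- df$c3
  if (!all(is.finite(vals))) stop("non-finite values in snapshot table")
  coords <- NULL; masks <- NULL
  gpath <- paste0(path, ".geom.tsv")
  if (file.exists(gpath)) {
    g <- read_geometry_table(gpath)
    coords <- g$coords; masks = g$masks
  }
  t0 <- if (is.null(meta$t0)) 0 else as.numeric(meta$t0)
  dt <- as.numeric(meta$dt)
  snapshot_set(vals, dt = dt, kind = meta$kind,
               times = t0 + (seq_len(nt) - 1) * dt,
               coords = coords, masks = masks,
               flow_rate = if (is.null(meta$flow_rate)) NULL
                           else as.numeric(meta$flow_rate))
}

#' Write node coordinates and region labels
#'
#' Tab-separated columns `id`, `x`, `y`, `z`, `region` where region is one
#' of `wall`, `outlet`, `inlet` or `lumen`.
#'
#' @param x a [snapshot_set()] or `toy_geometry` with coords and masks.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_table <- function(x, path) {
  if (inherits(x, "toy_geometry")) {
    coords <- x$coords
    masks <- list(wall = x$wall, outlet = x$outlet, inlet = x$inlet)
  } else {
    coords <- x$coords; masks <- x$masks
  }
  n <- ncol(coords)
  region <- rep("lumen", n)
  for (nm in names(masks)) region[masks[[nm]]] <- nm
  df <- data.frame(id = seq_len(n), x = fmt_num(coords[1, ]),
                   y = fmt_num(coords[2, ]), z = fmt_num(coords[3, ]),
                   region = region)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a geometry table written by [write_geometry_table()]
#'
#' @param path table path.
#' @return List with `coords` (`3 x N`) and `masks`.
#' @export
read_geometry_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric", "numeric",
                                         "numeric", "character"))
  df <- df[order(df$id), ]
  coords <- rbind(df$x, df$y, df$z)
  masks <- list(wall = df$region == "wall",
                outlet = df$region == "outlet",
                inlet = df$region == "inlet")
  list(coords = coords, masks = masks)
}

#' Export a fluid deck as legacy-VTK point files
#'
#' One ASCII legacy-VTK POLYDATA file per frame (`<basename>_NNNN.vtk`)
#' with a POINTS block (node coordinates, or particle positions for
#' particle decks) and a POINT_DATA VECTORS block holding the frame's
#' field values.  Intended for visualisation; not a round-trip archival
#' format (coordinates are written at reduced precision).
#'
#' @param set a [snapshot_set()].
#' @param dir output directory (created if missing).
#' @param basename file stem; default the deck kind.
#' @param frames frame indices to export; default all.
#' @return Character vector of file paths, invisibly.
#' @export
write_vtk_points <- function(set, dir, basename = set$kind, frames = NULL) {
  stopifnot(inherits(set, "snapshot_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(frames)) frames <- seq_len(n_frames(set))
  paths <- character(0)
  for (k in frames) {
    pts <- if (!is.null(set$coords)) set$coords else set$values[, , k]
    dim(pts) <- c(3, length(pts) / 3)
    n <- ncol(pts)
    p <- file.path(dir, sprintf("%s_%04d.vtk", basename, k))
    con <- file(p, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("%s frame %d t=%g", basename, k, set$times[k]),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", n)), con)
    writeLines(apply(signif(t(pts), 9), 1, paste, collapse = " "), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS field double"), con)
    vals <- t(matrix(set$values[, , k], 3))
    writeLines(apply(signif(vals, 9), 1, paste, collapse = " "), con)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read one legacy-VTK point file written by [write_vtk_points()]
#'
#' @param path `.vtk` file path.
#' @return List with `points` (`3 x N`) and `field` (`3 x N`).
#' @export
read_vtk_points <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE), 3)
  iv <- grep("^VECTORS", lines)[1]
  field <- matrix(scan(text = lines[(iv + 1):(iv + n)], quiet = TRUE), 3)
  list(points = pts, field = field)
}

# ---- model bundle -----------------------------------------------------

write_array_tsv <- function(x, path) {
  m <- as.matrix(x)
  if (is.complex(m)) {
    out <- cbind(matrix(fmt_num(Re(m)), nrow(m)),
                 matrix(fmt_num(Im(m)), nrow(m)))
  } else {
    out <- matrix(fmt_num(m), nrow(m))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_array_tsv <- function(path, nrow, ncol, complex = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (complex) {
    matrix(complex(real = m[, seq_len(ncol)],
                   imaginary = m[, ncol + seq_len(ncol)]), nrow, ncol)
  } else {
    matrix(m, nrow, ncol)
  }
}

#' Persist a fitted DMD model as a text bundle
#'
#' Writes a directory containing a JSON manifest (shapes, `dt`, rank,
#' flow-rate parameter, format version, creation seed if supplied) and one
#' TSV file per array; complex arrays are stored as side-by-side real and
#' imaginary blocks.  Numbers are written with 17 significant digits, so
#' [read_model_bundle()] reproduces every array bit-exactly.
#'
#' @param model a [dmd_fit()] result.
#' @param dir bundle directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param seed optional creation seed recorded in the manifest.
#' @param overwrite replace an existing bundle.
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir, seed = NULL, overwrite = FALSE) {
  stopifnot(inherits(model, "dmd_model"))
  man_path <- file.path(dir, "manifest.json")
  if (file.exists(man_path) && !overwrite)
    stop("bundle already exists at ", dir)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arrays <- list(Ur = model$Ur, Sr = matrix(model$Sr, ncol = 1),
                 Vr = model$Vr, A_tilde = model$A_tilde,
                 Lambda = matrix(model$Lambda, ncol = 1), W = model$W,
                 Phi = model$Phi, b0 = matrix(model$b0, ncol = 1))
  spec <- lapply(arrays, function(a)
    list(nrow = nrow(a), ncol = ncol(a), complex = is.complex(a)))
  for (nm in names(arrays))
    write_array_tsv(arrays[[nm]], file.path(dir, paste0(nm, ".tsv")))
  has_geom <- !is.null(model$coords)
  if (has_geom)
    write_geometry_table(list(coords = model$coords, masks = model$masks),
                         file.path(dir, "geometry.tsv"))
  manifest <- list(format_version = FORMAT_VERSION, class = "dmd_model",
                   dt = model$dt, r = model$r, m = model$m,
                   n_entities = model$n_entities, kind = model$kind,
                   flow_rate = model$flow_rate, seed = seed,
                   has_geometry = has_geom, arrays = spec)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Load a DMD model bundle
#'
#' @param dir directory written by [write_model_bundle()].
#' @return A `dmd_model`.
#' @export
read_model_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$class, "dmd_model"))
    stop("not a dmd_model bundle")
  arr <- list()
  for (nm in names(manifest$arrays)) {
    s <- manifest$arrays[[nm]]
    arr[[nm]] <- read_array_tsv(file.path(dir, paste0(nm, ".tsv")),
                                s$nrow, s$ncol, s$complex)
  }
  coords <- NULL; masks <- NULL
  if (isTRUE(manifest$has_geometry)) {
    g <- read_geometry_table(file.path(dir, "geometry.tsv"))
    coords <- g$coords; masks <- g$masks
  }
  structure(
    list(Ur = arr$Ur, Sr = drop(arr$Sr), Vr = arr$Vr,
         A_tilde = arr$A_tilde, Lambda = drop(arr$Lambda), W = arr$W,
         Phi = arr$Phi, b0 = drop(arr$b0), dt = as.numeric(manifest$dt),
         r = as.integer(manifest$r),
         flow_rate = if (is.null(manifest$flow_rate)) NULL
                     else as.numeric(manifest$flow_rate),
         n_entities = as.integer(manifest$n_entities),
         kind = manifest$kind, coords = coords, masks = masks,
         m = as.integer(manifest$m)),
    class = "dmd_model")
}
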