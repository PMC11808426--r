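#' Read a flow snapshot
#'
#' Reads a [field_grid()] from a legacy-VTK structured grid
#' (`STRUCTURED_POINTS`, ASCII) or a delimited text table.  Velocity
#' may be stored as one 3-component `VECTORS` array or as three scalar
#' arrays `u`, `v`, `w`; the liquid volume fraction must be present as
#' `alpha`; `k` and `omega` are optional.
#'
#' @param path File to read.
#' @param format `"vtk_legacy"` or `"delimited"`; guessed from the
#'   file extension (`.vtk` vs anything else) when missing.
#' @param ... Passed to [field_grid()] (e.g. `wall_radius`).
#' @return A [field_grid()].
#' @export
load_fields <- function(path, format = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk_legacy"
              else "delimited"
  }
  format <- match.arg(format, c("vtk_legacy", "delimited"))
  switch(format,
         vtk_legacy = .read_vtk_legacy(path, ...),
         delimited = .read_field_table(path, ...))
}

#' Write a flow snapshot
#'
#' Writes a [field_grid()] as an ASCII legacy-VTK structured-points
#' file (cell data) or as a delimited text table with columns
#' `x,y,z,u,v,w,alpha[,k,omega]`.
#'
#' @param grid A [field_grid()].
#' @param path Output file.
#' @param format `"vtk_legacy"` or `"delimited"`; guessed from the
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
save_fields <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "field_grid"))
  if (is.null(format)) {
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk_legacy"
              else "delimited"
  }
  format <- match.arg(format, c("vtk_legacy", "delimited"))
  switch(format,
         vtk_legacy = .write_vtk_legacy(grid, path),
         delimited = .write_field_table(grid, path))
  invisible(path)
}

.fmt_num <- function(x) sprintf("%.17g", x)

.write_vtk_legacy <- function(grid, path) {
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  origin <- c(grid$x[1] - grid$dx / 2, grid$y[1] - grid$dy / 2,
              grid$z[1] - grid$dz / 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "two-phase flow snapshot",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", dims[1] + 1, dims[2] + 1, dims[3] + 1),
               paste("ORIGIN", .fmt_num(origin[1]), .fmt_num(origin[2]),
                     .fmt_num(origin[3])),
               paste("SPACING", .fmt_num(grid$dx), .fmt_num(grid$dy),
                     .fmt_num(grid$dz)),
               paste("CELL_DATA", prod(dims))), con)
  writeLines(c("VECTORS U double",
               paste(.fmt_num(as.vector(grid$u)), .fmt_num(as.vector(grid$v)),
                     .fmt_num(as.vector(grid$w)))), con)
  write_scalar <- function(name, arr) {
    writeLines(c(paste("SCALARS", name, "double 1"), "LOOKUP_TABLE default",
                 .fmt_num(as.vector(arr))), con)
  }
  write_scalar("alpha", grid$alpha)
  if (!is.null(grid$k)) write_scalar("k", grid$k)
  if (!is.null(grid$omega)) write_scalar("omega", grid$omega)
}

.read_vtk_legacy <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  hdr_at <- function(pattern) grep(pattern, lines, ignore.case = TRUE)[1]
  need <- function(pattern, what) {
    i <- hdr_at(pattern)
    if (is.na(i)) stop("malformed VTK file '", path, "': missing ", what,
                       call. = FALSE)
    i
  }
  if (is.na(hdr_at("^ASCII"))) {
    stop("only ASCII legacy VTK files are supported: ", path, call. = FALSE)
  }
  if (is.na(hdr_at("^DATASET\\s+STRUCTURED_POINTS"))) {
    stop("only STRUCTURED_POINTS datasets are supported: ", path,
         call. = FALSE)
  }
  dims <- as.integer(strsplit(trimws(lines[need("^DIMENSIONS", "DIMENSIONS")]),
                              "\\s+")[[1]][-1])
  origin <- as.numeric(strsplit(trimws(lines[need("^ORIGIN", "ORIGIN")]),
                                "\\s+")[[1]][-1])
  spacing <- as.numeric(strsplit(trimws(lines[need("^SPACING", "SPACING")]),
                                 "\\s+")[[1]][-1])
  cell_i <- hdr_at("^CELL_DATA")
  point_i <- hdr_at("^POINT_DATA")
  if (!is.na(cell_i)) {
    ncell <- as.integer(strsplit(trimws(lines[cell_i]), "\\s+")[[1]][2])
    res <- dims - 1L
    centers <- lapply(1:3, function(a) {
      origin[a] + (seq_len(res[a]) - 0.5) * spacing[a]
    })
    start <- cell_i
  } else if (!is.na(point_i)) {
    ncell <- as.integer(strsplit(trimws(lines[point_i]), "\\s+")[[1]][2])
    res <- dims
    centers <- lapply(1:3, function(a) {
      origin[a] + (seq_len(res[a]) - 1) * spacing[a]
    })
    start <- point_i
  } else {
    stop("malformed VTK file '", path, "': no CELL_DATA or POINT_DATA section",
         call. = FALSE)
  }
  if (prod(res) != ncell) {
    stop("VTK file '", path, "': data count ", ncell,
         " does not match DIMENSIONS", call. = FALSE)
  }

  arrays <- list()
  i <- start + 1L
  n_lines <- length(lines)
  read_values <- function(from, count) {
    vals <- numeric(0)
    j <- from
    while (length(vals) < count && j <= n_lines) {
      tok <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) && is.na(suppressWarnings(as.numeric(tok[1])))) break
      vals <- c(vals, as.numeric(tok))
      j <- j + 1L
    }
    if (length(vals) < count) {
      stop("VTK file '", path, "': truncated data block near line ", from,
           call. = FALSE)
    }
    list(values = vals[seq_len(count)], next_line = j)
  }
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    tok <- strsplit(line, "\\s+")[[1]]
    key <- toupper(tok[1])
    if (key == "SCALARS") {
      name <- tok[2]
      i <- i + 1L
      if (i <= n_lines && grepl("^LOOKUP_TABLE", lines[i],
                                ignore.case = TRUE)) i <- i + 1L
      blk <- read_values(i, ncell)
      arrays[[name]] <- array(blk$values, dim = res)
      i <- blk$next_line
    } else if (key == "VECTORS") {
      name <- tok[2]
      blk <- read_values(i + 1L, 3L * ncell)
      m <- matrix(blk$values, ncol = 3, byrow = TRUE)
      arrays[[paste0(name, ".x")]] <- array(m[, 1], dim = res)
      arrays[[paste0(name, ".y")]] <- array(m[, 2], dim = res)
      arrays[[paste0(name, ".z")]] <- array(m[, 3], dim = res)
      arrays[[".vector_name"]] <- name
      i <- blk$next_line
    } else {
      i <- i + 1L
    }
  }
  .assemble_grid(arrays, centers, path, ...)
}

.assemble_grid <- function(arrays, centers, path, ...) {
  vec <- arrays[[".vector_name"]]
  if (!is.null(vec)) {
    u <- arrays[[paste0(vec, ".x")]]
    v <- arrays[[paste0(vec, ".y")]]
    w <- arrays[[paste0(vec, ".z")]]
  } else if (all(c("u", "v", "w") %in% names(arrays))) {
    u <- arrays$u; v <- arrays$v; w <- arrays$w
  } else {
    stop("snapshot '", path, "': velocity missing (need a VECTORS array ",
         "or scalars u, v, w)", call. = FALSE)
  }
  if (is.null(arrays$alpha)) {
    stop("snapshot '", path, "': volume fraction missing (array 'alpha')",
         call. = FALSE)
  }
  field_grid(centers[[1]], centers[[2]], centers[[3]], u, v, w,
             alpha = arrays$alpha, k = arrays$k, omega = arrays$omega, ...)
}

.write_field_table <- function(grid, path) {
  res <- c(length(grid$x), length(grid$y), length(grid$z))
  df <- data.frame(
    x = rep(grid$x, times = res[2] * res[3]),
    y = rep(rep(grid$y, each = res[1]), times = res[3]),
    z = rep(grid$z, each = res[1] * res[2]),
    u = as.vector(grid$u), v = as.vector(grid$v), w = as.vector(grid$w),
    alpha = as.vector(grid$alpha))
  if (!is.null(grid$k)) df$k <- as.vector(grid$k)
  if (!is.null(grid$omega)) df$omega <- as.vector(grid$omega)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_field_table <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#")
  required <- c("x", "y", "z", "alpha")
  missing_cols <- setdiff(required, names(df))
  if ("alpha" %in% missing_cols) {
    stop("snapshot '", path, "': volume fraction missing (column 'alpha')",
         call. = FALSE)
  }
  if (length(missing_cols)) {
    stop("snapshot '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("u", "v", "w") %in% names(df))) {
    stop("snapshot '", path, "': velocity missing (columns u, v, w)",
         call. = FALSE)
  }
  x <- sort(unique(df$x)); y <- sort(unique(df$y)); z <- sort(unique(df$z))
  res <- c(length(x), length(y), length(z))
  if (nrow(df) != prod(res)) {
    stop("snapshot '", path, "': rows do not form a full structured grid ",
         sprintf("(%d rows vs %d x %d x %d cells)", nrow(df),
                 res[1], res[2], res[3]), call. = FALSE)
  }
  ix <- match(df$x, x); iy <- match(df$y, y); iz <- match(df$z, z)
  lin <- ix + (iy - 1L) * res[1] + (iz - 1L) * res[1] * res[2]
  if (anyDuplicated(lin)) {
    stop("snapshot '", path, "': duplicate grid positions", call. = FALSE)
  }
  to_array <- function(col) {
    arr <- array(NA_real_, dim = res)
    arr[lin] <- col
    arr
  }
  field_grid(x, y, z,
             u = to_array(df$u), v = to_array(df$v), w = to_array(df$w),
             alpha = to_array(df$alpha),
             k = if ("k" %in% names(df)) to_array(df$k),
             omega = if ("omega" %in% names(df)) to_array(df$omega), ...)
}

# ---- operating-condition tables -------------------------------------

# recognised condition columns: name -> (target field, conversion to SI)
.condition_columns <- function() list(
  n_rpm = list("n", rpm_to_hz), n_hz = list("n", identity),
  n_1s = list("n", identity),
  d_mm = list("d", mm_to_m), d_m = list("d", identity),
  d0_mm = list("d0", mm_to_m), d0_m = list("d0", identity),
  VL_mL = list("VL", mL_to_m3), VL_m3 = list("VL", identity),
  rho_kgm3 = list("rho", identity),
  eta_mPas = list("eta", mPas_to_Pas), eta_Pas = list("eta", identity),
  K_mPasm = list("K", mPas_to_Pas), K_Pasm = list("K", identity),
  m = list("m", identity),
  T_C = list("T", degC_to_K), T_K = list("T", identity),
  g_ms2 = list("g", identity)
)

#' Read an operating-condition table
#'
#' Reads a delimited text table of shake-flask operating conditions.
#' Units are declared through the column names; recognised columns are
#' `n_rpm`/`n_hz`/`n_1s`, `d_mm`/`d_m`, `d0_mm`/`d0_m`, `VL_mL`/`VL_m3`,
#' `rho_kgm3`, `eta_mPas`/`eta_Pas` (Newtonian) or `K_mPasm`/`K_Pasm`
#' plus `m` (power law), `T_C`/`T_K` and `g_ms2`.  Everything is
#' converted to SI once, here.
#'
#' @param path Delimited text file with a header row; the separator is
#'   sniffed from the header (comma, semicolon, tab or whitespace).
#' @param flask Optional flask preset name used to fill a missing
#'   diameter column (see [flask_preset()]).
#' @return A data.frame in SI units with columns `n`, `d`, `d0`, `VL`,
#'   `rho`, `T`, `g` and either `eta` or `K` + `m` (`NA` where not
#'   given).
#' @export
read_conditions <- function(path, flask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl(";", header)) ";" else if (grepl(",", header)) ","
         else if (grepl("\t", header)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  out <- data.frame(row = seq_len(nrow(df)))
  colspec <- .condition_columns()
  unknown <- setdiff(names(df), names(colspec))
  if (length(unknown)) {
    warning("ignoring unrecognised column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(names(df), names(colspec))) {
    spec <- colspec[[col]]
    target <- spec[[1]]
    if (target %in% names(out)) {
      stop("column '", col, "' duplicates '", target,
           "' already declared in another unit", call. = FALSE)
    }
    out[[target]] <- spec[[2]](df[[col]])
  }
  # [[ for exact matching: $ would partially match 'd' to 'd0'
  if (is.null(out[["d"]]) && !is.null(flask)) out$d <- flask_preset(flask)
  for (field in c("rho", "T", "g")) {
    if (is.null(out[[field]])) {
      out[[field]] <- c(rho = 1000, T = 293.15, g = 9.81)[[field]]
    }
  }
  for (field in c("n", "d", "d0", "VL")) {
    if (is.null(out[[field]])) {
      stop("condition table lacks required quantity '", field, "'",
           call. = FALSE)
    }
  }
  if (is.null(out[["eta"]]) && (is.null(out[["K"]]) || is.null(out[["m"]]))) {
    stop("condition table needs a viscosity column (eta) or the ",
         "power-law pair (K, m)", call. = FALSE)
  }
  out$row <- NULL
  out
}
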