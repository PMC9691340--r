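# Point-cloud file I/O: PLY (ascii and binary_little_endian), XYZ, CSV.

#' Read a point cloud from file
#'
#' Supports PLY (ascii and binary_little_endian vertex elements), plain XYZ
#' (3 whitespace-separated columns) and CSV with `x,y,z` columns. PLY
#' per-vertex integer properties named `semantic_label` / `instance_label`
#' are loaded when present; for XYZ/CSV a label sidecar CSV with columns
#' `point_index,semantic_label,instance_label` (0-based indices) can be given.
#'
#' @param path file path.
#' @param format one of "ply", "xyz", "csv"; default guessed from extension.
#' @param labels optional path to a CSV label sidecar.
#' @param up_axis vertical axis index, default 3.
#' @return A [point_cloud].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz", "csv"),
                             labels = NULL, up_axis = 3L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", csv = "csv", txt = "xyz",
                     .stopf("cannot guess format from extension '%s'", ext))
  }
  pc <- switch(format,
    ply = .read_ply(path, up_axis),
    xyz = {
      m <- tryCatch(as.matrix(utils::read.table(path)),
                    error = function(e) .stopf("malformed XYZ file '%s': %s", path, conditionMessage(e)))
      if (ncol(m) < 3) .stopf("XYZ file '%s' has %d columns, expected >= 3", path, ncol(m))
      if (any(!is.finite(m[, 1:3]))) .stopf("non-finite coordinate in '%s'", path)
      point_cloud(m[, 1:3, drop = FALSE], up_axis = up_axis)
    },
    csv = {
      df <- utils::read.csv(path)
      need <- c("x", "y", "z")
      if (!all(need %in% names(df))) .stopf("CSV '%s' must have columns x,y,z", path)
      if (any(!is.finite(as.matrix(df[need])))) .stopf("non-finite coordinate in '%s'", path)
      point_cloud(as.matrix(df[need]),
                  semantic_label = df$semantic_label, instance_label = df$instance_label,
                  up_axis = up_axis)
    })
  if (!is.null(labels)) {
    lab <- utils::read.csv(labels)
    idx <- lab$point_index + 1L
    if (any(idx < 1L | idx > nrow(pc$coords))) .stopf("label sidecar indices out of range")
    sem <- rep(NA_integer_, nrow(pc$coords)); ins <- rep(NA_integer_, nrow(pc$coords))
    if (!is.null(lab$semantic_label)) sem[idx] <- lab$semantic_label
    if (!is.null(lab$instance_label)) ins[idx] <- lab$instance_label
    pc$semantic_label <- if (all(is.na(sem))) NULL else sem
    pc$instance_label <- if (all(is.na(ins))) NULL else ins
  }
  pc
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_ply <- function(path, up_axis) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) .stopf("'%s' is not a PLY file (missing 'ply' magic)", path)
  fmt <- NULL; elems <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) .stopf("PLY '%s': premature end of header", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = character(0), types = character(0))
    } else if (tok[1] == "property") {
      if (tok[2] == "list") .stopf("PLY '%s': list properties are not supported", path)
      elems[[cur]]$types <- c(elems[[cur]]$types, tok[2])
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elems$vertex)) .stopf("PLY '%s': no vertex element", path)
  v <- elems$vertex
  pre <- names(elems)[seq_len(which(names(elems) == "vertex") - 1L)]
  if (identical(fmt, "ascii")) {
    for (e in pre) readLines(con, n = elems[[e]]$n)  # skip earlier elements
    txt <- readLines(con, n = v$n)
    if (length(txt) < v$n) .stopf("PLY '%s': expected %d vertex lines, got %d", path, v$n, length(txt))
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))), nrow = v$n, byrow = TRUE)
    if (ncol(m) != length(v$props)) .stopf("PLY '%s': vertex line width mismatch", path)
    colnames(m) <- v$props
  } else if (identical(fmt, "binary_little_endian")) {
    for (e in pre) {
      sz <- sum(.ply_type_size[elems[[e]]$types])
      readBin(con, "raw", n = sz * elems[[e]]$n)
    }
    sizes <- .ply_type_size[v$types]
    if (any(is.na(sizes))) .stopf("PLY '%s': unknown property type", path)
    raw <- readBin(con, "raw", n = sum(sizes) * v$n)
    if (length(raw) < sum(sizes) * v$n) .stopf("PLY '%s': truncated binary vertex data", path)
    m <- matrix(NA_real_, v$n, length(v$props), dimnames = list(NULL, v$props))
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    row_sz <- sum(sizes)
    for (p in seq_along(v$props)) {
      ty <- v$types[p]
      byte_idx <- as.vector(outer(seq_len(sizes[p]) + offs[p], (seq_len(v$n) - 1L) * row_sz, `+`))
      col_raw <- raw[byte_idx]
      m[, p] <- switch(ty,
        float = , float32 = readBin(col_raw, "numeric", n = v$n, size = 4L, endian = "little"),
        double = , float64 = readBin(col_raw, "numeric", n = v$n, size = 8L, endian = "little"),
        char = , int8 = readBin(col_raw, "integer", n = v$n, size = 1L, signed = TRUE, endian = "little"),
        uchar = , uint8 = readBin(col_raw, "integer", n = v$n, size = 1L, signed = FALSE, endian = "little"),
        short = , int16 = readBin(col_raw, "integer", n = v$n, size = 2L, signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(col_raw, "integer", n = v$n, size = 2L, signed = FALSE, endian = "little"),
        int = , int32 = , uint = , uint32 = readBin(col_raw, "integer", n = v$n, size = 4L, endian = "little"))
    }
  } else .stopf("PLY '%s': unsupported format '%s'", path, fmt %||% "?")
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(m))) .stopf("PLY '%s': vertex element lacks x/y/z", path)
  if (any(!is.finite(m[, need]))) .stopf("non-finite coordinate in '%s'", path)
  point_cloud(m[, need, drop = FALSE],
              semantic_label = if ("semantic_label" %in% colnames(m)) as.integer(m[, "semantic_label"]) else NULL,
              instance_label = if ("instance_label" %in% colnames(m)) as.integer(m[, "instance_label"]) else NULL,
              up_axis = up_axis)
}

#' Write a point cloud to an ASCII PLY file
#'
#' Labels (when present) are written as extra integer vertex properties
#' `semantic_label` / `instance_label`.
#'
#' @param points a [point_cloud].
#' @param path output file path.
#' @param digits coordinate precision (significant digits), default 8.
#' @export
write_point_cloud <- function(points, path, digits = 8) {
  stopifnot(inherits(points, "point_cloud"))
  xyz <- points$coords
  n <- nrow(xyz)
  props <- c("property double x", "property double y", "property double z")
  cols <- list(format(xyz[, 1], digits = digits, trim = TRUE, scientific = FALSE),
               format(xyz[, 2], digits = digits, trim = TRUE, scientific = FALSE),
               format(xyz[, 3], digits = digits, trim = TRUE, scientific = FALSE))
  if (!is.null(points$semantic_label)) {
    lab <- points$semantic_label
    if (!is.numeric(lab)) .stopf("semantic_label must be integer for PLY export; map class names to ids first")
    props <- c(props, "property int semantic_label")
    cols <- c(cols, list(as.integer(lab)))
  }
  if (!is.null(points$instance_label)) {
    props <- c(props, "property int instance_label")
    cols <- c(cols, list(as.integer(points$instance_label)))
  }
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n), props, "end_header")
  body <- do.call(paste, cols)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write per-point labels as a CSV sidecar
#'
#' Columns: `point_index` (0-based), `instance_id`, `class_id`, `class_name`.
#'
#' @param labels data frame with columns `instance_id`, `class_id`, `class_name`
#'   (as produced by [run_pipeline]).
#' @param path output CSV path.
#' @export
write_label_csv <- function(labels, path) {
  df <- data.frame(point_index = seq_len(nrow(labels)) - 1L,
                   instance_id = labels$instance_id,
                   class_id = labels$class_id,
                   class_name = labels$class_name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
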