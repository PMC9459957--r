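# Minimal PLY point-cloud codec (ASCII and binary_little_endian), vertex
# element only: double x/y/z, optional double intensity, optional int32
# label. Coordinates are stored as 64-bit floats so TXT <-> PLY round trips
# are lossless.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Write / read a point cloud as PLY
#'
#' Vertex-only PLY with `double` x/y/z properties, optional `double`
#' intensity and `int` label (0 = stem, 1 = leaf, 2 = pot, 3 = other), in
#' ASCII or binary little-endian encoding; both decode identically.
#'
#' @param cloud a [point_cloud()].
#' @param path file path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `write_ply()`: the path, invisibly. `read_ply()`: a
#'   [point_cloud()].
#' @export
write_ply <- function(cloud, path,
                      format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  props <- c("x", "y", "z",
             if (!is.null(cloud$intensity)) "intensity",
             if (!is.null(cloud$label)) "label")
  header <- c("ply",
              paste("format", format, "1.0"),
              "comment phenoscan ply v1; lengths cm",
              paste("element vertex", n),
              vapply(props, function(p)
                paste("property", if (p == "label") "int" else "double", p),
                ""),
              "end_header")
  dbl <- cloud$points
  if (!is.null(cloud$intensity)) dbl <- cbind(dbl, cloud$intensity)
  lab <- if (!is.null(cloud$label)) label_to_code(cloud$label)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (n > 0) {
      txt <- apply(dbl, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " "))
      if (!is.null(lab)) txt <- paste(txt, lab)
      writeLines(txt, con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
              eos = NULL)
    if (n > 0) {
      # interleave per-row: stack the raw bytes of each column block
      drow <- matrix(writeBin(as.vector(t(dbl)), raw(), size = 8,
                              endian = "little"),
                     nrow = 8 * ncol(dbl))
      if (!is.null(lab)) {
        irow <- matrix(writeBin(as.integer(lab), raw(), size = 4,
                                endian = "little"), nrow = 4)
        writeBin(as.vector(rbind(drow, irow)), con)
      } else {
        writeBin(as.vector(drow), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("not a PLY file (no end_header): ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500) stop("not a PLY file: ", path)
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  el <- grep("^element ", header)
  vert_el <- grep("^element vertex ", header)
  if (length(vert_el) != 1) stop("PLY must have one vertex element")
  n <- as.integer(strsplit(trimws(header[vert_el]), "\\s+")[[1]][3])
  next_el <- el[el > vert_el]
  end_at <- if (length(next_el)) min(next_el) else length(header)
  prop_lines <- grep("^property ", header)
  prop_lines <- prop_lines[prop_lines > vert_el & prop_lines < end_at]
  toks <- strsplit(trimws(header[prop_lines]), "\\s+")
  types <- vapply(toks, `[`, "", 2)
  names_ <- vapply(toks, function(t) t[length(t)], "")
  if (!all(c("x", "y", "z") %in% names_))
    stop("PLY vertex element missing required x/y/z properties")
  if (any(!types %in% names(ply_type_size)))
    stop("unsupported PLY property type: ",
         paste(setdiff(types, names(ply_type_size)), collapse = ", "))

  if (fmt == "ascii") {
    if (n == 0) {
      m <- matrix(numeric(0), ncol = length(names_))
    } else {
      lines <- readLines(con, n = n)
      m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                  ncol = length(names_), byrow = TRUE)
    }
  } else {
    sizes <- ply_type_size[types]
    stride <- sum(sizes)
    body <- readBin(con, raw(), n = n * stride)
    if (length(body) < n * stride) stop("truncated PLY body: ", path)
    offs <- cumsum(c(0, sizes[-length(sizes)]))
    m <- matrix(0, n, length(names_))
    row0 <- stride * (seq_len(n) - 1)
    for (j in seq_along(names_)) {
      idx <- as.vector(outer(seq_len(sizes[j]), row0 + offs[j], `+`))
      bytes <- body[idx]
      m[, j] <- switch(types[j],
        double = , float64 = readBin(bytes, numeric(), n = n, size = 8,
                                     endian = "little"),
        float = , float32 = readBin(bytes, numeric(), n = n, size = 4,
                                    endian = "little"),
        readBin(bytes, integer(), n = n, size = ply_type_size[types[j]],
                endian = "little",
                signed = !startsWith(types[j], "u") | sizes[j] >= 4))
    }
  }
  colnames(m) <- names_
  point_cloud(m[, c("x", "y", "z"), drop = FALSE],
              intensity = if ("intensity" %in% names_) m[, "intensity"],
              label = if ("label" %in% names_)
                code_to_label(as.integer(m[, "label"])))
}
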