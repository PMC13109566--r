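#' Read a labelled point cloud from disk
#'
#' Supported formats: `ply` (ASCII or binary little-endian, per-vertex integer
#' property `label` optional), `xyzl` (whitespace-separated text, three or
#' four columns), and `rds` (compressed R container, used for fixtures).
#' With `format = "auto"` the file extension decides.
#'
#' @param path Path to an existing file.
#' @param format One of `"auto"`, `"ply"`, `"xyzl"`, `"rds"`.
#' @return A validated [point_cloud()] tibble; the `label` column is present
#'   only when the file carries labels.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyzl", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- format_from_extension(path)
  cloud <- switch(format,
    ply = read_ply(path),
    xyzl = read_xyzl(path),
    rds = {
      obj <- readRDS(path)
      point_cloud(obj$coords, label = obj$label, name = obj$name)
    }
  )
  validate_point_cloud(cloud)
}

#' Write a labelled point cloud to disk
#'
#' Coordinates are stored at single precision or better in every format;
#' labels round-trip losslessly and are omitted when absent.
#'
#' @param cloud A point-cloud data frame.
#' @param path Output path.
#' @param format One of `"ply"`, `"xyzl"`, `"rds"`; default from the extension.
#' @param ascii For `ply`, write the ASCII dialect instead of the default
#'   binary little-endian one.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyzl", "rds"),
                              ascii = FALSE) {
  format <- match.arg(format)
  validate_point_cloud(cloud)
  if (format == "auto") format <- format_from_extension(path)
  switch(format,
    ply = write_ply(cloud, path, ascii = ascii),
    xyzl = write_xyzl(cloud, path),
    rds = saveRDS(list(coords = cloud_coords(cloud),
                       label = if (has_labels(cloud)) as.integer(cloud$label),
                       name = attr(cloud, "name")), path)
  )
  invisible(path)
}

# Pure function of the file extension.
format_from_extension <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = "ply",
    xyzl = , xyz = , txt = "xyzl",
    rds = "rds",
    stop("cannot infer point-cloud format from extension '.", ext, "'",
         call. = FALSE)
  )
}

read_xyzl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty xyzl file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (!all(nf %in% c(3L, 4L)) || length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1] | !(nf %in% c(3L, 4L)))[1]
    stop("malformed xyzl row at line ", bad, " of ", path,
         " (expected 3 or 4 columns, got ", nf[bad], ")", call. = FALSE)
  }
  vals <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:3]),
                                  numeric(3)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop("malformed xyzl row at line ", bad, " of ", path,
         " (non-numeric coordinate)", call. = FALSE)
  }
  lab <- NULL
  if (nf[1] == 4L) {
    lab <- suppressWarnings(as.integer(vapply(toks, `[`, character(1), 4)))
    if (anyNA(lab)) {
      bad <- which(is.na(lab))[1]
      stop("malformed xyzl row at line ", bad, " of ", path,
           " (non-integer label)", call. = FALSE)
    }
  }
  point_cloud(t(vals), label = lab,
              name = tools::file_path_sans_ext(basename(path)))
}

write_xyzl <- function(cloud, path) {
  xyz <- cloud_coords(cloud)
  cols <- sprintf("%.9g", xyz)
  dim(cols) <- dim(xyz)
  rows <- paste(cols[, 1], cols[, 2], cols[, 3])
  if (has_labels(cloud)) rows <- paste(rows, cloud$label)
  writeLines(rows, path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_type_float <- c("float", "float32", "double", "float64")

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) {
    stop("not a PLY file (missing 'ply' magic): ", path, call. = FALSE)
  }
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame(name, type))
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1)
    lineno <- lineno + 1L
    if (!length(ln)) stop("PLY header ended prematurely at line ", lineno,
                          call. = FALSE)
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(), props = character())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY parse error at line ", lineno,
                             ": property before element", call. = FALSE)
      if (tok[2] == "list") {
        stop("PLY list properties are not supported (line ", lineno, ")",
             call. = FALSE)
      }
      cur$types <- c(cur$types, tok[2])
      cur$props <- c(cur$props, tok[3])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("PLY parse error at header line ", lineno, ": '", ln, "'",
           call. = FALSE)
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format declaration: ", fmt %||% "<missing>",
         call. = FALSE)
  }
  if (is.null(elements$vertex)) stop("PLY file has no vertex element", call. = FALSE)
  vertex_first <- names(elements)[1] == "vertex"
  if (!vertex_first) stop("PLY vertex element must come first", call. = FALSE)
  el <- elements$vertex
  n <- el$count
  p <- length(el$props)
  unknown <- setdiff(el$types, names(ply_type_size))
  if (length(unknown)) stop("unknown PLY property type: ", unknown[1], call. = FALSE)
  if (fmt == "ascii") {
    rows <- readLines(con, n = n)
    if (length(rows) < n) stop("PLY body truncated: expected ", n,
                               " vertex rows", call. = FALSE)
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    nf <- lengths(toks)
    if (any(nf != p)) {
      bad <- which(nf != p)[1]
      stop("malformed PLY vertex row at body line ", bad, call. = FALSE)
    }
    mat <- suppressWarnings(matrix(as.numeric(unlist(toks)), ncol = p, byrow = TRUE))
    if (anyNA(mat)) {
      bad <- which(apply(is.na(mat), 1, any))[1]
      stop("malformed PLY vertex row at body line ", bad, call. = FALSE)
    }
  } else {
    sizes <- ply_type_size[el$types]
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * n)
    if (length(raw) < rec * n) stop("PLY body truncated", call. = FALSE)
    mat <- matrix(0, nrow = n, ncol = p)
    off <- 0L
    for (j in seq_len(p)) {
      sz <- sizes[j]
      byte_idx <- outer(seq_len(sz), (seq_len(n) - 1L) * rec + off, `+`)
      col_raw <- raw[as.vector(byte_idx)]
      ty <- el$types[j]
      mat[, j] <- if (ty %in% ply_type_float) {
        readBin(col_raw, "double", n = n, size = sz, endian = "little")
      } else {
        readBin(col_raw, "integer", n = n, size = sz, endian = "little",
                signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
      }
      off <- off + sz
    }
  }
  need <- c("x", "y", "z")
  if (!all(need %in% el$props)) {
    stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
  }
  lab <- NULL
  if ("label" %in% el$props) {
    lab <- as.integer(round(mat[, match("label", el$props)]))
  }
  point_cloud(mat[, match(need, el$props), drop = FALSE], label = lab,
              name = tools::file_path_sans_ext(basename(path)))
}

write_ply <- function(cloud, path, ascii = FALSE) {
  xyz <- cloud_coords(cloud)
  n <- nrow(xyz)
  labelled <- has_labels(cloud)
  header <- c(
    "ply",
    paste("format", if (ascii) "ascii" else "binary_little_endian", "1.0"),
    "comment stemleaf point cloud",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    if (labelled) "property uchar label",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (ascii) {
    rows <- paste(sprintf("%.9g", xyz[, 1]), sprintf("%.9g", xyz[, 2]),
                  sprintf("%.9g", xyz[, 3]))
    if (labelled) rows <- paste(rows, cloud$label)
    writeLines(rows, con)
  } else {
    floats <- writeBin(as.vector(t(xyz)), raw(), size = 4, endian = "little")
    dim(floats) <- c(12L, n)
    if (labelled) {
      labs <- matrix(as.raw(cloud$label), nrow = 1)
      floats <- rbind(floats, labs)
    }
    writeBin(as.vector(floats), con)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
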