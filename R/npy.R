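## Minimal NumPy .npy v1.0 container support (little-endian '<f4'/'<f8',
## C-order only). Kept deliberately small: it exists so dataset directories
## interoperate with the scientific Python stack.

npy_magic <- as.raw(c(0x93, charToRaw("NUMPY")))

#' Write a numeric array as a NumPy `.npy` file
#'
#' Writes version 1.0 of the format, C (row-major) element order,
#' little-endian. Only floating-point payloads are supported.
#'
#' @param x numeric vector, matrix or array.
#' @param path output file path.
#' @param dtype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @keywords internal
write_npy <- function(x, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  descr <- if (dtype == "float32") "<f4" else "<f8"
  shape <- paste0("(", paste0(format(dims, scientific = FALSE, trim = TRUE),
                              collapse = ", "),
                  if (length(dims) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  ## total header block (magic 6 + version 2 + len 2 + dict) padded to 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  ## C order: last index varies fastest; R arrays are column-major
  vals <- if (length(dims) > 1L) as.vector(aperm(x, rev(seq_along(dims)))) else as.vector(x)
  writeBin(as.double(vals), con,
           size = if (dtype == "float32") 4L else 8L, endian = "little")
  invisible(path)
}

#' Read a NumPy `.npy` file into an R array
#'
#' Supports v1.0/2.0 headers with `<f4`, `<f8`, `<i4` or `<i8` payloads in C
#' or Fortran order.
#'
#' @param path file path.
#' @return numeric array with the stored shape (vector if 1-d).
#' @keywords internal
read_npy <- function(path) {
  if (!file.exists(path)) stop("npy file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, npy_magic)) {
    stop("not a .npy file: ", path, call. = FALSE)
  }
  ver <- as.integer(readBin(con, "raw", 2L))
  hlen <- if (ver[1] >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- readChar(con, hlen, useBytes = TRUE)

  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(dims) == 0L || anyNA(dims)) dims <- integer(0)

  n <- if (length(dims)) prod(dims) else 1L
  vals <- switch(descr,
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported npy dtype: ", descr, call. = FALSE)
  )
  if (length(vals) != n) {
    stop("npy payload truncated: expected ", n, " values, got ", length(vals),
         call. = FALSE)
  }
  if (length(dims) <= 1L) return(vals)
  if (fortran) {
    array(vals, dim = dims)
  } else {
    aperm(array(vals, dim = rev(dims)), rev(seq_along(dims)))
  }
}
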