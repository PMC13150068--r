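# Minimal NPY (NumPy array format, v1.0 header) reader/writer.
#
# Arrays are written column-major exactly as R stores them, declared with
# 'fortran_order': True and the logical shape, which NumPy loads natively.
# Integer arrays serialize as little-endian int32 ('<i4'), doubles as
# '<f8'. The reader additionally accepts '<i8', '<f4' and '|b1' and both
# memory orders.

.sx_npy_magic <- as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"),
                          utf8ToInt("M"), utf8ToInt("P"), utf8ToInt("Y")))

#' Write an array in NPY format
#'
#' @param x An integer or double vector/matrix/array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x) && !is.integer(x)) {
    .sx_abort("write_npy() supports integer and double arrays.",
              "spherevox_io_error")
  }
  descr <- if (is.integer(x)) "<i4" else "<f8"
  shape <- dim(x) %||% length(x)
  shape_str <- if (length(shape) == 1) sprintf("(%d,)", shape) else
    sprintf("(%s)", paste(shape, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                    descr, shape_str)
  # pad with spaces so magic+version+len+header is a multiple of 64,
  # terminated by newline
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) .sx_abort(
                    paste0("Cannot open for writing: ", path),
                    "spherevox_io_error"))
  on.exit(close(con))
  writeBin(.sx_npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  if (is.integer(x)) {
    writeBin(as.vector(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.vector(x), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read an NPY array file
#'
#' @param path Path to an `.npy` file (v1.x header, numeric or boolean
#'   dtype).
#' @return An R array (integer or double) with the file's shape.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) {
    .sx_abort(paste0("NPY file not found: ", path), "spherevox_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, .sx_npy_magic)) {
    .sx_abort(paste0("Not an NPY file: ", path), "spherevox_io_error")
  }
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n_elem <- if (length(shape)) prod(shape) else 1L
  vals <- switch(descr,
    "<i4" = readBin(con, "integer", n_elem, size = 4, endian = "little"),
    "<i8" = {
      w <- readBin(con, "integer", 2L * n_elem, size = 4, endian = "little")
      lo <- w[seq(1L, by = 2L, length.out = n_elem)]
      hi <- w[seq(2L, by = 2L, length.out = n_elem)]
      v <- ifelse(lo < 0, lo + 2^32, as.numeric(lo)) + hi * 2^32
      if (any(abs(v) > .Machine$integer.max)) {
        .sx_abort("int64 value exceeds R integer range.", "spherevox_io_error")
      }
      as.integer(v)
    },
    "<f8" = readBin(con, "double", n_elem, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n_elem, size = 4, endian = "little"),
    "|b1" = as.integer(readBin(con, "raw", n_elem)),
    .sx_abort(paste0("Unsupported NPY dtype: ", descr), "spherevox_io_error")
  )
  if (length(shape) <= 1) return(vals)
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}
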