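#' Read frames from CSV (one signal per row)
#'
#' Empty cells and "nan" (case-insensitive) are treated as missing and can
#' be repaired with [clean_nans()].
#'
#' @param path CSV file path.
#' @param header does the file carry a header row? Default FALSE.
#' @return a [frame_set()] (frames may contain NA until cleaned).
#' @export
read_frames_csv <- function(path, header = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = header,
                                   na.strings = c("", "nan", "NaN", "NAN"),
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  frame_set(m)
}

#' Write frames to CSV (one signal per row)
#' @param fs a [frame_set()].
#' @param path output path.
#' @export
write_frames_csv <- function(fs, path) {
  utils::write.table(fs$frames, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# --- minimal NPY v1.0 float64 support ---------------------------------------
# No NPY reader exists for R in this stack, so the format (magic string,
# little-endian header length, Python-dict header, raw float64 payload) is
# handled directly; only C-order 1-D/2-D float64 arrays are supported,
# which covers the frame matrices this tool exchanges.

#' Read a 1-D or 2-D float64 NPY file
#' @param path NPY file path.
#' @return numeric matrix (1-D arrays become one-row matrices).
#' @export
read_frames_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an NPY file")
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("<f8", header, fixed = TRUE)) {
    stop("only little-endian float64 NPY arrays are supported")
  }
  if (grepl("'fortran_order':\\s*True", header)) {
    stop("Fortran-order NPY arrays are not supported")
  }
  shp <- regmatches(header, regexpr("\\(([0-9, ]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[() ]", "", shp), ",")[[1L]])
  dims <- dims[!is.na(dims)]
  vals <- readBin(con, "numeric", prod(dims), size = 8L, endian = "little")
  if (length(dims) == 1L) {
    frame_set(matrix(vals, 1L, dims[1L]))
  } else if (length(dims) == 2L) {
    frame_set(matrix(vals, dims[1L], dims[2L], byrow = TRUE))
  } else {
    stop("only 1-D or 2-D NPY arrays are supported")
  }
}

#' Write frames as a 2-D float64 NPY file
#' @param fs a [frame_set()] (or plain matrix).
#' @param path output path.
#' @export
write_frames_npy <- function(fs, path) {
  m <- if (inherits(fs, "frame_set")) fs$frames else as.matrix(fs)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  # pad so that magic(6)+version(2)+hlen(2)+header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
  invisible(path)
}
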