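#' @include AllClasses.R
NULL

#' Read / write a LabeledVolume container
#'
#' Simple self-described container for dense 3D label grids: a plain-text
#' header line (dimensions, voxel size in nm, offset in nm) followed by the
#' voxel labels as a gzip-compressed stream of 32-bit little-endian
#' integers in column-major (x fastest) order.
#'
#' @param x a \linkS4class{LabeledVolume}.
#' @param path file path (conventional extension: \code{.lv3}).
#' @return \code{readVolume} returns a \linkS4class{LabeledVolume}.
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "LabeledVolume"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("LV3 %d %d %d %.9g %.9g %.9g %.9g %.9g %.9g\n",
                 dim(x@data)[1], dim(x@data)[2], dim(x@data)[3],
                 x@voxelSize[1], x@voxelSize[2], x@voxelSize[3],
                 x@offset[1], x@offset[2], x@offset[3])
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(x@data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || ch == "\n") break
    hdr <- c(hdr, ch)
  }
  tok <- strsplit(trimws(paste(hdr, collapse = "")), "\\s+")[[1]]
  if (length(tok) != 10L || tok[1] != "LV3")
    stop("volume parse error: bad header in ", path)
  d <- as.integer(tok[2:4])
  vals <- readBin(con, "integer", n = prod(d), size = 4L, endian = "little")
  if (length(vals) != prod(d))
    stop("volume parse error: truncated payload in ", path)
  LabeledVolume(array(vals, dim = d), voxelSize = as.numeric(tok[5:7]),
                offset = as.numeric(tok[8:10]))
}
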