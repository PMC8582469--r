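# Minimal MetaImage (MHD header + raw) reader/writer for dose maps and
# phantom rasters.  Covers the fields this package emits; not a general
# MetaImage implementation.

.mhd_types <- c(MET_FLOAT = "numeric", MET_DOUBLE = "numeric",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_UCHAR = "integer", MET_INT = "integer")
.mhd_sizes <- c(MET_FLOAT = 4L, MET_DOUBLE = 8L, MET_SHORT = 2L,
                MET_USHORT = 2L, MET_UCHAR = 1L, MET_INT = 4L)

#' Write a 3D array as a MetaImage (.mhd + .raw) pair
#'
#' @param x a 3D array, or a `dose_map` (its `value` volume is written and a
#'   second `<name>_sigma` pair holds the relative uncertainty)
#' @param path output path ending in `.mhd`
#' @param spacing_mm,origin_mm grid geometry (taken from a `dose_map`)
#' @param element_type MetaImage element type for the raw file
#' @export
write_mhd <- function(x, path, spacing_mm = c(1, 1, 1),
                      origin_mm = c(0, 0, 0), element_type = "MET_FLOAT") {
  if (inherits(x, "dose_map")) {
    sig <- estimate_uncertainty(x)
    sig[is.na(sig)] <- 0
    write_mhd(sig, sub("\\.mhd$", "_sigma.mhd", path),
              x$spacing_mm, x$origin_mm, element_type)
    spacing_mm <- x$spacing_mm; origin_mm <- x$origin_mm
    x <- x$value
  }
  stopifnot(length(dim(x)) == 3, element_type %in% names(.mhd_sizes))
  rawfile <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dim(x), collapse = " ")),
           paste("ElementSpacing =", paste(spacing_mm, collapse = " ")),
           paste("Offset =", paste(origin_mm, collapse = " ")),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", rawfile))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawfile), "wb")
  on.exit(close(con))
  v <- as.vector(x)
  if (.mhd_types[[element_type]] == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = .mhd_sizes[[element_type]], endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) pair
#' @param path `.mhd` header path
#' @return list with `data` (3D array), `spacing_mm`, `origin_mm`
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(field("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(field("ElementSpacing"), "\\s+")[[1]])
  origin <- if (!is.null(field("Offset")))
    as.numeric(strsplit(field("Offset"), "\\s+")[[1]]) else c(0, 0, 0)
  etype <- field("ElementType")
  if (!etype %in% names(.mhd_sizes)) stop("unsupported ElementType: ", etype)
  rawfile <- file.path(dirname(path), field("ElementDataFile"))
  con <- file(rawfile, "rb")
  on.exit(close(con))
  n <- prod(dims)
  v <- readBin(con, .mhd_types[[etype]], n, size = .mhd_sizes[[etype]],
               endian = "little",
               signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  list(data = array(v, dim = dims), spacing_mm = spacing, origin_mm = origin)
}
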