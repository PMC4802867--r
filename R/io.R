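#' Read a 2-D grayscale image
#'
#' Dispatches on the file extension:
#' * `.pgm` / `.pnm` — ASCII (P2) or binary (P5) portable graymap, 8 or
#'   16 bit;
#' * `.csv` / `.tsv` / `.txt` — plain numeric matrix;
#' * `.nii` — uncompressed single-slice NIfTI-1 (pixel spacing read from
#'   the header);
#' * `.png` / `.tif` / `.tiff` — converted through a local `python`
#'   interpreter with Pillow/tifffile when one is available on the PATH.
#'
#' DICOM input is not supported by this build; convert the slice to
#' NIfTI or PGM first.
#'
#' @param path input file.
#' @return A numeric matrix with attribute `pixel_spacing` (mm per
#'   pixel, `NA` when unknown).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = , pnm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    tsv = , txt = as.matrix(utils::read.table(path, header = FALSE)),
    nii = read_nifti_slice(path),
    png = , tif = , tiff = read_via_python(path),
    dcm = stop("DICOM input is not supported; convert to NIfTI or PGM",
               call. = FALSE),
    stop("unsupported image format: .", ext, call. = FALSE))
  img <- unname(as.matrix(img))
  storage.mode(img) <- "double"
  if (is.null(attr(img, "pixel_spacing"))) attr(img, "pixel_spacing") <- NA_real_
  img
}

#' Read a portable graymap (PGM)
#'
#' Supports ASCII `P2` and binary `P5`, maxval up to 65535 (16-bit
#' binary samples are big-endian per the format).
#'
#' @param path input file.
#' @return Integer-valued numeric matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with '#' comments allowed
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n = n))
    } else {
      raw2 <- readBin(con, "raw", n = 2L * n)
      vals <- as.integer(raw2[c(TRUE, FALSE)]) * 256L +
        as.integer(raw2[c(FALSE, TRUE)])
    }
  } else stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  if (length(vals) < n) stop("truncated PGM data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a portable graymap (PGM)
#'
#' @param image numeric matrix; values are rounded and clamped to
#'   `[0, maxval]`.
#' @param path output file.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @param ascii write ASCII `P2` instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L, ascii = FALSE) {
  v <- round(as.vector(t(image)))
  v <- pmin(maxval, pmax(0, v))
  h <- nrow(image); w <- ncol(image)
  if (ascii) {
    con <- file(path, "wb")
    writeLines(c("P2", paste(w, h), as.character(maxval),
                 paste(v, collapse = "\n")), con)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
    if (maxval < 256L) {
      writeBin(as.raw(v), con)
    } else {
      hi <- v %/% 256L; lo <- v %% 256L
      writeBin(as.raw(as.vector(rbind(hi, lo))), con)
    }
    close(con)
  }
  invisible(path)
}

#' Write an RGB portable pixmap (PPM, binary P6, 8-bit)
#'
#' @param r,g,b numeric matrices of equal size, values in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(r, g, b, path) {
  h <- nrow(r); w <- ncol(r)
  clip <- function(m) pmin(255, pmax(0, round(as.vector(t(m)))))
  px <- as.raw(as.vector(rbind(clip(r), clip(g), clip(b))))
  con <- file(path, "wb")
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(px, con)
  close(con)
  invisible(path)
}

nifti_dtypes <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE),
                     `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a single-slice uncompressed NIfTI-1 image
#'
#' Minimal reader for `.nii` files holding one 2-D slice (the third and
#' later dimensions, if present, must equal 1).  Handles both byte
#' orders, the common scalar datatypes and the `scl_slope`/`scl_inter`
#' scaling.  The returned matrix is indexed `[row = y, col = x]`, and the
#' `pixel_spacing` attribute carries `pixdim[1]` (mm along x).
#'
#' @param path input `.nii` file.
#' @return Numeric matrix with attribute `pixel_spacing`.
#' @export
read_nifti_slice <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- if (sz == 348L) "little" else "big"
  if (endian == "big") {
    seek(con, 0L)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (sz != 348L) stop("not a NIfTI-1 file", call. = FALSE)
  }
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dims[1L]
  if (ndim < 2L || any(dims[seq(4L, 1L + ndim)][-(1:2)] > 1L))
    stop("only single-slice NIfTI images are supported", call. = FALSE)
  nx <- dims[2L]; ny <- dims[3L]
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file", call. = FALSE)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  seek(con, as.integer(vox_offset))
  n <- nx * ny
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  img <- t(matrix(vals, nrow = nx, ncol = ny))   # [y, x]
  attr(img, "pixel_spacing") <- if (pixdim[2L] > 0) pixdim[2L] else NA_real_
  img
}

#' Write a single-slice NIfTI-1 image (float32, uncompressed)
#'
#' @param image numeric matrix indexed `[row = y, col = x]`.
#' @param path output `.nii` file.
#' @param pixel_spacing mm per pixel stored in `pixdim` (default 1).
#' @return `path`, invisibly.
#' @export
write_nifti_slice <- function(image, path, pixel_spacing = 1) {
  ny <- nrow(image); nx <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L); wraw(36L)                      # sizeof_hdr + unused
  wi(c(2L, nx, ny, 1L, 1L, 1L, 1L, 1L), 2L)   # dim
  wraw(14L)                                    # intent_p*, intent_code
  wi(16L, 2L); wi(32L, 2L); wi(0L, 2L)        # datatype=float32, bitpix
  wf(c(1, pixel_spacing, pixel_spacing, 1, 1, 1, 1, 1))  # pixdim
  wf(352); wf(1); wf(0)                        # vox_offset, scl_slope/inter
  wraw(224L)
  seek(con, 344L)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)
  seek(con, 352L)
  wf(as.vector(t(image)))                      # x fastest
  invisible(path)
}

read_via_python <- function(path) {
  py <- Sys.which("python")
  if (py == "")
    stop("reading ", tools::file_ext(path),
         " requires a python interpreter with Pillow on the PATH; ",
         "convert the image to PGM or NIfTI instead", call. = FALSE)
  out <- tempfile(fileext = ".pgm")
  script <- sprintf(paste0(
    "import sys\nimport numpy as np\n",
    "from PIL import Image\n",
    "im = np.asarray(Image.open(r'%s').convert('I'))\n",
    "mx = 65535 if im.max() > 255 else 255\n",
    "with open(r'%s','wb') as f:\n",
    "    f.write(b'P5\\n%%d %%d\\n%%d\\n' %% (im.shape[1], im.shape[0], mx))\n",
    "    f.write(im.astype('>u2' if mx > 255 else 'u1').tobytes())\n"),
    path, out)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out))
    stop("python-based conversion of ", path, " failed", call. = FALSE)
  read_pgm(out)
}
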