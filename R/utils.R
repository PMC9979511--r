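# Internal helpers shared across modules.

#' Run code with a temporarily fixed RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and a stream label,
# kept within the 31-bit signed-integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert an RGB array to grayscale luma
#'
#' Uses the Rec. 709 luma weights 0.2125 R + 0.7154 G + 0.0721 B. A matrix
#' input is returned unchanged (already grayscale).
#' @noRd
to_gray <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  d <- dim(img)
  if (length(d) == 2) return(img)
  if (length(d) == 3 && d[3] >= 3) {
    return(0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3])
  }
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  stop("unsupported image dimensions: ", paste(d, collapse = "x"))
}

# Read a PNG or TIFF file into an [x, y, channel] array in [0, 1].
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (expect png/tif/tiff): ", path)
  )
  # readPNG returns [row(y), col(x), ch]; transpose to [x, y, ch]
  if (length(dim(raw)) == 2) {
    t(raw)
  } else {
    aperm(raw[, , seq_len(min(3, dim(raw)[3])), drop = FALSE], c(2, 1, 3))
  }
}

# Write an [x, y(, ch)] array in [0, 1] as PNG.
save_image <- function(img, path) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  d <- dim(img)
  out <- if (length(d) == 2) t(img) else aperm(img, c(2, 1, 3))
  png::writePNG(clamp(out, 0, 1), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
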