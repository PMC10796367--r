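#' Read a source image (PNG or TIFF) as an RGB pixel array
#'
#' Reads a slide or core image into the internal representation used
#' throughout the package: a numeric `H x W x 3` array with intensities in
#' `[0, 1]`. Alpha channels are dropped; grayscale images are rejected
#' because the pipeline is defined on RGB stains.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param slide_id Identifier attached to the image; defaults to the file
#'   name without extension.
#' @param magnification_tag Free-text magnification metadata (e.g. `"20x"`).
#' @return A `source_image`: list with `slide_id`, `pixels`, `magnification_tag`.
#' @export
read_source_image <- function(path, slide_id = NULL, magnification_tag = "20x") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)", call. = FALSE)
  )
  if (length(dim(px)) < 3L)
    stop("invalid input: grayscale image; RGB required", call. = FALSE)
  source_image(as_pixels(px),
               slide_id = slide_id %||% tools::file_path_sans_ext(basename(path)),
               magnification_tag = magnification_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a source image object from a pixel array
#'
#' @param pixels `H x W x 3` numeric array; intensities in `[0, 1]` or `[0, 255]`.
#' @param slide_id Slide identifier string.
#' @param magnification_tag Free-text magnification metadata.
#' @return A `source_image` list.
#' @export
source_image <- function(pixels, slide_id = "slide", magnification_tag = "20x") {
  structure(list(slide_id = slide_id, pixels = as_pixels(pixels),
                 magnification_tag = magnification_tag),
            class = "source_image")
}

#' Segment an image into non-overlapping square tiles
#'
#' Lays a regular grid anchored at the top-left corner; partial tiles at the
#' right and bottom borders are discarded, so exactly
#' `floor(H / tile_size) * floor(W / tile_size)` tiles are emitted. Each tile
#' carries its tissue coverage (see [tissue_coverage()]). Tile `(r, c)`
#' (0-based) covers pixel rows `r * tile_size + 1 ... (r + 1) * tile_size`.
#'
#' @param image A `source_image` or an RGB pixel array.
#' @param tile_size Side length in pixels (default 224).
#' @return List of `tile_record` objects, each with `slide_id`, `row`, `col`,
#'   `pixels`, `coverage`. An image smaller than one tile yields an empty
#'   list with a warning.
#' @export
segment_tiles <- function(image, tile_size = 224L) {
  if (tile_size < 16L) stop("tile_size must be >= 16", call. = FALSE)
  if (!inherits(image, "source_image")) image <- source_image(image)
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  nr <- h %/% tile_size; nc <- w %/% tile_size
  if (nr < 1L || nc < 1L) {
    warning("image ", image$slide_id, " (", h, "x", w,
            ") is smaller than one ", tile_size, "px tile; no tiles emitted")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (r in 0:(nr - 1L)) {
    for (cc in 0:(nc - 1L)) {
      crop <- px[(r * tile_size + 1L):((r + 1L) * tile_size),
                 (cc * tile_size + 1L):((cc + 1L) * tile_size), , drop = FALSE]
      k <- k + 1L
      tiles[[k]] <- structure(
        list(slide_id = image$slide_id, row = r, col = cc,
             pixels = crop, coverage = tissue_coverage(crop)),
        class = "tile_record")
    }
  }
  tiles
}

#' Tissue coverage of a tile via Otsu thresholding
#'
#' Converts the tile to BT.601 luminance, computes a single Otsu threshold on
#' its grayscale histogram, and classifies pixels strictly darker than the
#' threshold as tissue (stained tissue is darker than the white slide
#' background). Constant-intensity tiles contain no separable foreground and
#' return 0.
#'
#' @param tile_pixels RGB pixel array (or a `tile_record`).
#' @return Fraction of tissue pixels in `[0, 1]`.
#' @export
tissue_coverage <- function(tile_pixels) {
  px <- as_pixels(tile_pixels)
  gray <- luminance(px)
  if (diff(range(gray)) < 1e-12) return(0)
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1), levels = 256)
  mean(gray < thr)
}

#' Filter tiles by minimum tissue coverage
#'
#' Retains exactly the tiles whose coverage is greater than or equal to
#' `min_coverage` (boundary inclusive), preserving input order. Idempotent.
#'
#' @param tiles List of `tile_record`s with populated `coverage`.
#' @param min_coverage Coverage threshold in `[0, 1]` (default 0.60).
#' @return Filtered list of tiles.
#' @export
filter_tiles <- function(tiles, min_coverage = 0.60) {
  cov <- vapply(tiles, function(t) t$coverage, numeric(1))
  if (anyNA(cov)) stop("coverage missing on some tiles", call. = FALSE)
  tiles[cov >= min_coverage]
}

#' Tabulate tile metadata
#'
#' @param tiles List of `tile_record`s.
#' @param min_coverage Threshold used to populate the `kept` flag.
#' @return `data.frame` with `slide_id`, `row`, `col`, `coverage`, `kept`.
#' @export
tile_index <- function(tiles, min_coverage = 0.60) {
  if (length(tiles) == 0L)
    return(data.frame(slide_id = character(), row = integer(), col = integer(),
                      coverage = numeric(), kept = logical()))
  data.frame(
    slide_id = vapply(tiles, function(t) t$slide_id, character(1)),
    row = vapply(tiles, function(t) as.integer(t$row), integer(1)),
    col = vapply(tiles, function(t) as.integer(t$col), integer(1)),
    coverage = vapply(tiles, function(t) t$coverage, numeric(1)),
    kept = vapply(tiles, function(t) t$coverage >= min_coverage, logical(1))
  )
}

#' Write tiles to a directory of PNG files
#'
#' Files are named `{slide_id}_{row}_{col}.png`.
#'
#' @param tiles List of `tile_record`s.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(tiles, function(t) {
    p <- file.path(dir, sprintf("%s_%d_%d.png", t$slide_id, t$row, t$col))
    png::writePNG(t$pixels, p)
    p
  }, character(1))
  invisible(paths)
}
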