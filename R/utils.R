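#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 pmap imap keep
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

# ---- bounding boxes ---------------------------------------------------------
# Convention throughout: x, y are 0-based pixel offsets of the top-left corner,
# w, h positive integer extents; a box covers the half-open pixel set
# [x, x + w) x [y, y + h).

#' Construct a bounding box
#'
#' Boxes are plain one-row tibbles with integer columns `x`, `y`, `w`, `h`
#' (0-based top-left origin, half-open extents), so they can live directly as
#' columns of object and region tables.
#'
#' @param x,y Integer pixel offsets of the top-left corner (0-based).
#' @param w,h Positive integer pixel extents.
#' @return A one-row tibble with columns `x`, `y`, `w`, `h`.
#' @export
bounding_box <- function(x, y, w, h) {
  x <- as.integer(x); y <- as.integer(y); w <- as.integer(w); h <- as.integer(h)
  if (any(is.na(c(x, y, w, h)))) abort("bounding box fields must be integral")
  if (w <= 0L || h <= 0L) abort("bounding box extents must be positive")
  tibble(x = x, y = y, w = w, h = h)
}

box_in_bounds <- function(box, width, height) {
  box$x >= 0L & box$y >= 0L & (box$x + box$w) <= width & (box$y + box$h) <= height
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes (anything with `x`, `y`, `w`, `h` fields).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0L, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0L, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- as.numeric(ix) * as.numeric(iy)
  union <- as.numeric(a$w) * a$h + as.numeric(b$w) * b$h - inter
  if (union <= 0) return(0)
  inter / union
}

#' Tight hull of two boxes
#'
#' The smallest axis-aligned box containing both inputs (the "joint region"
#' used by the visual-context branch and by phrase labels).
#'
#' @param a,b Boxes.
#' @return A one-row box tibble.
#' @export
box_hull <- function(a, b) {
  x0 <- min(a$x, b$x); y0 <- min(a$y, b$y)
  x1 <- max(a$x + a$w, b$x + b$w); y1 <- max(a$y + a$h, b$y + b$h)
  bounding_box(x0, y0, x1 - x0, y1 - y0)
}

box_center_in <- function(inner, outer) {
  cx <- inner$x + inner$w / 2
  cy <- inner$y + inner$h / 2
  cx >= outer$x && cx < outer$x + outer$w && cy >= outer$y && cy < outer$y + outer$h
}

# ---- image helpers ----------------------------------------------------------
# Images are numeric arrays dim c(height, width, 3) with values in [0, 1].

crop_image <- function(pixels, box) {
  if (box$w <= 0L || box$h <= 0L) abort("degenerate box")
  d <- dim(pixels)
  if (box$x < 0L || box$y < 0L || box$x + box$w > d[2] || box$y + box$h > d[1])
    abort("box outside image bounds")
  pixels[(box$y + 1L):(box$y + box$h), (box$x + 1L):(box$x + box$w), , drop = FALSE]
}

image_gray <- function(pixels) {
  (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
}

# Nearest-neighbour resample at cell centres. Exactly invariant under integer
# pixel-duplication upscaling, which interpolating resizers are not.
resample_nearest <- function(mat, nr, nc) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- pmin(h, floor((seq_len(nr) - 0.5) * h / nr) + 1L)
  ci <- pmin(w, floor((seq_len(nc) - 0.5) * w / nc) + 1L)
  mat[ri, ci, drop = FALSE]
}

# ---- numerics ---------------------------------------------------------------

softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# ---- seeding ----------------------------------------------------------------
# Counter-based split of one user seed into independent stream seeds; stable
# under parallel generation because stream i never consumes stream j's draws.

split_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 100000) * 16807 + as.numeric(i) * 2246822519
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
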