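# Internal helpers shared across modules.

#' @useDynLib glandseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded components never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a global seed
#'
#' Counter-based fan-out: every pipeline stage draws its own seed from the
#' single global seed and a stage label, keeping results below 2^31.
#'
#' @param seed integer global seed.
#' @param key character stage label.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 2654435) %% 2147483629 + 1)
}

#' Grayscale (ITU-R 601 luma) of an RGB tile
#'
#' @param img `(H, W, 3)` array in `[0, 255]` (a matrix passes through).
#' @return `(H, W)` matrix in `[0, 255]`.
#' @export
as_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Binary dilation with the 3x3 cross (4-connectivity), `iters` rounds.
dilate_cross <- function(mask, iters = 1) {
  m <- mask
  if (iters < 1) return(m)
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(iters)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-H, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -W, drop = FALSE])
    m <- m | up | dn | lf | rt
  }
  m
}

# Pixels of `mask` 4-adjacent to a pixel outside it (the image frame counts
# as outside), i.e. the inner boundary.
inner_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-H, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -W, drop = FALSE])
  mask & !(up & dn & lf & rt)
}

check_same_shape <- function(a, b, what = "rasters") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stopf("shape mismatch: %s have dims %s vs %s", what,
          paste(dim(a)[1:2], collapse = "x"), paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}

# Bilinear / nearest square resize of an (H, W[, C]) array via EBImage.
resize_raster <- function(x, size, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (d[1] == size && d[2] == size) return(x)
  filt <- if (mode == "bilinear") "bilinear" else "none"
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = size, h = size,
                                            filter = filt))
  if (length(d) == 2) dim(out) <- c(size, size) else dim(out) <- c(size, size, d[3])
  out
}
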