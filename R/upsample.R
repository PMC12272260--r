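# Learnable dynamic upsampling: offset prediction by 1x1 convolution,
# pixel shuffle to the upsampled resolution, offset-corrected sampling
# grid, and differentiable bilinear grid sampling.
#
# Coordinate convention everywhere: 0-based pixel centres, x = column,
# y = row, offsets in input-pixel units. Coordinate channel 1 of a grid
# holds x, channel 2 holds y.

#' Uniform sampling grid for upsampling by an integer factor
#'
#' Output pixel (u, v) (0-based row, column) maps to input coordinate
#' x = (v + 0.5) / s - 0.5, y = (u + 0.5) / s - 0.5, the pixel-centre
#' convention under which s = 1 is exactly the identity grid.
#'
#' @param H,W input spatial size.
#' @param s integer upsampling factor (>= 1).
#' @return a 2 x sH x sW array; channel 1 = x coordinates, channel 2 = y.
#' @examples
#' makeUniformGrid(1, 1, 2)[1, , ]  # x coords: -0.25, 0.25
#' @export
makeUniformGrid <- function(H, W, s) {
  stopifnot(H >= 1, W >= 1, s >= 1)
  sH <- H * s; sW <- W * s
  xs <- ((0:(sW - 1)) + 0.5) / s - 0.5
  ys <- ((0:(sH - 1)) + 0.5) / s - 0.5
  g <- array(0, c(2L, sH, sW))
  g[1, , ] <- matrix(xs, sH, sW, byrow = TRUE)
  g[2, , ] <- matrix(ys, sH, sW)
  g
}

#' Pixel shuffle: channel blocks to spatial positions
#'
#' Rearranges a (C s^2) x H x W tensor into a C x sH x sW tensor; output
#' pixel (c, h s + i, w s + j) takes input channel c s^2 + i s + j at
#' (h, w) (0-based). A bijection on elements.
#'
#' @param x 3-d array whose channel count is divisible by s^2.
#' @param s integer factor.
#' @return rearranged array.
#' @export
pixelShuffle <- function(x, s) {
  assertArray3(x)
  d <- dim(x); Cs <- d[1]; H <- d[2]; W <- d[3]
  if (s == 1L) return(x)
  if (Cs %% (s * s) != 0L)
    stop("channel count ", Cs, " not divisible by s^2 = ", s * s)
  C <- Cs %/% (s * s)
  # input channel index = j + s*i + s^2*c (0-based) -> dims (j, i, c, H, W)
  dim(x) <- c(s, s, C, H, W)
  y <- aperm(x, c(3L, 2L, 4L, 1L, 5L))  # (c, i, H, j, W)
  dim(y) <- c(C, s * H, s * W)
  y
}

# Inverse rearrangement, used by the backward pass.
pixelUnshuffle <- function(y, s) {
  d <- dim(y); C <- d[1]; sH <- d[2]; sW <- d[3]
  if (s == 1L) return(y)
  dim(y) <- c(C, s, sH %/% s, s, sW %/% s)  # (c, i, H, j, W)
  x <- aperm(y, c(4L, 2L, 1L, 3L, 5L))      # (j, i, c, H, W)
  dim(x) <- c(C * s * s, sH %/% s, sW %/% s)
  x
}

#' Predict a sampling-offset grid from a feature map
#'
#' Applies a 1x1 convolution with parameters \code{theta} (mapping C
#' channels to 2 s^2 channels) to the feature map, then pixel-shuffles the
#' result to the upsampled resolution, yielding one (dx, dy) displacement
#' per upsampled pixel in input-pixel units.
#'
#' @param x C x H x W feature array.
#' @param theta list(W = C x 2s^2 weight matrix, b = length-2s^2 bias).
#' @param s upsampling factor.
#' @param offsetScale multiplier on the predicted offsets (default 1).
#' @return a 2 x sH x sW offset array (channel 1 = dx, channel 2 = dy).
#' @export
predictOffsets <- function(x, theta, s, offsetScale = 1) {
  assertArray3(x)
  d <- dim(x); C <- d[1]
  if (nrow(theta$W) != C || ncol(theta$W) != 2L * s * s)
    stop("theta must map ", C, " channels to ", 2L * s * s, " channels")
  m <- matrix(x, nrow = C)                       # C x (H W)
  o <- crossprod(theta$W, m) + theta$b           # 2s^2 x (H W)
  o <- array(o, c(2L * s * s, d[2], d[3]))
  pixelShuffle(o, s) * offsetScale
}

#' Bilinear grid sampling
#'
#' Samples a C x H x W tensor at the positions of a sampling grid
#' (2 x oH x oW, input-pixel units, channel 1 = x, channel 2 = y),
#' identically for every channel. Positions outside the image are clamped
#' to the border before interpolation. Differentiable with respect to both
#' the tensor and the grid (used by the training engine's backward pass).
#'
#' @param x C x H x W array.
#' @param S 2 x oH x oW sampling grid.
#' @return a C x oH x oW array.
#' @examples
#' x <- array(c(0, 2, 1, 3), c(1, 2, 2))  # [[0,1],[2,3]] as rows y, cols x
#' S <- array(c(0.5, 0.5), c(2, 1, 1))
#' gridSampleBilinear(x, S)[1, 1, 1]      # 1.5
#' @export
gridSampleBilinear <- function(x, S) {
  assertArray3(x); assertArray3(S)
  d <- dim(x); ds <- dim(S)
  if (ds[1] != 2L) stop("S must have 2 coordinate channels")
  out <- cpp_grid_sample(x, d[1], d[2], d[3],
                         as.vector(S[1, , ]), as.vector(S[2, , ]))
  array(out, c(d[1], ds[2], ds[3]))
}

#' Dynamic upsampling of a feature map
#'
#' The full learnable operator: predict offsets from the feature map
#' (\code{\link{predictOffsets}}), add them to the uniform grid
#' (\code{\link{makeUniformGrid}}), and resample by bilinear grid sampling.
#' With zero-initialised \code{theta} this reduces exactly to fixed
#' bilinear upsampling, which is also how the operator is initialised for
#' training.
#'
#' @inheritParams predictOffsets
#' @return a C x sH x sW array.
#' @export
dynamicUpsample <- function(x, theta, s, offsetScale = 1) {
  d <- dim(x)
  S <- makeUniformGrid(d[2], d[3], s) + predictOffsets(x, theta, s, offsetScale)
  gridSampleBilinear(x, S)
}
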