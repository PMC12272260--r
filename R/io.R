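# File I/O: TIFF/PNG stacks, integer label masks, dataset export, tiled
# full-frame inference and run manifests.
#
# Conventions: grayscale stacks are T x H x W arrays (multi-page TIFF, one
# page per frame; a 1-page file keeps its T dimension of size 1); RGB PNG
# images are 3 x H x W in RGB channel order; label masks are 16-bit
# integer TIFF. Pixel coordinates are 0-based (row, col) = (y, x)
# everywhere, shared between images and masks.

#' Read an image stack
#'
#' Multi-page grayscale/float TIFF becomes a T x H x W array with
#' attribute \code{bitDepth}; an RGB PNG (or RGB TIFF page) becomes a
#' 3 x H x W array in RGB order with attribute \code{format = "rgb"}.
#' Intensities come back as the floats stored in the file: integer TIFF
#' reads are rescaled from [0,1] back to integer counts.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return numeric array with dtype metadata attributes.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) {
      out <- aperm(m[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
      attr(out, "format") <- "rgb"
      attr(out, "bitDepth") <- 8L
      return(out)
    }
    out <- array(m, c(1L, nrow(m), ncol(m)))
    attr(out, "bitDepth") <- 8L
    return(out)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  bits <- attr(first, "bits.per.sample") %||% 32L
  if (bits < 32L) {
    # integer storage comes back scaled to [0, 1]; restore raw counts
    pages <- lapply(pages, function(m) round(m * (2^bits - 1)))
    first <- pages[[1]]
  }
  if (length(dim(first)) == 3L && dim(first)[3] >= 3L) {
    out <- aperm(first[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
    attr(out, "format") <- "rgb"
    attr(out, "bitDepth") <- bits
    return(out)
  }
  out <- array(0, c(length(pages), nrow(first), ncol(first)))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  attr(out, "bitDepth") <- bits
  out
}

#' Write an image stack
#'
#' Grayscale T x H x W (or H x W, or 1 x H x W) arrays go to multi-page
#' float TIFF (32-bit; TIFF float storage covers [0, 1], so wider-ranged
#' data must be rescaled first - \code{writeSyntheticDataset} records its
#' rescaling factor in the dataset metadata) or integer TIFF at the
#' requested bit depth; 3 x H x W arrays with \code{format = "rgb"} go to
#' PNG.
#'
#' @param x the array to write.
#' @param path destination (.tif for stacks, .png for RGB).
#' @param bitDepth 8, 16 (integer counts) or 32 (float).
#' @return the path, invisibly.
#' @export
writeStack <- function(x, path, bitDepth = 32L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    stopifnot(length(dim(x)) == 3L, dim(x)[1] == 3L)
    png::writePNG(aperm(x, c(2L, 3L, 1L)), path)
    return(invisible(path))
  }
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  pages <- lapply(seq_len(dim(x)[1]), function(t) {
    m <- x[t, , ]
    if (bitDepth == 32L) m else m / (2^bitDepth - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

#' Read / write integer label masks (16-bit TIFF)
#'
#' @param mask integer H x W matrix (labels 0..65535).
#' @param path file path.
#' @return \code{readMask} the integer matrix; \code{writeMask} the path.
#' @export
writeMask <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask < 65536))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Export a synthetic dataset to disk
#'
#' Writes train_A/ and train_B/ as float TIFF frames, test/ as per-field
#' multi-page stacks for both domains with 16-bit label masks and trace
#' CSVs, plus a JSON sidecar holding field parameters, seeds and split
#' membership. Byte-identical across runs with the same seed.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  for (sub in c("train_A", "train_B", "test"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  # float TIFF holds [0, 1]: rescale by one dataset-global factor, recorded
  # in metadata.json as intensityScale
  gmax <- max(1,
              vapply(ds@trainA, max, 1), vapply(ds@trainB, max, 1),
              vapply(ds@testPaired, function(it)
                max(it$imagesA, it$imagesB), 1))
  for (i in seq_along(ds@trainA))
    writeStack(ds@trainA[[i]][1, , ] / gmax,
               file.path(dir, "train_A", sprintf("img%03d.tif", i)))
  for (i in seq_along(ds@trainB))
    writeStack(ds@trainB[[i]][1, , ] / gmax,
               file.path(dir, "train_B", sprintf("img%03d.tif", i)))
  for (i in seq_along(ds@testPaired)) {
    item <- ds@testPaired[[i]]
    base <- file.path(dir, "test", sprintf("field%02d", i))
    writeStack(item$imagesA / gmax, paste0(base, "_A.tif"))
    writeStack(item$imagesB / gmax, paste0(base, "_B.tif"))
    writeMask(item$maskA, paste0(base, "_maskA.tif"))
    writeMask(item$maskB, paste0(base, "_maskB.tif"))
    utils::write.csv(item$traces, paste0(base, "_traces.csv"),
                     row.names = FALSE)
  }
  meta <- list(
    seed = ds@seed, noise = ds@noise, intensityScale = gmax,
    fieldSeedsA = ds@metadata$fieldSeedsA,
    fieldSeedsB = ds@metadata$fieldSeedsB,
    fieldSeedsTest = ds@metadata$fieldSeedsTest,
    fields = lapply(ds@testPaired, function(it)
      list(cells = it$field@cells, imageSize = it$field@imageSize,
           backgroundLevel = it$field@backgroundLevel)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Translate a full-frame stack with a trained model
#'
#' Frames larger than the tile size are processed as overlapping tiles
#' (25\% overlap) blended with linear feathering, so seams vanish and
#' interior pixels match an untiled forward pass. Frames not exceeding the
#' tile size in either dimension are translated in one pass.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param stack T x H x W array (or H x W matrix).
#' @param direction "AtoB" or "BtoA".
#' @param tile tile side in pixels (e.g. the training patch size).
#' @param overlap fraction of the tile overlapped by its neighbour.
#' @return translated stack, same T x H x W (single-channel targets).
#' @export
translateStack <- function(model, stack, direction = "AtoB", tile = 64L,
                           overlap = 0.25) {
  if (is.matrix(stack)) stack <- array(stack, c(1L, nrow(stack), ncol(stack)))
  d <- dim(stack)
  out <- array(0, d)
  for (t in seq_len(d[1])) {
    frame <- stack[t, , ]
    if (d[2] <= tile && d[3] <= tile) {
      out[t, , ] <- translate(model, frame, direction)[1, , ]
      next
    }
    acc <- matrix(0, d[2], d[3]); wacc <- matrix(0, d[2], d[3])
    step <- max(1L, as.integer(round(tile * (1 - overlap))))
    starts <- function(n) {
      s <- seq(1L, max(n - tile + 1L, 1L), by = step)
      if (tail(s, 1L) != n - tile + 1L && n > tile) s <- c(s, n - tile + 1L)
      s
    }
    ramp <- function(n) {
      ov <- as.integer(round(tile * overlap))
      w <- rep(1, n)
      if (ov > 1L) {
        w[seq_len(ov)] <- seq(0, 1, length.out = ov + 2L)[2:(ov + 1L)]
        w[n + 1L - seq_len(ov)] <- w[seq_len(ov)]
      }
      w
    }
    wt <- outer(ramp(tile), ramp(tile))
    for (r0 in starts(d[2])) for (c0 in starts(d[3])) {
      rr <- r0:(r0 + tile - 1L); cc <- c0:(c0 + tile - 1L)
      tr <- translate(model, frame[rr, cc], direction)[1, , ]
      acc[rr, cc] <- acc[rr, cc] + tr * wt
      wacc[rr, cc] <- wacc[rr, cc] + wt
    }
    out[t, , ] <- acc / wacc
  }
  out
}

#' Write a run manifest
#'
#' Records task name, config hash, seed, artifact paths and package
#' version alongside every produced output, so each artifact traces back
#' to its run.
#'
#' @param dir run directory.
#' @param config the \linkS4class{TaskConfig} used.
#' @param seed master seed.
#' @param artifacts named list/character of produced paths.
#' @return manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, config, seed, artifacts = list()) {
  cfgList <- list(name = config@name, patchSize = config@patchSize,
                  normalization = config@normalization,
                  lambdaAdv = config@lambdaAdv, lambdaCyc = config@lambdaCyc,
                  lambdaInfo = config@lambdaInfo,
                  schedule = config@schedule, iterations = config@iterations,
                  infoLossOn = config@infoLossOn,
                  widths = config@spec@widths, cz = config@spec@cz,
                  upsampler = config@spec@upsampler)
  manifest <- list(
    task = config@name,
    configHash = unname(tools::md5sum(writeTempJson(cfgList))),
    seed = seed,
    artifacts = artifacts,
    package = "InfoCycle",
    version = as.character(utils::packageVersion("InfoCycle")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# serialise an object to a temporary JSON file (for hashing)
writeTempJson <- function(obj) {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA)
  tf
}
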