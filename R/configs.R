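# Shipped task configurations.
#
# One preset per translation task, mirroring the published recipes:
#   calcium     1x256x256 patches, scale-only normalisation by the 99th
#               percentile, lambda (adv, cyc, info) = (1, 5, 10),
#               channels 8/16/32, CZ = 8, no batch norm, sigmoid growth of
#               the cycle weight.
#   he          512x512 RGB histology, [0,1] normalisation, (5, 10, 10),
#               channels 32/64/128/256, CZ = 3, batch norm.
#   dapi        256x256, percentiles 0.1/99.0, (1, 10, 5)... see YAML:
#               (adv 1, cyc 10, info 5), channels 32/64/128/256, CZ = 8.
#   mri / penicillium / planaria
#               percentiles 0.1/99.9, (1, 10, 1), channels 32/64/128/256,
#               CZ = 3, batch norm. planaria trains on 64x64 z-slices.
#   synthetic   the desk-scale rings-to-disks task: 64x64, calcium-style
#               weights and architecture, scaled-down discriminator,
#               schedule off.
# The YAML files under inst/configs/ are the source of truth; taskConfig()
# reads them so user configs can be derived by editing a copy.

configFromList <- function(cf) {
  spec <- translationSpec(
    channelsA = cf$channels_a, channelsB = cf$channels_b, cz = cf$cz,
    widths = cf$widths, useBatchNorm = cf$batchnorm,
    useModulation = cf$modulation %||% FALSE,
    upsampler = cf$upsampler %||% "dynamic",
    finalActivation = cf$final_activation %||% "linear",
    discWidths = cf$disc_widths %||% c(64L, 128L, 256L, 512L),
    offsetScale = cf$offset_scale %||% 1)
  new("TaskConfig", name = cf$name, patchSize = as.integer(cf$patch_size),
      normalization = list(mode = cf$normalization$mode,
                           lo = cf$normalization$lo %||% 0,
                           hi = cf$normalization$hi),
      lambdaAdv = cf$lambda_adv, lambdaCyc = cf$lambda_cyc,
      lambdaInfo = cf$lambda_info,
      schedule = list(enabled = isTRUE(cf$schedule$enabled),
                      k = cf$schedule$k %||% 10,
                      m = cf$schedule$m %||% 0.5),
      iterations = as.integer(cf$iterations),
      infoLossOn = cf$info_loss %||% TRUE,
      spec = spec, checkpointEvery = as.integer(cf$checkpoint_every %||% 100L))
}

#' Load a task configuration
#'
#' Reads one of the shipped per-task YAML configurations (or a user file)
#' into a validated \linkS4class{TaskConfig}. Shipped tasks: "calcium",
#' "he", "dapi", "mri", "penicillium", "planaria", "synthetic".
#' \code{...} overrides individual fields, e.g.
#' \code{taskConfig("synthetic", info_loss = FALSE)} for the ablation
#' without the information-consistency term or
#' \code{taskConfig("synthetic", upsampler = "bilinear")} for the fixed
#' upsampler.
#'
#' @param task preset name or path to a YAML file.
#' @param ... named overrides of top-level YAML fields.
#' @return a \linkS4class{TaskConfig}.
#' @examples
#' taskConfig("calcium")
#' @export
taskConfig <- function(task = "synthetic", ...) {
  path <- if (file.exists(task)) task else
    system.file("configs", paste0(task, ".yaml"), package = "InfoCycle")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown task '", task, "' and no such config file")
  cf <- yaml::read_yaml(path)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(cf), "schedule", "normalization"))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    cf <- modifyList(cf, over)
  }
  obj <- configFromList(cf)
  validObject(obj)
  validObject(obj@spec)
  obj
}
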