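# Training objectives: least-squares adversarial terms, L1 cycle
# consistency, L1 information consistency, their weighted sum, and the
# sigmoid growth schedule for the cycle weight.
#
# All L1 terms are means over elements (not sums), so loss weights stay
# comparable across patch sizes and channel counts.

#' Adversarial loss (least-squares GAN form)
#'
#' Discriminator term per domain: 0.5 mean[(D(real) - 1)^2] +
#' 0.5 mean[D(fake)^2]; generator term per domain:
#' 0.5 mean[(D(fake) - 1)^2]; both summed over the two domains. The fake
#' images are treated as constants in the discriminator term (the caller
#' detaches them). The classical log (cross-entropy) form is available via
#' \code{form = "log"}: discriminator term
#' -mean log D(real) - mean log(1 - D(fake)) with scores squashed through a
#' sigmoid.
#'
#' @param scoresRealA,scoresRealB discriminator score maps on real images.
#' @param scoresFakeA,scoresFakeB score maps on translated (fake) images
#'   (fake-A = translation into domain A).
#' @param form "lsgan" (default) or "log".
#' @return list(generator, discriminator) scalar loss terms. The generator
#'   term uses the fake scores only.
#' @export
adversarialLoss <- function(scoresRealA, scoresRealB, scoresFakeA,
                            scoresFakeB, form = c("lsgan", "log")) {
  form <- match.arg(form)
  if (form == "lsgan") {
    dTerm <- 0.5 * mean((scoresRealA - 1)^2) + 0.5 * mean(scoresFakeA^2) +
             0.5 * mean((scoresRealB - 1)^2) + 0.5 * mean(scoresFakeB^2)
    gTerm <- 0.5 * mean((scoresFakeA - 1)^2) + 0.5 * mean((scoresFakeB - 1)^2)
  } else {
    sq <- function(s) 1 / (1 + exp(-s))
    dTerm <- -mean(log(sq(scoresRealA))) - mean(log1p(-sq(scoresFakeA))) -
              mean(log(sq(scoresRealB))) - mean(log1p(-sq(scoresFakeB)))
    gTerm <- -mean(log(sq(scoresFakeA))) - mean(log(sq(scoresFakeB)))
  }
  list(generator = gTerm, discriminator = dTerm)
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between each input and its round-trip
#' reconstruction, summed over both directions: the translation must retain
#' enough information to reconstruct the original image.
#'
#' @param xA,xB input images.
#' @param xABA reconstruction of xA (A -> B -> A).
#' @param xBAB reconstruction of xB (B -> A -> B).
#' @return scalar loss, >= 0, exactly 0 iff both reconstructions are exact.
#' @export
cycleLoss <- function(xA, xB, xABA, xBAB) {
  if (!identical(dim(xA), dim(xABA)) || !identical(dim(xB), dim(xBAB)))
    stop("reconstruction shapes must match their inputs")
  l1Mean(xA, xABA) + l1Mean(xB, xBAB)
}

#' Information-consistency loss
#'
#' Mean absolute difference between the feature map encoded from each input
#' and the feature map encoded (by the other domain's encoder) from its
#' translation, summed over both directions. This is the constraint that
#' forces the full-resolution feature domain to carry the same spatial and
#' quantitative information before and after translation.
#'
#' @param zA,zB feature maps of the inputs.
#' @param zAB feature map re-encoded from the A -> B translation.
#' @param zBA feature map re-encoded from the B -> A translation.
#' @return scalar loss, >= 0, exactly 0 iff re-encoded features match.
#' @export
infoLoss <- function(zA, zB, zAB, zBA) {
  if (!identical(dim(zA), dim(zAB)) || !identical(dim(zB), dim(zBA)))
    stop("feature-map shapes must match")
  l1Mean(zA, zAB) + l1Mean(zB, zBA)
}

#' Weighted total loss
#'
#' @param weights list or numeric with lambdaAdv, lambdaCyc, lambdaInfo
#'   (all finite and >= 0).
#' @param lossAdv,lossCyc,lossInfo component values.
#' @return lambdaAdv * lossAdv + lambdaCyc * lossCyc + lambdaInfo * lossInfo.
#' @export
totalLoss <- function(weights, lossAdv, lossCyc, lossInfo) {
  w <- as.list(weights)
  stopifnot(all(vapply(w[c("lambdaAdv", "lambdaCyc", "lambdaInfo")],
                       isScalarNumber, TRUE)))
  if (any(unlist(w[c("lambdaAdv", "lambdaCyc", "lambdaInfo")]) < 0))
    stop("loss weights must be nonnegative")
  w$lambdaAdv * lossAdv + w$lambdaCyc * lossCyc + w$lambdaInfo * lossInfo
}

#' Scheduled cycle-consistency weight
#'
#' Sigmoid growth of the cycle weight over training: at iteration i of I
#' the effective weight is lambdaCyc * sigma(k (i / I - m)), with sigma the
#' logistic function, k the steepness and m the midpoint fraction. The
#' weight is monotone nondecreasing in i, equals lambdaCyc / 2 at i = m I,
#' and approaches lambdaCyc as i -> I for large k. A disabled schedule
#' returns lambdaCyc unchanged.
#'
#' @param schedule list(enabled, k, m) with k > 0 and 0 <= m <= 1.
#' @param i current iteration (0 <= i <= I).
#' @param I total iterations (>= 1).
#' @param lambdaCyc nominal cycle weight.
#' @return the effective weight at iteration i.
#' @export
cycleWeight <- function(schedule, i, I, lambdaCyc) {
  if (!isTRUE(schedule$enabled)) return(lambdaCyc)
  stopifnot(I >= 1, schedule$k > 0, schedule$m >= 0, schedule$m <= 1)
  lambdaCyc / (1 + exp(-schedule$k * (i / I - schedule$m)))
}
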