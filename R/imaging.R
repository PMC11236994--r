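#' ROI-restricted Pearson colocalization
#'
#' Standard Pearson correlation of the two channels over the pixels selected
#' by the ROI mask, without intensity thresholding — the plain reading of
#' whole-ROI colocalization coefficients.
#'
#' @param imgA,imgB numeric matrices of identical dimension.
#' @param roiMask logical matrix of the same dimension (pixels to include);
#'   defaults to the whole field.
#' @return Pearson R in [-1, 1].
#' @export
pearsonColoc <- function(imgA, imgB, roiMask = NULL) {
  stopifnot(identical(dim(imgA), dim(imgB)))
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(imgA), ncol(imgA))
  stopifnot(identical(dim(roiMask), dim(imgA)))
  a <- imgA[roiMask]; b <- imgB[roiMask]
  if (length(a) < 2L) stop("ROI must contain at least 2 pixels")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance within ROI: Pearson R undefined")
  stats::cor(a, b)
}

#' Segment fluorescent foci
#'
#' Pixels above a threshold (a fixed value, or Otsu's method) are grouped by
#' 4-connectivity; components smaller than \code{minArea} are discarded.
#'
#' @param image non-negative numeric matrix.
#' @param threshold numeric threshold, or "otsu".
#' @param minArea minimum component size in pixels (default 5).
#' @param channel label attached to each focus.
#' @return List of foci; each is a list with \code{channel},
#'   \code{pixels} (n x 2 matrix of row/col), \code{centroid}, \code{area}.
#' @export
detectFoci <- function(image, threshold = "otsu", minArea = 5L,
                       channel = "other") {
  stopifnot(length(image) > 0)
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (diff(rng) == 0) return(list())
    scaled <- (image - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  }
  bw <- image > threshold
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))   # 4-connected labelling
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(image))
  foci <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < minArea) next
    foci[[length(foci) + 1L]] <- list(
      channel = channel, pixels = unname(px),
      centroid = colMeans(px), area = nrow(px))
  }
  foci
}

#' Are two foci in contact?
#'
#' Operationalizes "no empty space observable between two foci": true when
#' the minimum Euclidean pixel-to-pixel distance between the member sets is
#' at most \code{tol} pixels (default 1, i.e. 4-adjacent or overlapping).
#'
#' @param focusA,focusB foci as returned by \code{\link{detectFoci}}.
#' @param tol contact tolerance in pixels (default 1).
#' @return Logical.
#' @export
fociContact <- function(focusA, focusB, tol = 1) {
  pa <- focusA$pixels; pb <- focusB$pixels
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(min(d2)) <= tol
}

#' Classify the contact arrangement of one germ granule
#'
#' The tri-condensate taxonomy anchored on the P granule:
#' \describe{
#'   \item{EP_only}{exactly one E focus contacts the P focus and that E
#'     contacts no Z focus.}
#'   \item{EPZ}{exactly one E focus contacts the P focus and also contacts a
#'     Z focus.}
#'   \item{multiE_P}{two or more E foci contact the same P focus, at least
#'     one of them also contacting a Z focus.}
#'   \item{other}{anything else.}
#' }
#' Z foci not contacting anything play no role: the taxonomy is defined
#' relative to the P anchor.
#'
#' @param pFocus the anchoring P-granule focus (required).
#' @param eFoci,zFoci lists of E- and Z-channel foci.
#' @param tol contact tolerance in pixels.
#' @return List: category, contacts (data.frame of edges).
#' @export
classifyArrangement <- function(pFocus, eFoci, zFoci, tol = 1) {
  if (is.null(pFocus)) stop("no P focus supplied")
  edges <- data.frame(a = character(), b = character())
  eOnP <- vapply(eFoci, function(e) fociContact(e, pFocus, tol), TRUE)
  eZ <- vapply(seq_along(eFoci), function(i)
    any(vapply(zFoci, function(z) fociContact(eFoci[[i]], z, tol), TRUE)),
    TRUE)
  if (length(eFoci) == 0L) eOnP <- logical(0)
  for (i in which(eOnP)) edges <- rbind(edges,
    data.frame(a = paste0("E", i), b = "P"))
  for (i in which(eZ)) edges <- rbind(edges,
    data.frame(a = paste0("E", i), b = "Z"))
  nE <- sum(eOnP)
  category <- if (nE == 1L && !eZ[which(eOnP)]) "EP_only"
    else if (nE == 1L && eZ[which(eOnP)]) "EPZ"
    else if (nE >= 2L && any(eZ[eOnP])) "multiE_P"
    else "other"
  list(category = category, contacts = edges)
}
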