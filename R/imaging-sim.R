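#' Render a multi-channel foci image with a known contact graph
#'
#' Each focus is rendered as an isotropic Gaussian whose half-maximum radius
#' equals the nominal focus radius (sigma = r / sqrt(2 ln 2)), so
#' segmentation at half the peak intensity recovers a disc of roughly the
#' nominal size. The ground-truth contact graph is computed analytically
#' from centres and radii under the same tolerance contract as
#' \code{\link{fociContact}}: contact iff centre distance <= r1 + r2 + tol.
#'
#' @param layout data.frame with columns channel, x, y (centre, pixels),
#'   radius, intensity.
#' @param imageSize c(rows, cols) of the field.
#' @param noiseSd sd of additive Gaussian noise (clamped at 0).
#' @param seed integer seed.
#' @param tol contact tolerance in pixels (default 1).
#' @param minSeparation same-channel foci closer than this are rejected as
#'   unresolvable (default: sum of radii).
#' @return List: \code{images} (named list of matrices per channel),
#'   \code{truth} (data.frame of contact edges i, j), \code{layout}.
#' @export
simulateFociImage <- function(layout, imageSize = c(48L, 48L), noiseSd = 0,
                              seed = 1L, tol = 1, minSeparation = NULL) {
  stopifnot(all(c("channel", "x", "y", "radius", "intensity") %in%
                colnames(layout)))
  if (any(layout$x - layout$radius < 1 | layout$y - layout$radius < 1 |
          layout$x + layout$radius > imageSize[1] |
          layout$y + layout$radius > imageSize[2]))
    stop("foci must fit inside the image")
  n <- nrow(layout)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || layout$channel[i] != layout$channel[j]) next
    d <- sqrt((layout$x[i] - layout$x[j])^2 + (layout$y[i] - layout$y[j])^2)
    lim <- minSeparation %||% (layout$radius[i] + layout$radius[j])
    if (d < lim)
      stop("same-channel foci closer than the resolvable limit")
  }
  set.seed(seed)
  rows <- matrix(seq_len(imageSize[1]), imageSize[1], imageSize[2])
  cols <- matrix(seq_len(imageSize[2]), imageSize[1], imageSize[2],
                 byrow = TRUE)
  images <- list()
  for (ch in unique(layout$channel)) {
    img <- matrix(0, imageSize[1], imageSize[2])
    for (i in which(layout$channel == ch)) {
      sig <- layout$radius[i] / sqrt(2 * log(2))
      img <- img + layout$intensity[i] *
        exp(-((rows - layout$x[i])^2 + (cols - layout$y[i])^2) /
              (2 * sig^2))
    }
    if (noiseSd > 0)
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, noiseSd),
                               imageSize[1]), 0)
    images[[ch]] <- img
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- seq_len(n)[-seq_len(i)]
    if (!length(js)) return(NULL)
    d <- sqrt((layout$x[i] - layout$x[js])^2 +
                (layout$y[i] - layout$y[js])^2)
    hit <- js[d <= layout$radius[i] + layout$radius[js] + tol]
    if (!length(hit)) return(NULL)
    data.frame(i = i, j = hit)
  }))
  list(images = images,
       truth = truth %||% data.frame(i = integer(), j = integer()),
       layout = layout)
}

#' Draw a cohort of germ granules with known arrangement categories
#'
#' Each granule is an E/P/Z layout built to realise one of the three
#' arrangement categories, drawn with the supplied mixture weights.
#' Geometry: the P focus anchors the granule; touching foci are placed with
#' centre distance r1 + r2 - 2 (unambiguous pixel contact after rendering),
#' non-touching foci at least r1 + r2 + 5 apart. Orientation is randomised
#' per granule.
#'
#' @param n number of granules (default 210).
#' @param weights category probabilities, in the order EP_only, EPZ,
#'   multiE_P (default c(0.32, 0.48, 0.20)).
#' @param seed integer seed.
#' @param radii named radii in pixels (defaults E 4, P 5, Z 3.5).
#' @param intensity peak intensity (default 100).
#' @param imageSize field size (default 56 x 56).
#' @param noiseSd image noise (default 5).
#' @return List of granules; each has \code{category} (truth), \code{field}
#'   (the \code{\link{simulateFociImage}} result).
#' @export
generateArrangementCohort <- function(n = 210L,
                                      weights = c(EP_only = 0.32,
                                                  EPZ = 0.48,
                                                  multiE_P = 0.20),
                                      seed = 1L,
                                      radii = c(E = 4, P = 5, Z = 3.5),
                                      intensity = 100,
                                      imageSize = c(56L, 56L), noiseSd = 5) {
  set.seed(seed)
  cats <- sample(names(weights), n, replace = TRUE, prob = weights)
  granule_seeds <- sample.int(2^31 - 2, n)
  pol <- function(c0, d, th) c(c0[1] + d * cos(th), c0[2] + d * sin(th))
  lapply(seq_len(n), function(i) {
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- imageSize / 2
    touch <- function(r1, r2) r1 + r2 - 2
    apart <- function(r1, r2) r1 + r2 + 5
    rows <- list(data.frame(channel = "P", x = ctr[1], y = ctr[2],
                            radius = radii["P"], intensity = intensity))
    add <- function(ch, at, r)
      rows[[length(rows) + 1L]] <<- data.frame(channel = ch, x = at[1],
                                               y = at[2], radius = r,
                                               intensity = intensity)
    if (cats[i] == "EP_only") {
      ## E touches P; Z touches P on the far side, away from E
      add("E", pol(ctr, touch(radii["P"], radii["E"]), th), radii["E"])
      add("Z", pol(ctr, touch(radii["P"], radii["Z"]), th + pi), radii["Z"])
    } else if (cats[i] == "EPZ") {
      e_at <- pol(ctr, touch(radii["P"], radii["E"]), th)
      add("E", e_at, radii["E"])
      add("Z", pol(e_at, touch(radii["E"], radii["Z"]), th), radii["Z"])
    } else {
      ## two E on one P, one of them also touching a Z
      e1 <- pol(ctr, touch(radii["P"], radii["E"]), th)
      add("E", e1, radii["E"])
      add("E", pol(ctr, touch(radii["P"], radii["E"]), th + 2 * pi / 3),
          radii["E"])
      add("Z", pol(e1, touch(radii["E"], radii["Z"]), th), radii["Z"])
    }
    field <- simulateFociImage(do.call(rbind, rows), imageSize = imageSize,
                               noiseSd = noiseSd, seed = granule_seeds[i])
    list(category = cats[i], field = field)
  })
}

#' Re-classify a rendered cohort from its images
#'
#' Segments each channel at half the nominal peak intensity and runs
#' \code{\link{classifyArrangement}}; the per-cohort category frequencies
#' are the quantity compared against the generating mixture weights.
#'
#' @param cohort result of \code{\link{generateArrangementCohort}}.
#' @param threshold segmentation threshold (default half the default peak).
#' @param tol contact tolerance in pixels.
#' @return data.frame with truth and called category per granule.
#' @export
classifyCohort <- function(cohort, threshold = 50, tol = 1) {
  calls <- vapply(cohort, function(gr) {
    imgs <- gr$field$images
    fget <- function(ch) if (is.null(imgs[[ch]])) list() else
      detectFoci(imgs[[ch]], threshold = threshold, channel = ch)
    p <- fget("P"); e <- fget("E"); z <- fget("Z")
    if (length(p) != 1L) return("other")
    classifyArrangement(p[[1]], e, z, tol = tol)$category
  }, "")
  data.frame(truth = vapply(cohort, `[[`, "", "category"), call = calls)
}
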