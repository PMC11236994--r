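test_that("pearsonColoc matches cor() and honours the ROI mask", {
  set.seed(9)
  a <- matrix(runif(400), 20)
  b <- 0.5 * a + matrix(rnorm(400, sd = 0.1), 20)
  expect_equal(pearsonColoc(a, b), cor(as.vector(a), as.vector(b)))
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE
  expect_equal(pearsonColoc(a, b, mask), cor(a[mask], b[mask]))
  expect_equal(pearsonColoc(a, a), 1)
  expect_error(pearsonColoc(a, matrix(1, 20, 20)), "zero variance")
  one <- matrix(FALSE, 20, 20)
  one[1, 1] <- TRUE
  expect_error(pearsonColoc(a, b, one), "at least 2")
})

test_that("detectFoci segments components and drops small ones", {
  img <- matrix(0, 30, 30)
  img[5:9, 5:9] <- 10        # 25 px
  img[20:21, 20:21] <- 10    # 4 px, below default minArea
  foci <- detectFoci(img, threshold = 5, channel = "E")
  expect_length(foci, 1)
  expect_equal(foci[[1]]$area, 25)
  expect_equal(unname(foci[[1]]$centroid), c(7, 7))
  expect_equal(foci[[1]]$channel, "E")
  expect_length(detectFoci(img, threshold = 5, minArea = 3L), 2)
  ## diagonal-only neighbours are separate components (4-connectivity)
  img2 <- matrix(0, 10, 10)
  img2[2:4, 2:4] <- 10
  img2[5:7, 5:7] <- 10
  expect_length(detectFoci(img2, threshold = 5, minArea = 1L), 2)
  ## Otsu picks a threshold between the two intensity populations
  img3 <- matrix(2, 30, 30) + matrix(rnorm(900, sd = 0.1), 30)
  img3[10:15, 10:15] <- 20
  expect_length(detectFoci(img3, threshold = "otsu"), 1)
  expect_length(detectFoci(matrix(1, 5, 5)), 0)
})

test_that("fociContact implements the boundary-distance rule", {
  mk <- function(px) list(channel = "x", pixels = px,
                          centroid = colMeans(px), area = nrow(px))
  a <- mk(cbind(1:2, 1))
  touching <- mk(cbind(3, 1))      # distance 1
  gap <- mk(cbind(4, 1))           # distance 2
  diagonal <- mk(cbind(3, 2))      # distance sqrt(2)
  expect_true(fociContact(a, touching))
  expect_false(fociContact(a, gap))
  expect_false(fociContact(a, diagonal))
  expect_true(fociContact(a, diagonal, tol = 1.5))
})

test_that("classifyArrangement covers the taxonomy and its edge cases", {
  mk <- function(x, y) {
    px <- as.matrix(expand.grid(x + (-1:1), y + (-1:1)))
    list(channel = "x", pixels = unname(px), centroid = c(x, y), area = 9)
  }
  ## 3x3 blocks of radius 1: centres 3 apart leave a 1-pixel boundary gap,
  ## exactly the contact tolerance
  p <- mk(20, 20)
  eOn <- mk(20, 23)        # touches P
  eOff <- mk(20, 40)       # far from everything
  zOnE <- mk(20, 26)       # touches eOn only
  zFar <- mk(40, 40)
  expect_equal(classifyArrangement(p, list(eOn), list(zFar))$category,
               "EP_only")
  expect_equal(classifyArrangement(p, list(eOn), list(zOnE))$category,
               "EPZ")
  e2 <- mk(23, 20)
  expect_equal(classifyArrangement(p, list(eOn, e2), list(zOnE))$category,
               "multiE_P")
  ## two E on P but no Z contact is not multiE_P
  expect_equal(classifyArrangement(p, list(eOn, e2), list(zFar))$category,
               "other")
  expect_equal(classifyArrangement(p, list(eOff), list())$category, "other")
  expect_equal(classifyArrangement(p, list(), list())$category, "other")
  expect_error(classifyArrangement(NULL, list(eOn), list()), "P focus")
})

test_that("simulateFociImage renders recoverable foci with a truth graph", {
  layout <- data.frame(channel = c("P", "E", "Z"),
                       x = c(24, 24, 40), y = c(24, 32, 40),
                       radius = c(5, 4, 3.5), intensity = 100)
  field <- simulateFociImage(layout, imageSize = c(56L, 56L), noiseSd = 0,
                             seed = 2L)
  ## truth: P(1)-E(2) centres 8 apart <= 5+4+1; Z contacts nothing
  expect_equal(field$truth, data.frame(i = 1L, j = 2L))
  pf <- detectFoci(field$images$P, threshold = 50, channel = "P")
  expect_length(pf, 1)
  expect_equal(unname(pf[[1]]$centroid), c(24, 24), tolerance = 0.1)
  ## segmented disc at half maximum has roughly the nominal radius
  expect_lt(abs(sqrt(pf[[1]]$area / pi) - 5), 1)
  expect_error(simulateFociImage(transform(layout, x = c(2, 24, 40))),
               "fit inside")
  expect_error(simulateFociImage(
    data.frame(channel = "E", x = c(20, 22), y = 20, radius = 4,
               intensity = 100), imageSize = c(48L, 48L)),
    "resolvable")
})

test_that("a rendered cohort reclassifies to its generating categories", {
  cohort <- generateArrangementCohort(n = 40L, seed = 31L)
  calls <- classifyCohort(cohort)
  expect_equal(nrow(calls), 40)
  expect_gte(mean(calls$call == calls$truth), 0.95)
})
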