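# helper: fixture with hand-placed streamlines between the two parcels of a
# makeTractogramFixture() volume (parcel centers at x = 2 and x = 6)
two_parcel_fixture <- function(rows_yz, lesionSpec = NULL) {
  fx <- makeTractogramFixture(nParcels = 2L, nStreamlines = 0L,
                              lesionSpec = lesionSpec, seed = 1L)
  fx$streamlines <- lapply(rows_yz, function(yz)
    rbind(c(2, yz[1], yz[2]), c(6, yz[1], yz[2])))
  fx
}

test_that("endpoint parcels follow the affine/nearest-voxel convention", {
  fx <- makeTractogramFixture(nParcels = 3L, nStreamlines = 0L, seed = 1L)
  # straight streamline from parcel 1 into parcel 2
  expect_equal(endpointParcels(rbind(c(2, 5, 5), c(6, 5, 5)), fx$atlas),
               c(1L, 2L))
  # endpoint in background -> none
  expect_null(endpointParcels(rbind(c(0, 0, 0), c(6, 5, 5)), fx$atlas))
  # both endpoints in the same parcel -> none
  expect_null(endpointParcels(rbind(c(10, 4, 4), c(11, 6, 6)), fx$atlas))
  # endpoint outside the volume -> none, not an error
  expect_null(endpointParcels(rbind(c(-5, 5, 5), c(6, 5, 5)), fx$atlas))
})

test_that("normative connectome counts streamlines per parcel pair", {
  fx <- two_parcel_fixture(list(c(3, 5), c(4, 5), c(5, 5)))
  counts <- normativeConnectome(fx$streamlines, fx$atlas, 2L)
  expect_equal(counts, matrix(c(0L, 3L, 3L, 0L), 2))
  expect_equal(normativeConnectome(list(), fx$atlas, 2L),
               matrix(0L, 2, 2))
  # mixed random fixture agrees with the generator's exact enumeration
  fx2 <- makeTractogramFixture(nParcels = 4L, nStreamlines = 15L, seed = 9L)
  expect_equal(normativeConnectome(fx2$streamlines, fx2$atlas, 4L),
               fx2$truth$normative)
})

test_that("lesion-hit detection resamples between coarse vertices", {
  vol <- array(0L, dim = c(10, 10, 10))
  vol[6, 6, 6] <- 1L  # lesion voxel (5,5,5) zero-based
  attr(vol, "affine") <- diag(4)
  # diagonal 2-point streamline passing through (5,5,5) at its midpoint
  sl <- rbind(c(3, 3, 3), c(7, 7, 7))
  expect_true(streamlineHitsLesion(sl, vol))
  # dense independent check: points along the segment, nearest voxel
  tt <- seq(0, 1, length.out = 2001)
  pts <- round(cbind(3 + 4 * tt, 3 + 4 * tt, 3 + 4 * tt))
  expect_true(any(pts[, 1] == 5 & pts[, 2] == 5 & pts[, 3] == 5))
  # a streamline well away from the lesion
  expect_false(streamlineHitsLesion(rbind(c(1, 1, 1), c(8, 1, 1)), vol))
})

test_that("damage matrix gives exact disruption fractions", {
  # 3 streamlines between parcels (1,2); lesion transects exactly the y = 5
  # row -> SD[1,2] = 1/3
  fx <- two_parcel_fixture(list(c(3, 5), c(5, 5), c(7, 5)),
                           lesionSpec = list(x = c(4, 4), y = c(5, 5),
                                             z = c(0, 11)))
  dm <- lesionDamageMatrix(fx)
  expect_equal(dm$damage[1, 2], 1 / 3)
  expect_equal(dm$damage, t(dm$damage))
  expect_true(all(dm$disrupted <= dm$normative))

  # empty lesion -> zero damage
  fx0 <- makeTractogramFixture(nParcels = 3L, nStreamlines = 10L, seed = 2L)
  expect_equal(lesionDamageMatrix(fx0)$damage, matrix(0, 3, 3))

  # lesion covering the whole volume -> SD = 1 wherever normative > 0
  dims <- dim(fx0$atlas)
  fxall <- makeTractogramFixture(
    nParcels = 3L, nStreamlines = 10L, seed = 2L,
    lesionSpec = list(x = c(0, dims[1] - 1), y = c(0, dims[2] - 1),
                      z = c(0, dims[3] - 1)))
  dm2 <- lesionDamageMatrix(fxall)
  expect_equal(dm2$damage[dm2$normative > 0],
               rep(1, sum(dm2$normative > 0)))
})

test_that("damage grows monotonically with the lesion and stays in [0,1]", {
  set.seed(4)
  for (i in 1:15) {
    les1 <- list(x = sort(sample(0:13, 2)), y = sort(sample(2:9, 2)),
                 z = sort(sample(2:9, 2)))
    les2 <- list(x = c(max(0, les1$x[1] - 2), min(17, les1$x[2] + 2)),
                 y = c(max(0, les1$y[1] - 2), min(11, les1$y[2] + 2)),
                 z = les1$z)
    f1 <- makeTractogramFixture(4L, 12L, lesionSpec = les1, seed = i)
    f2 <- makeTractogramFixture(4L, 12L, lesionSpec = les2, seed = i)
    d1 <- lesionDamageMatrix(f1); d2 <- lesionDamageMatrix(f2)
    expect_true(all(d1$damage >= 0 & d1$damage <= 1))
    expect_true(all(d2$damage - d1$damage >= -1e-12))
    expect_true(all(d1$disrupted <= d1$normative))
    # and both match the generator's exact ground truth
    expect_equal(d1$damage, f1$truth$damage)
    expect_equal(d2$damage, f2$truth$damage)
  }
})

test_that("streamline TSV round-trips", {
  sls <- list(rbind(c(1, 2, 3), c(4, 5, 6)),
              rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1)))
  f <- tempfile(fileext = ".tsv")
  writeStreamlinesTSV(sls, f)
  back <- readStreamlinesTSV(f)
  expect_equal(length(back), 2L)
  expect_equal(unname(back[[2]]), sls[[2]], ignore_attr = TRUE)
})
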