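# Concrete simulated devices: light source, stage, filter wheel,
# deformable mirror, controller, and camera geometry.

test_that("light power is bounded, never clamped, and persists", {
  lt <- freshLight()
  expect_identical(getPower(lt), 0)
  setPower(lt, 1)
  expect_identical(getPower(lt), 1)
  setPower(lt, 0.37)
  expect_category(setPower(lt, 1.0001), "rangeError")
  expect_category(setPower(lt, -0.2), "rangeError")
  expect_identical(getPower(lt), 0.37)       # rejected writes don't clamp
  enable(lt); disable(lt); enable(lt)
  expect_identical(getPower(lt), 0.37)       # persists across enable/disable
})

test_that("light emission log records software activations at zero duration", {
  lt <- freshLight()
  enable(lt)
  setTrigger(lt, triggerConfig("software", "once"))
  setPower(lt, 0.5)
  trigger(lt)
  trigger(lt)
  log <- emissionLog(lt)
  expect_length(log, 2L)
  expect_identical(log[[1L]]$durationSeconds, 0)
  expect_identical(log[[2L]]$power, 0.5)
})

test_that("stage reports axes, limits and default positions", {
  st <- freshStage()
  expect_identical(axisNames(st), c("x", "y", "z"))
  expect_identical(axisPositions(st), c(x = 0, y = 0, z = 0))
  lims <- axisLimits(st)
  expect_identical(lims$z, c(lower = 0, upper = 100))
})

test_that("stage moves are atomic: any invalid axis leaves all unmoved", {
  st <- freshStage()
  moveTo(st, c(x = 10, y = 20))
  expect_identical(axisPositions(st)[c("x", "y")], c(x = 10, y = 20))
  # second axis out of range: first must not move either
  expect_category(moveTo(st, c(x = 50, z = 1e6)), "limitError")
  expect_identical(axisPositions(st), c(x = 10, y = 20, z = 0))
  expect_category(moveTo(st, c(x = 1, w = 2)), "unknownAxisError")
  expect_identical(axisPositions(st), c(x = 10, y = 20, z = 0))
  moveBy(st, c(z = 5, x = -3))
  expect_identical(axisPositions(st), c(x = 7, y = 20, z = 5))
  expect_category(moveBy(st, c(x = -100)), "limitError")
})

test_that("random stage walks always stay within limits", {
  set.seed(77)
  st <- freshStage()
  lims <- axisLimits(st)
  for (i in 1:300) {
    ax <- sample(c("x", "y", "z"), 1)
    tgt <- runif(1, -50, 150)
    ok <- tgt >= lims[[ax]][["lower"]] && tgt <= lims[[ax]][["upper"]]
    before <- axisPositions(st)
    if (ok) {
      moveTo(st, stats::setNames(tgt, ax))
      expect_equal(axisPositions(st)[[ax]], tgt)
    } else {
      expect_category(moveTo(st, stats::setNames(tgt, ax)), "limitError")
      expect_identical(axisPositions(st), before)
    }
    pos <- axisPositions(st)
    for (a in names(pos))
      expect_true(pos[[a]] >= lims[[a]][["lower"]] &&
                  pos[[a]] <= lims[[a]][["upper"]])
  }
})

test_that("filter wheel positions are 0-based and bounded", {
  fw <- freshWheel(6L)
  expect_identical(nPositions(fw), 6L)
  expect_identical(getFilterPosition(fw), 0L)
  setFilterPosition(fw, 5)
  expect_identical(getFilterPosition(fw), 5L)
  expect_category(setFilterPosition(fw, 6), "rangeError")
  expect_category(setFilterPosition(fw, -1), "rangeError")
  expect_identical(getFilterPosition(fw), 5L)
})

test_that("deformable mirror validates patterns and plays its queue in order", {
  dm <- freshMirror(69L)
  expect_identical(nActuators(dm), 69L)
  p1 <- rep(0.5, 69)
  applyPattern(dm, p1)
  expect_identical(currentPattern(dm), p1)
  expect_category(applyPattern(dm, rep(0.5, 68)), "validationError")
  expect_category(applyPattern(dm, c(rep(0.5, 68), 1.2)), "validationError")
  expect_identical(currentPattern(dm), p1)

  pats <- lapply(1:4, function(i) rep(i / 10, 69))
  queuePatterns(dm, pats)
  expect_identical(queueLength(dm), 4L)
  for (i in 1:4) {
    nextPattern(dm)
    expect_identical(currentPattern(dm), pats[[i]])
  }
  expect_identical(queueLength(dm), 0L)
  expect_category(nextPattern(dm), "emptyQueueError")
  applied <- appliedLog(dm)
  expect_identical(applied[[length(applied)]], pats[[4L]])
})

test_that("mirror advances through its queue on hardware edges", {
  dm <- freshMirror(10L)
  enable(dm)
  setTrigger(dm, triggerConfig("rising_edge", "once"))
  pats <- lapply(1:3, function(i) rep(i / 4, 10))
  queuePatterns(dm, pats)
  tpl <- compileTemplate(data.frame(tick = c(0, 5, 9),
                                    line = 0L, action = "pulse"))
  runTemplate(tpl, lineMapping(`0` = dm))
  expect_identical(queueLength(dm), 0L)
  expect_identical(currentPattern(dm), pats[[3L]])
})

test_that("controller exposes children that share its shutdown", {
  ctrl <- SimulatedController$new(name = "hub", nPositions = 4L)
  kids <- children(ctrl)
  expect_setequal(names(kids), c("wheel", "light"))
  expect_identical(nPositions(kids$wheel), 4L)
  setPower(kids$light, 0.8)
  expect_identical(getPower(kids$light), 0.8)
  shutdown(ctrl)
  expect_identical(deviceState(kids$wheel), "shut_down")
  expect_identical(deviceState(kids$light), "shut_down")
})

test_that("camera geometry: binning rescales the frame, ROI crops it", {
  cam <- SpotCamera$new(name = "cam", sensorShape = c(512L, 512L), seed = 1L)
  enable(cam)
  setTrigger(cam, triggerConfig("software", "once"))
  expect_identical(cam$sensorShape(), c(512L, 512L))

  trigger(cam)
  f <- fetchFrame(cam)
  expect_identical(dim(framePixels(f)), c(512L, 512L))

  setBinning(cam, 2, 2)
  expect_identical(cam$binnedShape(), c(256L, 256L))
  trigger(cam)
  expect_identical(dim(framePixels(fetchFrame(cam))), c(256L, 256L))

  # width 100, height 50 -> pixel matrix is 50 rows x 100 cols
  setROI(cam, roi(0, 0, 100, 50))
  trigger(cam)
  expect_identical(dim(framePixels(fetchFrame(cam))), c(50L, 100L))

  expect_category(setROI(cam, roi(200, 0, 100, 50)), "validationError")
  # changing binning resets ROI to the full binned sensor
  setBinning(cam, 1, 1)
  r <- getROI(cam)
  expect_identical(c(r@height, r@width), c(512L, 512L))
})

test_that("frame metadata: indices increase, exposure and timestamp recorded", {
  cam <- armedCamera()
  setExposure(cam, 0.025)
  for (i in 1:3) trigger(cam)
  idx <- integer(0)
  repeat {
    f <- fetchFrame(cam)
    if (is.null(f)) break
    idx <- c(idx, frameIndex(f))
    expect_identical(frameExposure(f), 0.025)
  }
  expect_identical(idx, 1:3)
  expect_category(setExposure(cam, 0), "validationError")
  expect_category(setExposure(cam, -1), "validationError")
})

test_that("camera buffer is bounded and drops oldest frames", {
  cam <- armedCamera(shape = c(8L, 8L))
  for (i in 1:300) trigger(cam)
  expect_identical(framesAvailable(cam), 256L)
  expect_identical(droppedFrames(cam), 44L)
  expect_identical(frameIndex(fetchFrame(cam)), 45L)  # oldest surviving
})

test_that("display_image_number stamps the acquisition counter", {
  cam <- armedCamera(shape = c(32L, 32L))
  setSetting(cam, "display_image_number", TRUE)
  trigger(cam); trigger(cam)
  f1 <- fetchFrame(cam); f2 <- fetchFrame(cam)
  expect_identical(framePixels(f1)[1L, 1L], 1L)
  expect_identical(framePixels(f2)[1L, 1L], 2L)
})
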