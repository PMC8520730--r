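# Device server: worker processes, transparent proxies, data sinks, fault
# recovery and isolation. One shared server is started here and stopped in
# the final block; every block degrades with a clear failure if startup
# failed.

.ports <- testPorts(4L)
.defs <- list(
  deviceDefinition("stage", "stage", port = .ports[[1L]], shareProcess = "stg"),
  deviceDefinition("stage2", "stage", port = .ports[[1L]], shareProcess = "stg"),
  deviceDefinition("light", "light", port = .ports[[2L]]),
  deviceDefinition("cam", "spot_camera", port = .ports[[3L]],
                   params = list(height = 48L, width = 48L, seed = 7L)),
  deviceDefinition("ctrl", "controller", port = .ports[[4L]],
                   params = list(positions = 4L))
)
.srv <- serveTestDevices(.defs)
.uri <- function(port, name) sprintf("scope://127.0.0.1:%d/%s", port, name)

test_that("all served devices are reachable and respond with their identity", {
  expect_length(.srv$uris(), 5L)
  for (d in .defs) {
    px <- connectDevice(definitionURI(d))
    expect_s4_class(px, "DeviceProxy")
    expect_identical(deviceName(px), d@name)
    expect_identical(deviceState(px), "created")
  }
})

test_that("definition validation refuses duplicate URIs and split share groups", {
  dup <- list(deviceDefinition("a", "light", port = 21001L),
              deviceDefinition("a", "light", port = 21001L))
  expect_category(serveDevices(dup), "startupError")
  split <- list(deviceDefinition("a", "light", port = 21001L, shareProcess = "g"),
                deviceDefinition("b", "light", port = 21002L, shareProcess = "g"))
  expect_category(serveDevices(split), "startupError")
})

test_that("connecting to a bad endpoint or unknown name fails cleanly", {
  expect_error(connectDevice("scope://127.0.0.1:1/nothing", timeoutSeconds = 2))
  expect_category(connectDevice(.uri(.ports[[1L]], "no_such_device")),
                  "connectionError")
  expect_category(connectDevice("not a uri"), "connectionError")
})

test_that("two proxies to one URI address the same single device instance", {
  a <- connectDevice(.uri(.ports[[2L]], "light"))
  b <- connectDevice(.uri(.ports[[2L]], "light"))
  enable(a)
  setPower(a, 0.62)
  expect_identical(getPower(b), 0.62)
  expect_identical(deviceState(b), "enabled")
  setPower(b, 0.11)
  expect_identical(getPower(a), 0.11)
})

test_that("remote errors re-raise client-side in the same category", {
  st <- connectDevice(.uri(.ports[[1L]], "stage"))
  expect_category(moveTo(st, c(z = 1e9)), "limitError")
  expect_category(moveTo(st, c(q = 1)), "unknownAxisError")
  cam <- connectDevice(.uri(.ports[[3L]], "cam"))
  expect_category(getSetting(cam, "nope"), "unknownSettingError")
  expect_category(setPower(cam, 0.5), "runtimeError")  # not a light
  expect_category(trigger(cam), "lifecycleError")      # not enabled yet
})

test_that("a random op sequence behaves identically locally and remotely", {
  remote <- connectDevice(.uri(.ports[[1L]], "stage2"))
  local <- freshStage()
  applyOp <- function(dev, op) {
    vsTry(switch(op$what,
      moveTo = moveTo(dev, op$targets),
      moveBy = moveBy(dev, op$targets),
      enable = enable(dev),
      disable = disable(dev),
      positions = axisPositions(dev)))
  }
  set.seed(606)
  ops <- lapply(1:50, function(i) {
    what <- sample(c("moveTo", "moveBy", "enable", "disable", "positions"), 1,
                   prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
    ax <- sample(c("x", "y", "z"), sample(1:2, 1))
    list(what = what,
         targets = stats::setNames(round(runif(length(ax), -20, 120), 3), ax))
  })
  for (op in ops) {
    resL <- applyOp(local, op)
    resR <- applyOp(remote, op)
    expect_identical(resL$ok, resR$ok)
    if (resL$ok) expect_identical(resL$value, resR$value)
    else expect_identical(resL$category, resR$category)
  }
  expect_identical(axisPositions(local), axisPositions(remote))
  expect_identical(deviceState(local), deviceState(remote))
})

test_that("a served camera streams frames to a network sink in index order", {
  cam <- connectDevice(.uri(.ports[[3L]], "cam"))
  enable(cam)
  setTrigger(cam, triggerConfig("software", "once"))
  # before registration frames fall back to the worker-side buffer
  trigger(cam)
  expect_identical(framesAvailable(cam), 1L)
  f <- fetchFrame(cam)
  expect_identical(frameIndex(f), 1L)

  sink <- frameSink(network = TRUE)
  on.exit(sink$closeSink(), add = TRUE)
  registerDataClient(cam, sink)
  for (i in 1:5) trigger(cam)
  frames <- collectFrames(sink, 5, timeoutSeconds = 20)
  expect_length(frames, 5L)
  expect_identical(vapply(frames, frameIndex, 0L), 2:6)
  expect_identical(framesAvailable(cam), 0L)   # nothing buffered remotely

  # re-registering replaces the previous sink
  sink2 <- frameSink(network = TRUE)
  on.exit(sink2$closeSink(), add = TRUE)
  registerDataClient(cam, sink2)
  trigger(cam)
  expect_length(collectFrames(sink2, 1, timeoutSeconds = 20), 1L)
  expect_length(sinkFrames(sink), 5L)          # old sink got nothing new
})

test_that("sink registration is refused for non-camera devices", {
  lt <- connectDevice(.uri(.ports[[2L]], "light"))
  sink <- frameSink(network = TRUE)
  on.exit(sink$closeSink())
  expect_category(registerDataClient(lt, sink), "registrationError")
})

test_that("a faulted device is reported, then transparently reinitialised", {
  st <- connectDevice(.uri(.ports[[1L]], "stage"))
  moveTo(st, c(x = 123))
  injectFault(st)
  expect_category(moveTo(st, c(x = 5)), "deviceFaultError")
  # same URI, fresh instance with default state
  expect_identical(axisPositions(st), c(x = 0, y = 0, z = 0))
  expect_identical(deviceState(st), "created")
  stats <- .srv$workerStats(.ports[[1L]])
  expect_identical(stats$reinits$stage, 1L)
  expect_identical(stats$reinits$stage2, 0L)
  logs <- paste(unlist(.srv$workerLogs()), collapse = "\n")
  expect_match(logs, "reinitialized stage")
})

test_that("controller children arrive as working proxies", {
  ctrl <- connectDevice(.uri(.ports[[4L]], "ctrl"))
  kids <- children(ctrl)
  expect_setequal(names(kids), c("wheel", "light"))
  expect_s4_class(kids$wheel, "DeviceProxy")
  expect_identical(nPositions(kids$wheel), 4L)
  setFilterPosition(kids$wheel, 2)
  expect_identical(getFilterPosition(kids$wheel), 2L)
  setPower(kids$light, 0.3)
  expect_identical(getPower(kids$light), 0.3)
  shutdown(ctrl)
  expect_identical(deviceState(kids$light), "shut_down")
})

test_that("slow operations on different workers overlap in real time", {
  a <- connectDevice(.uri(.ports[[2L]], "light"))
  b <- connectDevice(.uri(.ports[[3L]], "cam"))
  t0 <- Sys.time()
  callConcurrently(a, b, "slowOp", list(0.5), list(0.5))
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(wall, 0.9)    # serial execution would need >= 1.0 s
  expect_gte(wall, 0.5)
})

test_that("killing one worker leaves the others untouched", {
  .srv$killWorker(.ports[[2L]])
  Sys.sleep(0.3)
  lt <- DeviceProxy$new(port = .ports[[2L]], target = "light")
  expect_error(lt$remoteCall("getPower"))
  # neighbours unaffected
  st <- connectDevice(.uri(.ports[[1L]], "stage2"))
  expect_named(axisPositions(st), c("x", "y", "z"))
})

test_that("stopping the server shuts down every remaining worker", {
  .srv$stop()
  Sys.sleep(0.3)
  for (p in .ports[c(1L, 3L, 4L)]) {
    px <- DeviceProxy$new(port = p, target = "any")
    expect_error(px$remoteCall("deviceState"))
  }
})
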