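# Trigger engine: compilation, execution on the virtual clock, and the
# z-stack builder. Conservation: activations delivered == activations due.

test_that("compilation sorts stably by tick and normalises types", {
  tpl <- compileTemplate(data.frame(tick = c(9, 0, 9, 3),
                                    line = c(1, 0, 0, 1),
                                    action = c("raise", "pulse", "pulse", "pulse")))
  a <- templateActions(tpl)
  expect_identical(a$tick, c(0L, 3L, 9L, 9L))
  # stable: the two tick-9 rows keep their original relative order
  expect_identical(a$line[3:4], c(1L, 0L))
  expect_identical(a$action[3:4], c("raise", "pulse"))
})

test_that("compilation rejects malformed rows and redundant transitions", {
  expect_category(compileTemplate(data.frame(tick = -1, line = 0, action = "pulse")),
                  "compilationError")
  expect_category(compileTemplate(data.frame(tick = 0.5, line = 0, action = "pulse")),
                  "compilationError")
  expect_category(compileTemplate(data.frame(tick = 0, line = 0, action = "bounce")),
                  "compilationError")
  # double raise
  err <- expect_category(
    compileTemplate(data.frame(tick = c(0, 5), line = 0,
                               action = c("raise", "raise"))),
    "compilationError")
  expect_match(conditionMessage(err), "row 2")
  # lower while low
  expect_category(
    compileTemplate(data.frame(tick = 0, line = 0, action = "lower")),
    "compilationError")
  # pulse on a held-high line
  expect_category(
    compileTemplate(data.frame(tick = c(0, 3), line = 0,
                               action = c("raise", "pulse"))),
    "compilationError")
  # empty templates compile to zero actions
  expect_identical(nrow(templateActions(compileTemplate(NULL))), 0L)
})

test_that("three pulses produce three frames timestamped at the pulse ticks", {
  cam <- freshCamera()
  enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  tpl <- compileTemplate(data.frame(tick = c(2, 7, 11), line = 0L,
                                    action = "pulse"))
  log <- runTemplate(tpl, lineMapping(`0` = cam))
  expect_identical(framesAvailable(cam), 3L)
  stamps <- vapply(1:3, function(i) frameTimestamp(fetchFrame(cam)), 0)
  expect_identical(stamps, c(2, 7, 11))
  expect_identical(logEntries(log)$effect, rep("activated", 3L))
})

test_that("a falling-edge target activates on the pulse's falling edge only", {
  cam <- freshCamera()
  enable(cam)
  setTrigger(cam, triggerConfig("falling_edge", "once"))
  tpl <- compileTemplate(data.frame(tick = 4L, line = 0L, action = "pulse"))
  runTemplate(tpl, lineMapping(`0` = cam))
  expect_identical(framesAvailable(cam), 1L)   # one edge matched, not two
})

test_that("a held line gives a bulb exposure of exactly (lower - raise) ticks", {
  cam <- freshCamera()
  enable(cam)
  setTrigger(cam, triggerConfig("level_high", "bulb"))
  tpl <- compileTemplate(data.frame(tick = c(10, 25), line = 0L,
                                    action = c("raise", "lower")),
                         tickSeconds = 0.001)
  log <- runTemplate(tpl, lineMapping(`0` = cam))
  f <- fetchFrame(cam)
  expect_identical(frameExposure(f), 0.015)     # 15 ticks * 1 ms
  expect_identical(frameTimestamp(f), 10)       # stamped at exposure start
  expect_match(logEntries(log)$effect[[2L]], "duration=0.015")
})

test_that("an active-low bulb target exposes while its line is held low", {
  lt <- freshLight()
  enable(lt)
  setPower(lt, 0.6)
  setTrigger(lt, triggerConfig("level_low", "bulb"))
  # line starts low -> raise ends nothing until a lower opened an interval
  tpl <- compileTemplate(data.frame(tick = c(3, 5, 9), line = 0L,
                                    action = c("raise", "lower", "raise")),
                         tickSeconds = 0.01)
  runTemplate(tpl, lineMapping(`0` = lt))
  log <- emissionLog(lt)
  expect_length(log, 1L)
  expect_identical(log[[1L]]$tick, 5L)
  expect_identical(log[[1L]]$durationSeconds, 0.04)   # (9 - 5) * 10 ms
  expect_identical(log[[1L]]$power, 0.6)
})

test_that("disabled targets are skipped and logged as ignored", {
  cam <- freshCamera()
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  enable(cam); disable(cam)
  tpl <- compileTemplate(data.frame(tick = 0L, line = 0L, action = "pulse"))
  log <- runTemplate(tpl, lineMapping(`0` = cam))
  expect_identical(framesAvailable(cam), 0L)
  expect_match(logEntries(log)$effect[[1L]], "ignored")
})

test_that("mapping validation rejects incompatible trigger configurations", {
  cam <- freshCamera()
  enable(cam)
  pulseTpl <- compileTemplate(data.frame(tick = 0L, line = 0L, action = "pulse"))
  bulbTpl <- compileTemplate(data.frame(tick = c(0L, 4L), line = 0L,
                                        action = c("raise", "lower")))
  setTrigger(cam, triggerConfig("software", "once"))
  expect_category(runTemplate(pulseTpl, lineMapping(`0` = cam)),
                  "configurationError")
  setTrigger(cam, triggerConfig("level_high", "bulb"))
  expect_category(runTemplate(pulseTpl, lineMapping(`0` = cam)),
                  "configurationError")
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  expect_category(runTemplate(bulbTpl, lineMapping(`0` = cam)),
                  "configurationError")
  expect_category(runTemplate(pulseTpl, lineMapping(`1` = cam)),
                  "runtimeError")   # action on unmapped line
})

test_that("same-tick actions run in template row order (light before camera)", {
  lt <- freshLight(); enable(lt)
  setTrigger(lt, triggerConfig("level_high", "bulb"))
  cam <- freshCamera(); enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  tpl <- compileTemplate(data.frame(tick = c(5, 5, 15),
                                    line = c(1, 0, 1),
                                    action = c("raise", "pulse", "lower")))
  log <- logEntries(runTemplate(tpl, lineMapping(`0` = cam, `1` = lt)))
  expect_identical(log$target[log$tick == 5], c("light", "cam"))
  expect_identical(log$effect[[1L]], "activation start")
})

test_that("the event log is ordered and records one entry per action", {
  set.seed(1234)
  cam <- freshCamera(); enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  ticks <- sort(sample(0:500, 40))
  tpl <- compileTemplate(data.frame(tick = sample(ticks), line = 0L,
                                    action = "pulse"))
  log <- logEntries(runTemplate(tpl, lineMapping(`0` = cam)))
  expect_identical(nrow(log), 40L)
  expect_false(is.unsorted(log$tick))
  expect_identical(framesAvailable(cam), 40L)
})

test_that("activation conservation holds over random seeded templates", {
  # For seeded random pulse trains, frames delivered must equal pulses
  # emitted; for seeded raise/lower pairs, bulb activations must equal the
  # number of held intervals and each duration must be exact.
  for (seed in c(101L, 202L, 303L, 404L, 505L)) {
    set.seed(seed)
    nPulse <- sample(5:30, 1)
    pulseTicks <- sort(sample(0:1000, nPulse))
    cam <- freshCamera(shape = c(16L, 16L)); enable(cam)
    setTrigger(cam, triggerConfig("rising_edge", "once"))
    nHold <- sample(3:10, 1)
    edges <- sort(sample(0:1000, 2L * nHold))
    raises <- edges[seq(1L, length(edges), by = 2L)]
    lowers <- edges[seq(2L, length(edges), by = 2L)]
    lt <- freshLight(); enable(lt)
    setTrigger(lt, triggerConfig("level_high", "bulb"))
    ts <- 0.002
    rows <- rbind(
      data.frame(tick = pulseTicks, line = 0L, action = "pulse"),
      data.frame(tick = raises, line = 1L, action = "raise"),
      data.frame(tick = lowers, line = 1L, action = "lower"))
    tpl <- compileTemplate(rows, tickSeconds = ts)
    runTemplate(tpl, lineMapping(`0` = cam, `1` = lt))
    expect_identical(framesAvailable(cam) + droppedFrames(cam), nPulse)
    em <- emissionLog(lt)
    expect_length(em, nHold)
    got <- vapply(em, function(e) e$durationSeconds, 0)
    expect_identical(got, (lowers - raises) * ts)
  }
})

test_that("the z-stack builder emits one camera pulse per (z, channel)", {
  zs <- zstackTemplate(zPositions = c(0, 10, 20, 30, 40), channels = 0:1)
  a <- templateActions(zs$template)
  expect_identical(sum(a$action == "pulse" & a$line == 0L), 10L)
  expect_identical(sum(a$action == "raise" & a$line == 1L), 10L)
  expect_identical(sum(a$action == "lower" & a$line == 1L), 10L)
  # channel-major within z: wheel moves cycle 0,1,0,1,...
  wheelMoves <- zs$moves$value[zs$moves$device == "wheel"]
  expect_identical(wheelMoves, rep(c(0, 1), 5))
  stageMoves <- zs$moves$value[zs$moves$device == "stage"]
  expect_identical(stageMoves, rep(c(0, 10, 20, 30, 40), each = 2))
})

test_that("a minimal 1x1 z-stack with zero settle still runs correctly", {
  zs <- zstackTemplate(zPositions = 7, channels = 0L, settleTicks = 0L,
                       exposureTicks = 5L, tickSeconds = 0.001)
  st <- freshStage(); fw <- freshWheel(1L)
  cam <- freshCamera(); enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  lt <- freshLight(); enable(lt)
  setTrigger(lt, triggerConfig("level_high", "bulb"))
  runTemplate(zs$template, lineMapping(`0` = cam, `1` = lt),
              moves = zs$moves, stage = st, wheel = fw)
  expect_identical(framesAvailable(cam), 1L)
  expect_identical(axisPositions(st)[["z"]], 7)
  expect_length(emissionLog(lt), 1L)
  expect_identical(emissionLog(lt)[[1L]]$durationSeconds, 0.005)
})

test_that("moves execute before line actions at the same tick", {
  zs <- zstackTemplate(zPositions = c(10, 20), channels = 0L,
                       settleTicks = 0L, exposureTicks = 2L)
  st <- freshStage(); fw <- freshWheel(1L)
  smp <- makeTestSample(nChannels = 1L)
  cam <- VirtualSampleCamera$new(name = "vcam", sample = smp, stage = st,
                                 wheel = fw, blur = blurModel(focalZ = 10),
                                 sensorShape = c(32L, 32L))
  enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  lt <- freshLight(); enable(lt)
  setTrigger(lt, triggerConfig("level_high", "bulb"))
  runTemplate(zs$template, lineMapping(`0` = cam, `1` = lt),
              moves = zs$moves, stage = st, wheel = fw)
  # with settleTicks = 0 the move and the pulse share a tick; each frame
  # must still see the post-move z exactly
  first <- framePixels(fetchFrame(cam))
  second <- framePixels(fetchFrame(cam))
  expect_identical(first,
                   acquireVirtual(smp, c(x = 0, y = 0, z = 10), 0L,
                                  blurModel(focalZ = 10), roi(0L, 0L, 32L, 32L)))
  expect_identical(second,
                   acquireVirtual(smp, c(x = 0, y = 0, z = 20), 0L,
                                  blurModel(focalZ = 10), roi(0L, 0L, 32L, 32L)))
  expect_false(identical(first, second))
})

test_that("templates and event logs round-trip through files", {
  tpl <- compileTemplate(data.frame(tick = c(0, 5, 15), line = c(0, 1, 1),
                                    action = c("pulse", "raise", "lower")),
                         tickSeconds = 0.004)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeTemplate(tpl, path)
  back <- readTemplate(path)
  expect_identical(templateActions(back), templateActions(tpl))
  expect_identical(templateTickSeconds(back), 0.004)

  cam <- freshCamera(); enable(cam)
  setTrigger(cam, triggerConfig("rising_edge", "once"))
  lt <- freshLight(); enable(lt)
  setTrigger(lt, triggerConfig("level_high", "bulb"))
  log <- runTemplate(tpl, lineMapping(`0` = cam, `1` = lt))
  logPath <- tempfile(fileext = ".tsv")
  on.exit(unlink(logPath), add = TRUE)
  writeEventLog(log, logPath)
  txt <- readLines(logPath)
  expect_identical(length(txt), nrow(logEntries(log)) + 1L)  # header + rows
})
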