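# Shared builders and independent oracles for the suite. Fixtures are
# always generated in code; nothing is read from disk.

freshCamera <- function(seed = 3L, shape = c(64L, 64L)) {
  SpotCamera$new(name = "cam", sensorShape = shape, seed = seed)
}

freshStage <- function() Stage$new(name = "stage")
freshWheel <- function(n = 6L) FilterWheel$new(name = "wheel", nPositions = n)
freshLight <- function() LightSource$new(name = "light")
freshMirror <- function(n = 69L) DeformableMirror$new(name = "mirror", nActuators = n)

armedCamera <- function(seed = 3L, shape = c(64L, 64L)) {
  cam <- freshCamera(seed, shape)
  enable(cam)
  setTrigger(cam, triggerConfig("software", "once"))
  cam
}

# Brute-force first-moment oracle: background-subtracted intensity centroid
# over all pixels, in (x, y) = (col, row), 0-based.
centroidOracle <- function(pixels, background) {
  w <- pmax(as.numeric(pixels) - background, 0)
  w <- matrix(w, nrow(pixels), ncol(pixels))
  total <- sum(w)
  rows <- row(w) - 1
  cols <- col(w) - 1
  c(x = sum(w * cols) / total, y = sum(w * rows) / total)
}

# Brute-force second-moment oracle for an isotropic Gaussian's sigma.
sigmaOracle <- function(pixels, background) {
  w <- pmax(as.numeric(pixels) - background, 0)
  w <- matrix(w, nrow(pixels), ncol(pixels))
  ctr <- centroidOracle(pixels, background)
  d2 <- (col(w) - 1 - ctr[["x"]])^2 + (row(w) - 1 - ctr[["y"]])^2
  sqrt(sum(w * d2) / (2 * sum(w)))
}

expect_category <- function(expr, category) {
  err <- tryCatch({ expr; NULL }, error = function(e) e)
  expect_false(is.null(err), label = "expected an error")
  expect_identical(errorCategory(err), category)
  invisible(err)
}

# A small served microscope shared by networking tests; stopped via
# withr-style on.exit in each test that uses it.
serveTestDevices <- function(defs) {
  srv <- serveDevices(defs, startupTimeout = 60)
  srv
}

testPorts <- function(n) {
  vapply(seq_len(n), function(i) virtuscope:::freePort(), 0)
}

# Internal helpers the tests lean on directly.
clipU16 <- virtuscope:::clipU16
vsTry <- virtuscope:::vsTry
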