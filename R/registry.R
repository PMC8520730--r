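#' Device-kind registry
#'
#' Maps the `kind` strings used in device-definition configuration files to
#' constructors. A definition's `params` are passed to the constructor as
#' named arguments. Kinds shipped with the package:
#' `"spot_camera"`, `"virtual_sample_camera"`, `"light"`, `"filterwheel"`,
#' `"stage"`, `"mirror"`, `"controller"`.
#'
#' The virtual-sample camera references sibling devices by name through the
#' `stage` and `wheel` params; this only works when the devices are served
#' from the same process (a `share_process` group) or built in-process.
#'
#' @param kind registered device-kind string.
#' @param params named list of construction parameters.
#' @param name device name.
#' @param siblings named list of already-constructed devices in the same
#'   process, for by-name references.
#' @return a new [Device] instance.
#' @export
createDevice <- function(kind, params = list(), name = kind, siblings = list()) {
  resolveRef <- function(key) {
    ref <- params[[key]]
    if (is.character(ref)) {
      dev <- siblings[[ref]]
      if (is.null(dev))
        vsError("startupError",
                sprintf("device '%s': no sibling device named '%s' for param '%s'",
                        name, ref, key))
      dev
    } else ref
  }
  num <- function(key, default = NULL) {
    v <- params[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  switch(kind,
    light = LightSource$new(name = name),
    filterwheel = FilterWheel$new(name = name,
                                  nPositions = as.integer(num("positions", 6))),
    stage = {
      axes <- params[["axes"]]
      if (is.character(axes)) axes <- parseAxesSpec(axes)
      if (is.null(axes)) Stage$new(name = name)
      else Stage$new(name = name, axes = axes)
    },
    mirror = DeformableMirror$new(name = name,
                                  nActuators = as.integer(num("actuators", 69))),
    controller = SimulatedController$new(name = name,
                                         nPositions = as.integer(num("positions", 6))),
    spot_camera = SpotCamera$new(name = name,
      sensorShape = c(as.integer(num("height", 512)), as.integer(num("width", 512))),
      seed = as.integer(num("seed", 1))),
    virtual_sample_camera = {
      sample <- params[["sample"]]
      if (is.null(sample))
        sample <- makeTestSample(
          nChannels = as.integer(num("channels", 2)),
          H = as.integer(num("sample_height", 256)),
          W = as.integer(num("sample_width", 256)),
          nSpots = as.integer(num("spots", 30)),
          seed = as.integer(num("seed", 1)))
      VirtualSampleCamera$new(name = name, sample = sample,
        stage = resolveRef("stage"), wheel = resolveRef("wheel"),
        blur = blurModel(focalZ = num("focal_z", 0),
                         coefficient = num("blur_coefficient", 0.5)))
    },
    vsError("startupError", sprintf("unknown device kind '%s'", kind))
  )
}

# "x:0:1000:0;y:0:1000:0;z:0:100:0" -> list of AxisDescriptor
parseAxesSpec <- function(text) {
  parts <- strsplit(strsplit(text, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) < 3L)
      vsError("startupError", "axis spec must be name:lower:upper[:position]")
    axisDescriptor(p[[1L]], as.numeric(p[[2L]]), as.numeric(p[[3L]]),
                   if (length(p) >= 4L) as.numeric(p[[4L]]) else as.numeric(p[[2L]]))
  })
}
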