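# virtuscope

Hardware-free microscope control and acquisition simulation for R.

## The problem

Code that runs automated microscopes — sequencing exposures with hardware
triggers, synchronising stages and filter wheels with cameras, recovering
from device faults, streaming frames to analysis — is some of the hardest
code in a lab to test. The behaviour that matters only emerges when
several instruments interact, real instruments are scarce and stateful,
and timing bugs hide until the night the experiment runs. `virtuscope`
rebuilds that entire stack in software with the same contracts hardware
drivers honour, so control and analysis code can be developed and tested
end to end, deterministically, in seconds, with nothing attached.

## What is in the box

- **A typed device model.** Cameras, light sources, filter wheels, stages,
  deformable mirrors and integrated controllers share one lifecycle
  (`created` / `enabled` / `disabled` / terminal `shut_down`), a typed and
  bounded settings map, and structured error categories (`limitError`,
  `rangeError`, `lifecycleError`, ...). Safety rules are enforced, never
  clamped: a light source rejects power outside [0, 1], a stage rejects a
  multi-axis move if *any* axis would exceed its limits — and moves none.
- **A trigger engine on a virtual clock.** Experiments are compiled
  templates of `(tick, line, action)` rows. Compilation rejects redundant
  line transitions with the offending row number; execution activates
  edge- and level-triggered devices exactly, with bulb durations equal to
  `(lower tick − raise tick) × tickSeconds`. No real time passes and no
  code sleeps, so runs are pure functions of their inputs.
- **Simulated instruments.** A Gaussian-spot camera renders seeded random
  spots with analytic ground truth; a stage-aware camera images a
  multi-channel virtual sample, windowed by stage position, channel-selected
  by the filter wheel, and defocused by `sigma = coefficient × |z − focalZ|`
  (bit-exact identity at focus).
- **A device server.** Each device definition is published at
  `scope://host:port/name` from its own worker process. Clients hold
  transparent proxies: the same generics work locally and remotely, remote
  errors re-raise in their original category, controller children arrive
  as proxies, a faulted device is reinitialised behind the same URI, and
  cameras push frames asynchronously to registered data sinks.
- **Command-line tools.** `inst/scripts/` ships `scope-server`,
  `scope-inspect`, `scope-zstack` and `scope-demo-spots` wrapping the
  exported functions `serveDevices()`, `cliInspect()`, `cliZstack()` and
  `cliDemoSpots()`.

## A worked example

A seeded spot frame has exact ground truth:

```r
library(virtuscope)
st <- spotStream(c(64, 64), seed = 7)
img <- st$nextFrame()
st$lastSpot()
#> center: 50.567, 27.512   sigma: 2.231   amplitude: 813.9
```

A brute-force intensity centroid of `img` returns `(50.568, 27.513)` —
within 0.001 px of the logged centre.

Inspecting a device:

```r
sim <- makeSimMicroscope(seed = 1)
cliInspect(sim$stage)
#> kind: stage
#> name: stage
#> state: created
#> trigger: unset
#> axis x: position=0 lower=0 upper=10000
#> axis y: position=0 lower=0 upper=10000
#> axis z: position=0 lower=0 upper=100
```

A two-channel z-stack, sequenced entirely by the trigger engine:

```r
res <- cliZstack(z = c(20, 25, 30), channels = 0:1, out = "stack.tif", seed = 1)
length(res$frames)
#> [1] 6
head(logEntries(res$log), 5)
#>   tick line action target                          effect
#> 1    0   NA   move  stage                            z=20
#> 2    0   NA   move  wheel                      position=0
#> 3    2    1  raise  light                activation start
#> 4    2    0  pulse camera                       activated
#> 5   12    1  lower  light activation end, duration=0.01 s
```

The six 128×128 pages land in `stack.tif` (page metadata in
`stack.tif.meta.tsv`: z, channel, exposure per page). The in-focus page
(z = 25) has pixel variance 43889.6 against 20261.1 for the defocused
z = 20 page — defocus visibly lowers contrast — and is bit-identical to
the corresponding virtual-sample window.

The same script runs against served devices:

```r
srv <- serveDevices(list(
  deviceDefinition("stage",  "stage",       port = 40001, shareProcess = "rig"),
  deviceDefinition("wheel",  "filterwheel", port = 40001, shareProcess = "rig",
                   params = list(positions = 2)),
  deviceDefinition("light",  "light",       port = 40001, shareProcess = "rig"),
  deviceDefinition("camera", "virtual_sample_camera", port = 40001,
                   shareProcess = "rig",
                   params = list(stage = "stage", wheel = "wheel", focal_z = 25))))
devices <- list(stage  = connectDevice("scope://127.0.0.1:40001/stage"),
                wheel  = connectDevice("scope://127.0.0.1:40001/wheel"),
                light  = connectDevice("scope://127.0.0.1:40001/light"),
                camera = connectDevice("scope://127.0.0.1:40001/camera"))
cliZstack(z = c(20, 25), channels = 0:1, out = "remote.tif", devices = devices)
srv$stop()
```

and produces pixel-identical pages, with frames delivered over an
asynchronous network sink.

## Documentation

Function documentation is in the roxygen comments throughout `R/`; the
methods vignette (`vignettes/virtuscope-methods.Rmd`) describes the models,
the trigger taxonomy, the defocus law and the known limitations.

## License

MIT, see `LICENSE`.
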