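Package: virtuscope
Title: Hardware-Free Microscope Control and Acquisition Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Typed abstractions for microscope devices (cameras, light
    sources, filter wheels, stages, deformable mirrors and integrated
    controllers) with a shared lifecycle, a bounded settings map and a
    uniform trigger-target contract; a deterministic trigger engine that
    compiles experiment templates into timed digital-line actions and
    drives devices on a virtual clock; simulated devices including a
    Gaussian-spot camera and a stage-aware virtual-sample camera with
    defocus blur and filter-wheel channel selection; a device server that
    publishes each device at a network endpoint in its own worker process
    with transparent client proxies, fault-triggered reinitialisation and
    asynchronous frame delivery to registered data clients; and
    command-line tools for device inspection and scripted multichannel
    z-stack acquisition to multi-page TIFF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'settings.R'
    'trigger-config.R'
    'frame.R'
    'device.R'
    'generics.R'
    'camera.R'
    'light.R'
    'filterwheel.R'
    'stage.R'
    'mirror.R'
    'controller.R'
    'virtual-sample.R'
    'simulated.R'
    'registry.R'
    'trigger-engine.R'
    'template-io.R'
    'config.R'
    'wire.R'
    'sink.R'
    'worker.R'
    'server.R'
    'proxy.R'
    'tiff-io.R'
    'cli.R'
    'zzz.R'
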