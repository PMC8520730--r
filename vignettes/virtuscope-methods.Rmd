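---
title: "Simulating a triggered microscope: models and design choices"
author: "virtuscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a triggered microscope: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtuscope)
```

## Why a hardware-free microscope

Automated-microscopy control code is notoriously hard to test: the
interesting behaviour — device lifecycles, hardware-triggered timing,
stage-synchronised acquisition, recovery from device faults — only shows up
when several instruments interact, and real instruments are scarce,
stateful and slow. `virtuscope` reproduces that whole stack in software.
Every component a scripted experiment touches has a simulated counterpart
that honours the same contracts a hardware driver would: cameras produce
frames only when triggered, light sources bound their power, stages refuse
to exceed their limits, and a trigger engine sequences everything on a
virtual clock. Control and analysis code written against this package
exercises the same code paths it would against instruments, and the entire
test suite runs in seconds with no hardware attached.

## The device model

All devices share one lifecycle — `created`, `enabled`, `disabled`,
`shut_down` — where `shut_down` is terminal and absorbing; every other
transition is allowed and idempotent where it should be (enabling an
enabled device is a no-op, shutting down twice is a no-op). Device-specific
features beyond the typed interface live in a *settings map* of named,
typed, bounded descriptors (`integer`, `real`, `enumerated`, `boolean`,
`text`), so generic UIs and persistence layers can manipulate any device
without knowing its type. A raw setting may share state with an
interface-level property (the spot camera's `binning_h`/`binning_v` and
its binning property are one piece of state), mirroring how vendor SDKs
expose the same knob at two levels.

Errors are structured conditions with a category
(`lifecycleError`, `limitError`, `rangeError`, `validationError`,
`triggerMismatchError`, ...) rather than strings, so callers and the remote
layer can re-raise them faithfully.

## Triggers: a closed taxonomy

A device that can act on a hardware signal is a *trigger target* with a
trigger configuration of type and mode. The representable combinations are
deliberately closed:

| type | modes |
|---|---|
| `software` | `once` |
| `rising_edge`, `falling_edge` | `once`, `strobe` |
| `level_high`, `level_low` | `bulb` |

The rationale: a software trigger is a direct call, so repetition modes are
meaningless; an edge carries no duration, so it cannot parameterise a bulb
exposure; a level has no repetition, so only bulb applies. Making invalid
combinations unrepresentable (`triggerConfig()` rejects them at
construction) removes a whole class of silent misconfiguration — a device
never has to decide at activation time what a nonsensical configuration
"meant".

## The trigger engine and the virtual clock

Experiments are *templates*: rows of `(tick, line, action)` with actions
`pulse`, `raise`, `lower`, compiled by `compileTemplate()`. Compilation
sorts stably by tick and simulates line levels, rejecting redundant
transitions (raising a high line, lowering a low one, pulsing a held line)
with an error naming the offending row — catching timing bugs before
anything runs. Execution by `runTemplate()` maps lines to devices and
walks the rows on a *virtual clock*: no real time passes, a tick is a unit
of `tickSeconds`, and a bulb activation's duration is exactly
`(lower tick - raise tick) * tickSeconds`. Determinism follows: the run is
a pure function of the template, the mapping and the device states, and
timing assertions in tests are exact rather than tolerance-based. Within a
tick, template row order is preserved, and interleaved stage/wheel moves
execute before line actions at the same tick, so "move then expose at tick
t" means what it says.

## The virtual sample and the defocus law

The stage-aware camera images a `VirtualSample`: a multi-channel mosaic
with a geometry (`unitsPerPixel`) and a constant background. Acquisition
crops the window whose top-left mosaic pixel is
`round(position / unitsPerPixel)` offset by the ROI, selects the channel
plane from the filter-wheel position, and applies defocus blur with

```
sigma = coefficient * |z - focalZ|
```

a linear approximation to the growth of the defocused point-spread
function's width near focus — deliberately the simplest model with the two
properties the tests rely on: it is exactly zero at focus and strictly
monotone in defocus distance. The blur is a separable Gaussian convolution
with the kernel truncated at `4 * sigma` (mass beyond that is below 1e-4
and invisible in 16-bit data). Two numerical choices matter:

* the convolution runs on a window enlarged by the kernel radius and then
  cropped ("valid" convolution), so edge pixels are blurred with real —
  or constant-background — neighbours instead of artificial reflections;
* at `sigma == 0` no kernel is built at all, so the in-focus path is the
  identity on the mosaic, bit for bit. Tests can therefore assert
  `identical()` rather than "close to".

Out-of-mosaic reads pad with the constant background, so navigation code
can roam beyond the sample without special cases. Values are rounded and
clipped to the unsigned 16-bit range at the very end.

## The Gaussian-spot generator: realism and limits

`spotStream()` renders one isotropic 2-D Gaussian per frame at a
uniform-random subpixel centre, with width and amplitude drawn from
configurable ranges, over a constant background — the classic synthetic
target for centroiding and alignment code, because its ground truth is
exact and its moments are analytic. Centres keep a margin of three maximum
widths from the border so the full spot is inside the frame and moment
estimates are unbiased. The stream holds a private RNG state seeded at
construction: the caller's RNG is never disturbed, and a given seed yields
a bit-identical sequence forever, which is what makes byte-identical
output files testable.

The generator is deliberately idealised: no photon shot noise, no read
noise, no pixelation beyond sampling the Gaussian at pixel centres, no
aberrations. That is a feature for contract tests (errors measure the
algorithm, not the noise) and a limitation for algorithm benchmarking —
detection-limit studies need a noise model layered on top.

## Remote devices

`serveDevices()` publishes each device definition at
`scope://host:port/name`, one worker *process* per definition (or per
`share_process` group), so a blocking operation on one device never stalls
another — real concurrency, not cooperative scheduling. Clients hold
transparent proxies: the same generics dispatch locally or over the wire,
remote errors re-raise in their original category, and controller children
come back as working proxies. Two behaviours are contractual:

* **fault transparency** — a faulted device raises `deviceFaultError`
  once, the worker reinitialises it from its definition, and the same URI
  serves a fresh instance on the next call;
* **asynchronous data** — a camera pushes frames to a registered sink
  *after* answering the triggering call, so acquisition is never blocked
  by a slow consumer; the sink-side buffer is bounded (256 frames,
  drop-oldest, logged).

The wire format is R's native serialization over TCP with one request per
connection — small, dependency-free, and sufficient for the request sizes
involved (frames are tens of kilobytes).

## Resolved design questions

Two contracts were underdetermined and are fixed as follows. *Settings
writes while a device is enabled and trigger-configured are permitted*:
real instruments accept parameter changes between exposures, and
forbidding them would push state machines into every caller.
*Reinitialisation after a fault resets the device to its constructed
defaults* rather than attempting to restore pre-fault state: restoring
state that may itself have caused the fault is the worse failure mode, and
the reinitialisation count is observable so callers can re-apply settings.

## Problem sizes

The shipped defaults — 256x256 two-channel mosaics, 128x128 sensors,
z-stacks of a few positions, 100-operation equivalence runs — are chosen
so the full test suite completes in well under a minute while every
contract is still exercised at non-trivial size. All generators scale:
nothing in the implementation depends on these sizes.

## Known limitations

* No noise model; simulated images are exact renders.
* The defocus law is linear and isotropic; no depth-dependent aberrations.
* TIFF page metadata lives in a `.meta.tsv` sidecar because the available
  writer does not emit per-page description tags.
* The wire protocol trusts its peer (native deserialization); the server
  is meant for localhost test rigs, not untrusted networks.
* Timing is virtual: the engine verifies orderings and durations on the
  virtual clock, not real-time jitter.

## A worked example

```{r example}
out <- tempfile(fileext = ".tif")
res <- cliZstack(z = c(20, 25, 30), channels = 0:1, out = out, seed = 1)
length(res$frames)                      # 3 z positions x 2 channels
head(logEntries(res$log), 8)
unlink(c(out, paste0(out, ".meta.tsv")))
```
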