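#' Device: shared lifecycle, settings map and trigger-target contract
#'
#' All device types (camera, light source, filter wheel, stage, deformable
#' mirror, controller) share one lifecycle — `created` -> `enabled` <->
#' `disabled` -> `shut_down`, with `shut_down` terminal — a map of typed,
#' bounded device-specific settings, and a trigger-target contract: each
#' device holds a [TriggerConfig-class] and is activated either by a
#' software [trigger()] call or by the trigger engine's digital-line events.
#'
#' Devices are mutable reference objects; use the exported generics
#' ([enable()], [setSetting()], [trigger()], ...) rather than calling
#' reference methods directly — the same generics work transparently on
#' remote device proxies.
#'
#' @field .name device name (used by the server registry).
#' @field .state lifecycle state string.
#' @export Device
#' @exportClass Device
Device <- setRefClass("Device",
  fields = list(
    .name = "character",
    .state = "character",
    .settingDefs = "list",    # name -> SettingDescriptor, declaration order
    .settingGet = "list",     # name -> function() value
    .settingSet = "list",     # name -> function(value) (validated value)
    .trigger = "ANY",         # TriggerConfig or NULL
    .faultArmed = "logical",
    .levelOpenTick = "numeric"  # tick at which a bulb activation opened, or NA
  ),
  methods = list(
    initialize = function(..., name = "device") {
      initFields(.name = name, .state = "created",
                 .settingDefs = list(), .settingGet = list(), .settingSet = list(),
                 .trigger = NULL, .faultArmed = FALSE, .levelOpenTick = NA_real_)
      callSuper(...)
    },

    assertNotShutDown = function() {
      if (identical(.state, "shut_down"))
        vsError("lifecycleError", sprintf("device '%s' is shut down", .name))
    },
    assertEnabled = function() {
      if (!identical(.state, "enabled"))
        vsError("lifecycleError",
                sprintf("device '%s' is %s, not enabled", .name, .state))
    },
    maybeFault = function() {
      if (isTRUE(.faultArmed)) {
        .faultArmed <<- FALSE
        vsError("deviceFaultError",
                sprintf("device '%s' raised an unrecoverable fault", .name))
      }
    },

    # -- settings map ----------------------------------------------------
    # Declare one setting. By default the value lives in an internal cell;
    # pass get/set to back the setting with shared state (the name-clash
    # rule: an interface property and a raw setting may coexist under
    # distinct names over the same underlying state).
    declareSetting = function(desc, initial = NULL, get = NULL, set = NULL) {
      nm <- desc@name
      .settingDefs[[nm]] <<- desc
      if (is.null(get)) {
        cell <- new.env(parent = emptyenv())
        cell$value <- initial
        get <- function() cell$value
        set <- function(value) cell$value <- value
      }
      .settingGet[[nm]] <<- get
      .settingSet[[nm]] <<- if (is.null(set)) function(value) NULL else set
      invisible(NULL)
    },
    describeSettings = function() {
      assertNotShutDown()
      unname(.settingDefs)
    },
    getSetting = function(name) {
      assertNotShutDown()
      if (is.null(.settingDefs[[name]]))
        vsError("unknownSettingError", sprintf("no setting named '%s'", name))
      .settingGet[[name]]()
    },
    setSetting = function(name, value) {
      assertNotShutDown()
      maybeFault()
      desc <- .settingDefs[[name]]
      if (is.null(desc))
        vsError("unknownSettingError", sprintf("no setting named '%s'", name))
      if (desc@readOnly)
        vsError("permissionError", sprintf("setting '%s' is read-only", name))
      stored <- checkSettingValue(desc, value)
      .settingSet[[name]](stored)
      stored
    },

    # -- lifecycle -------------------------------------------------------
    enable = function() {
      assertNotShutDown()
      if (!identical(.state, "enabled")) { onEnable(); .state <<- "enabled" }
      .state
    },
    disable = function() {
      assertNotShutDown()
      if (identical(.state, "enabled")) onDisable()
      .state <<- "disabled"
      .state
    },
    shutdown = function() {
      if (!identical(.state, "shut_down")) { onShutdown(); .state <<- "shut_down" }
      .state
    },
    deviceState = function() .state,
    onEnable = function() invisible(NULL),
    onDisable = function() invisible(NULL),
    onShutdown = function() invisible(NULL),

    # -- trigger-target contract ----------------------------------------
    setTrigger = function(config) {
      assertNotShutDown()
      stopifnot(is(config, "TriggerConfig"))
      .trigger <<- config
      invisible(NULL)
    },
    getTrigger = function() .trigger,
    trigger = function() {
      assertEnabled()
      if (is.null(.trigger) || !identical(.trigger@triggerType, "software"))
        vsError("triggerMismatchError",
                sprintf("device '%s' is not configured for software triggering", .name))
      maybeFault()
      activateOnce(tick = NA_real_, tickSeconds = NA_real_)
      invisible(NULL)
    },

    # One discrete activation (software call or matching edge). Overridden
    # by trigger-target device types; other types are not trigger targets.
    activateOnce = function(tick, tickSeconds) {
      vsError("runtimeError",
              sprintf("device '%s' is not a trigger target", .name))
    },
    # Bulb activation: the active interval opens on the matching level
    # transition and closes on the opposite one.
    activateLevelStart = function(tick) {
      vsError("runtimeError",
              sprintf("device '%s' is not a level trigger target", .name))
    },
    activateLevelEnd = function(tick, durationSeconds) {
      vsError("runtimeError",
              sprintf("device '%s' is not a level trigger target", .name))
    },

    # -- fault injection (simulated hardware failure) --------------------
    injectFault = function() {
      assertNotShutDown()
      .faultArmed <<- TRUE
      invisible(NULL)
    },

    # Artificial slow operation; used to demonstrate that devices served
    # from separate worker processes do not serialise on a shared lock.
    slowOp = function(seconds) {
      assertNotShutDown()
      Sys.sleep(seconds)
      seconds
    },

    deviceKind = function() "device",
    deviceName = function() .name,
    show = function() {
      cat(sprintf("<%s> '%s' state=%s settings=%d\n",
                  deviceKind(), .name, .state, length(.settingDefs)))
    }
  )
)
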