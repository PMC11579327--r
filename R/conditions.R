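# Classed conditions so callers (and the CLI) can distinguish bad user input
# from configuration problems and from mathematical singularities.

abort_isonox <- function(msg, class) {
  stop(structure(
    class = c(class, "isonox_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid <- function(msg) abort_isonox(msg, "isonox_invalid_input")
stop_config  <- function(msg) abort_isonox(msg, "isonox_config_error")
stop_singular <- function(msg) abort_isonox(msg, "isonox_singularity")
stop_parse   <- function(msg) abort_isonox(msg, "isonox_parse_error")
stop_domain  <- function(msg) abort_isonox(msg, "isonox_domain_error")
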