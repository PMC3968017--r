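# Classed conditions so callers (and tests) can distinguish failure modes.

stop_ntp <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ntp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_parse <- function(msg) stop_ntp(msg, "ntp_parse_error")
stop_layout <- function(msg) stop_ntp(msg, "ntp_layout_error")
stop_domain <- function(msg) stop_ntp(msg, "ntp_domain_error")
stop_state <- function(msg) stop_ntp(msg, "ntp_state_error")
stop_consistency <- function(msg) stop_ntp(msg, "ntp_consistency_error")
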