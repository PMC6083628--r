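# Classed error conditions so callers (and the command-line front-end) can
# distinguish configuration problems, bad input data and failed optimizations.

dv_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dietvalid_error", "error")))
}

dv_config_error <- function(msg) dv_error(msg, "dietvalid_config_error")

dv_input_error <- function(msg) dv_error(msg, "dietvalid_input_error")

dv_convergence_error <- function(msg) dv_error(msg, "dietvalid_convergence_error")
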