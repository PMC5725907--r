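# Classed conditions so callers can distinguish bad inputs from bad configs.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("sproutr_input_error", "sproutr_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sproutr_config_error", "sproutr_error")))
}

stop_generation <- function(...) {
  stop(errorCondition(paste0(...), class = c("sproutr_generation_error", "sproutr_error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("sproutr_usage_error", "sproutr_error")))
}
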