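# Classed conditions so the CLI can map failure modes to exit codes
# (usage -> 2, validation -> 3, parse -> 4).

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("chaindisp_usage_error", "chaindisp_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("chaindisp_validation_error", "chaindisp_error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("chaindisp_parse_error", "chaindisp_error")))
}

# numbers that are conceptually integers but may exceed .Machine$integer.max
# (chromosome lengths) are carried as doubles; format without scientific
# notation for file output
fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}
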