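## Classed error conditions so callers (and the study pipeline) can
## distinguish failure modes without string matching.

.gridEMGStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gridEMGError", "error", "condition")))
}

.configError <- function(msg) .gridEMGStop("gridEMG_config_error", msg)
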