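# Shared settings for the analysis workflow. The study protocol is the
# 7-segment isoflurane schedule (1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5 %).
# At full study scale each segment lasts 15 min with a 5-min discard
# and a 60 s depth-transition time constant; the desk-scale run used
# here shortens segments to 3 min and scales discard and transition by
# the same 3/15 factor. Set SEGMENT_MINUTES to 15 to reproduce the
# full-scale geometry.

library(anesdepth)

SEED <- 20260925
N_ANIMALS <- 5
SEGMENT_MINUTES <- 3
DISCARD_MINUTES <- SEGMENT_MINUTES / 3
TAU_S <- 60 * SEGMENT_MINUTES / 15

PROTOCOL <- make_protocol(c(1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5),
                          SEGMENT_MINUTES)
GEN_CONFIG <- generator_config(transition_tau_s = TAU_S)

RESULTS_DIR <- "results"
REC_DIR <- file.path(RESULTS_DIR, "recordings")
dir.create(REC_DIR, recursive = TRUE, showWarnings = FALSE)
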