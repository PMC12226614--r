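# Deterministic seed fan-out: a single global seed plus a stage name yields
# a stable per-stage seed, so adding a stage never perturbs the random
# streams of the others. Arithmetic stays below 2^53, results below 2^31.
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  s <- (h + as.numeric(global_seed)) %% 2147483647
  s <- (s * 48271) %% 2147483647     # Lehmer scramble
  as.integer(s)
}
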