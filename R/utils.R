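# derive a per-stage child seed from one global seed, so stages are
# reproducible both inside the pipeline and when run standalone
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 31) %% .Machine$integer.max)
}
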