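# Seed derivation. Every randomized operation in the package seeds the
# generator with a hash of (user seed, purpose tag) rather than the raw
# seed. Raw seeds chain dangerously: two operations seeded with nearby
# integers (say a generator stream at seed + 1 and a subsample draw at
# seed + 1) would consume identical uniform sequences, silently
# correlating logically independent draws (e.g. a predictor column with
# a subsampling decision). The tag hash keeps each purpose on its own
# reproducible stream.

.stream_seed <- function(seed, tag) {
  x <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    x <- (x * 69069 + ch) %% 2147483647   # exact in double precision
  }
  as.integer(x)
}

.with_stream <- function(seed, tag) {
  set.seed(.stream_seed(seed, tag))
}
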