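# shared small fixtures built in code

tinyModelConfig <- function(dim = 3L)
  modelConfig(dimensionality = dim, channels = c(2L, 3L, 4L, 4L))

ballMask <- function(d, centre, r) {
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  array((co$x - centre[1])^2 + (co$y - centre[2])^2 +
        (co$z - centre[3])^2 <= r^2, d)
}

smallPhantomPair <- function(seed = 1, injury = "sham", ...) {
  generatePhantom(phantomSpec(shape = c(32L, 32L, 16L),
                              spacing = c(0.16, 0.16, 0.16),
                              injury = injury, seed = seed, ...))
}
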