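# Shared tiny fixtures for the unit tests.  Everything is generated in
# code under fixed seeds; sizes are kept small so the whole suite stays
# fast.

# a small architecture for desk-top-speed training in tests
tiny_model <- function(L = 256L)
  model_config(conv_filters = c(4L, 8L, 8L, 8L), conv_kernel = 5L,
               bilstm_units = 8L, input_length = L)

# memoized small labeled beat set (250 Hz keeps beats under 256 samples)
tiny_beats <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_training_beats(n_beats = 24, L = 256L,
                                     sampling_rate = 250, seed = 42)
    cache
  }
})

# hand-built record with P onsets at 100, 600 and 1100 and a QRS inside
# each window (the segmentation-arithmetic fixture)
three_p_record <- function(n = 1600L, fs = 500) {
  sig <- sin(2 * pi * seq_len(n) / 50) * 0.1
  ann <- wave_annotations(
    wave_type = rep(c("P", "QRS"), 3),
    onset  = c(100L, 250L, 600L, 750L, 1100L, 1250L),
    peak   = c(120L, 270L, 620L, 770L, 1120L, 1270L),
    offset = c(150L, 300L, 650L, 800L, 1150L, 1300L))
  labels <- annotations_to_node_labels(ann, n)
  list(record = ecg_record(sig, fs, "threep"), labels = labels,
       annotations = ann)
}
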