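# Small fast fixtures shared across test files; everything is generated in
# code at test time.

tiny_world_config <- function(seed = 1L, ...) {
  world_config(n_subjects = 2, n_locations = 1,
               label_set = c("walk", "run", "sit"),
               seconds_per_activity = 2, sampling_hz = 25,
               channels_per_location = 2, seed = seed, ...)
}

# A small separable 2-class feature world, with train/test split per subject.
separable_tables <- function(seed = 1L, n_per_class = 40, class_sep = 10,
                             n_subjects = 1L, shift = 0) {
  cfg <- world_config(n_subjects = n_subjects, n_locations = 1,
                      label_set = c("a", "b"),
                      subject_shift_scale = shift, seed = seed)
  generate_feature_world(cfg, q = 4, n_per_class = n_per_class,
                         class_sep = class_sep, feature_sd = 1)
}

# A labeled 4-class feature table from one subject, for expert tests.
expert_world <- function(seed = 1L, n_per_class = 40, class_sep = 6, k = 4) {
  cfg <- world_config(n_subjects = 1, n_locations = 1,
                      label_set = paste0("l", seq_len(k)),
                      subject_shift_scale = 0, seed = seed)
  generate_feature_world(cfg, q = 4, n_per_class = n_per_class,
                         class_sep = class_sep, feature_sd = 1)
}

# A constant-label stream for segmentation arithmetic tests.
flat_stream <- function(n, channels = 1L, hz = 50, label = "walk") {
  structure(
    list(subject_id = "s1", location_id = "l1", sampling_hz = hz,
         samples = matrix(seq_len(n * channels) / 10, n, channels,
                          dimnames = list(NULL, paste0("ch", seq_len(channels)))),
         labels = rep(label, n)),
    class = "comeal_stream"
  )
}

# Stub experts with fixed answers, for the EMU tests.
fixed_answer <- function(label) function(x, true_label) label
echo_semi <- function() function(x, true_label) attr(x, "semi")
truth_answer <- function() function(x, true_label) true_label

# A small scenario for driver-level tests.
small_scenario <- function(seed = 1L, scenario = "context_change", ...) {
  build_scenario(scenario,
                 world_config(n_subjects = 3, n_locations = 1,
                              subject_shift_scale = 1.2, seed = seed),
                 q = 4, n_per_class = 40, class_sep = 3.5,
                 n_source_per_class = 15, ...)
}
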