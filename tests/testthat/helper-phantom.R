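# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# fast segmentation settings: narrower cord-center search (the frame is
# already centered on the canal), everything else at defaults
fast_seg_config <- function(...) {
  seg_config(cord_lower = c(0.02, 0.02, -0.1, -0.1),
             cord_upper = c(0.40, 0.40, 0.1, 0.1), ...)
}

# 16-slice noise-free phantom (cervical 2-7, dorsal 8-14), cell-centered
# cord parameters so noise-free recovery can be exact
small_truth <- function(noise_sd = 0, ...) {
  phantom_truth(nslice = 16L, occiput = 2L, c7 = 8L, d12 = 14L,
                cord_a = 0.11, cord_b = 0.07, cord_c = 0.01, cord_d = -0.03,
                noise_sd = noise_sd, ...)
}

small_phantom <- function() {
  cached("small_phantom",
         generate_phantom(small_truth(), shape = c(64, 64, 16),
                          spacing = c(1, 1, 2)))
}

small_segmentation <- function() {
  cached("small_segmentation", {
    ph <- small_phantom()
    segdef <- partition_segments(ph$ct, 2L, 8L, 14L)
    segment_volume_run(ph$ct, segdef, fast_seg_config())
  })
}

# full-size noise-free phantom (64 x 64 x 60, default geometry) and its
# segmentation, for the end-to-end recovery and closure checks
recovery_phantom <- function() {
  cached("recovery_phantom",
         generate_phantom(phantom_truth(noise_sd = 0),
                          shape = c(64, 64, 60), spacing = c(1, 1, 2)))
}

recovery_segmentation <- function() {
  cached("recovery_segmentation", {
    ph <- recovery_phantom()
    segdef <- partition_segments(ph$ct, 3L, 23L, 50L)
    segment_volume_run(ph$ct, segdef, fast_seg_config())
  })
}

# per-slice fit-vs-truth recovery indicator (within one accumulator cell
# in every parameter)
recovery_flags <- function(fits, truth_fits, side = 0.02) {
  m <- merge(fits, truth_fits, by = "slice", suffixes = c("", "_true"))
  eps <- 1e-9
  list(canal = abs(m$canal_a - m$canal_a_true) <= side + eps &
               abs(m$canal_b - m$canal_b_true) <= side + eps,
       cord = abs(m$cord_a - m$cord_a_true) <= side + eps &
              abs(m$cord_b - m$cord_b_true) <= side + eps &
              abs(m$cord_c - m$cord_c_true) <= side + eps &
              abs(m$cord_d - m$cord_d_true) <= side + eps)
}
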