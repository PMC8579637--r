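# Shared fixtures: acquisitions and a small, fast cohort configuration used
# by the pipeline-level tests (coarse voxels keep rendering cheap; the
# statistical structure is unchanged).

acq_dwi <- diffusion_acquisition(c(0, 600))
acq_dki <- diffusion_acquisition(c(0, 500, 1000, 1500, 2000))
acq_ivim <- diffusion_acquisition(c(0, 10, 20, 30, 50, 80, 100, 150, 200, 400, 600, 800))
acq_dce <- dce_acquisition(seq(0, by = 8.1, length.out = 35), n_baseline = 4)

small_config <- function(seed = 7, ...) {
  cohort_config(seed = seed, voxel_mm = 4, fov_mm = 48, n_slices = 6, ...)
}

tiny_config <- function(seed = 5, ...) {
  cohort_config(n_responders = 3, n_nonresponders = 2, seed = seed,
                voxel_mm = 6, fov_mm = 36, n_slices = 4, ...)
}
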