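# Shared fixtures built in code.

# Exact linear loading time course: M(t) = slope * t (mg), three identical
# replicates.
linear_timecourse <- function(slope = 0.1, times = c(1, 2, 3, 4, 6, 8),
                              geometry = filament_geometry(1.0, 0.175)) {
  m <- slope * times
  diffusion_timecourse(times, cbind(m, m, m), geometry = geometry)
}

# Random HSP triple in a realistic range.
random_hsp <- function() hansen(runif(1, 0, 25), runif(1, 0, 25), runif(1, 0, 25))

# Manual Ra evaluation, independent of ra_distance().
ra_by_hand <- function(a, b) {
  sqrt(4 * (a$delta_d - b$delta_d)^2 + (a$delta_p - b$delta_p)^2 +
         (a$delta_h - b$delta_h)^2)
}
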