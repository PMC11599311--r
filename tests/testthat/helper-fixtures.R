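# shared fixtures, memoised so expensive objects are built once per run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# static phantom (no breathing) for simulator/recon statistics
static_phantom <- function() {
  build_phantom(phantom_config(
    waveform = resp_waveform(si_amplitude = 0, ap_amplitude = 0)))
}

# a single-voxel point source at a voxel centre, everything else cold
point_source_phantom <- function() {
  act <- c(body = 0, lung_l = 0, lung_r = 0, liver = 0, spleen = 0,
           stomach = 0, kidney_l = 0, kidney_r = 0, chest_wall = 0,
           abdominal_wall = 0, brain = 0, air = 0)
  build_phantom(phantom_config(
    lesions = list(list(center = c(2, 2, 2), diameter = 4, activity = 1e6)),
    activity = act,
    waveform = resp_waveform(si_amplitude = 0, ap_amplitude = 0)))
}

# short static acquisition shared by listmode/recon/mumap tests
static_listmode_20s <- function() cached("static_lm20", {
  simulate_listmode(static_phantom(), scanner_geometry(),
                    duration_s = 20, mean_rate_cps = 8000, seed = 301)
})

# moving-phantom acquisition shared by signal/gating tests (short but with
# enough cycles for conditioning)
moving_listmode_40s <- function() cached("moving_lm40", {
  simulate_listmode(build_phantom(), scanner_geometry(),
                    duration_s = 40, mean_rate_cps = 8000, seed = 302)
})

default_ct <- function() cached("default_ct", {
  render_ct(build_phantom(), 1)
})

# uniform-value volume helper
uniform_volume <- function(value = 1, dims = c(20, 20, 20), spacing = 4) {
  new_volume(array(value, dims), rep(spacing, 3))
}

# hand-built 3-event list-mode set (valid cylinder geometry, R = 300)
tiny_listmode <- function(duration_s = 1) {
  ev <- tibble::tibble(
    t_ms = c(0L, 10L, 500L),
    d1x = c(-300, 0, 300), d1y = c(0, -300, 0), d1z = c(-50, 0, 20),
    d2x = c(300, 0, -300), d2y = c(0, 300, 0), d2z = c(50, 10, -10),
    tof_offset = c(30, -75, 0))
  header <- list(scanner = scanner_geometry(), duration_s = duration_s,
                 meta = unclass(subject_meta()), n_events = 3L,
                 tof_sign = "positive toward det2")
  urmc:::new_listmode(ev, header)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
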