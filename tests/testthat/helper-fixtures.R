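# Shared, lazily cached phantom fixtures (regenerating the template or a
# subject for every test would dominate the suite's run time).

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

default_spec <- function(...) phantom_spec(seed = 101L, ...)

fixture_template <- function() cached("template", make_template(default_spec()))

fixture_subject <- function() {
  cached("subject", make_subject(default_spec(), fixture_template(), 1L))
}

# noise-free, undeformed, exact-truth subject (perfect-alignment conditions)
clean_spec <- function() {
  phantom_spec(seed = 101L, deformation_amplitude_mm = 0, noise_sd = 0,
               manual_jitter_mm = 0)
}

fixture_clean_subject <- function() {
  cached("clean_subject", make_subject(clean_spec(), fixture_template(), 1L))
}

# small synthetic DSC series built from an explicit gamma-variate dip
toy_dsc <- function(nx = 6, ny = 6, nz = 2, nt = 81, tr = 0.689, s0 = 1000,
                    amp = 0.3, tp = 19, rise = 5, alpha = 3, shift_s = 0) {
  t_acq <- seq_len(nt) * tr
  g <- artroi:::gamma_variate(t_acq - shift_s, tp, rise, alpha)
  arr <- array(rep(s0 * (1 - amp * g), each = nx * ny * nz),
               c(nx, ny, nz, nt))
  dynamic_series(arr, make_grid(c(nx, ny, nz))$affine, tr_seconds = tr)
}

full_mask <- function(dsc) {
  volume_image(array(1, dim(dsc$data)[1:3]), dsc$affine)
}
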