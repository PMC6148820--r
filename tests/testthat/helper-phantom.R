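# Small phantom used by unit tests: fewer phases/slices and a smaller grid
# than the package default so single tests stay fast.
# Note the gentler taper: with only 4 annotated slices the default apical
# taper would shrink cross-sections far faster per step than the real
# acquisition the defaults emulate.
tiny_spec <- function(rv_edv_ml = 80, apical_taper = 0.75, ...) {
  phantom_spec(n_phases = 6L, n_slices = 5L, n_rows = 128L, n_cols = 128L,
               es_phase = 2L, basal_slice = 1L, apical_slice = 4L,
               rv_edv_ml = rv_edv_ml, apical_taper = apical_taper, ...)
}

# cache: several test files reuse the same noise-free tiny phantom
tiny_phantom_cache <- new.env(parent = emptyenv())
tiny_phantom <- function(noise_sd = 0, shift_mm = 0, rng_seed = 1L) {
  key <- paste(noise_sd, shift_mm, rng_seed, sep = "|")
  if (is.null(tiny_phantom_cache[[key]]))
    tiny_phantom_cache[[key]] <- generate_phantom(
      tiny_spec(noise_sd = noise_sd, shift_mm = shift_mm,
                rng_seed = rng_seed))
  tiny_phantom_cache[[key]]
}

# package-default phantom geometry without noise or misalignment
default_phantom <- function() {
  if (is.null(tiny_phantom_cache[["default"]]))
    tiny_phantom_cache[["default"]] <-
      generate_phantom(phantom_spec(noise_sd = 0, shift_mm = 0))
  tiny_phantom_cache[["default"]]
}

square_contour <- function(x0, y0, side, phase = 0L, slice = 0L) {
  contour(cbind(c(x0, x0 + side, x0 + side, x0),
                c(y0, y0, y0 + side, y0 + side)),
          phase, slice)
}
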