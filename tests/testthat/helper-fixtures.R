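# shared fixtures and independent oracles, built in code at test time

# degenerate two-level slab: no lacunae, no noise, no blur, flat interface
flat_slab_spec <- function(shape = c(32, 32, 32), zf = 0.5, seed = 1L) {
  phantom_spec(shape = shape, interface_z_fraction = zf,
               interface_roughness_amp = 0,
               lacunae_density = c(cartilage = 0, mineralized = 0),
               noise_sd = 0, edge_enhancement_amp = 0, psf_sigma = 0,
               seed = seed)
}

textured_spec <- function(shape = c(96, 96, 96), noise_sd = 0,
                          seed = 11L, ...) {
  phantom_spec(shape = shape, noise_sd = noise_sd, seed = seed, ...)
}

# circular integer shift of a 3D array (content wraps; interior unaffected)
circshift3 <- function(v, s) {
  d <- dim(v)
  idx <- lapply(1:3, function(ax) 1L + (seq_len(d[ax]) - 1L - s[ax]) %% d[ax])
  out <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  vol3d(array(out, d), voxel_size = voxel_size(v))
}

# brute-force spatial-domain ZNCC oracle: template t against window w at
# every integer offset; independent of the FFT path it checks
brute_zncc <- function(tmpl, window) {
  s <- dim(tmpl)
  L <- dim(window)
  nf <- L - s + 1L
  t0 <- tmpl - mean(tmpl)
  denT <- sqrt(sum(t0^2))
  out <- array(NA_real_, nf)
  for (k in seq_len(nf[3])) for (j in seq_len(nf[2]))
    for (i in seq_len(nf[1])) {
      sub <- window[i:(i + s[1] - 1L), j:(j + s[2] - 1L),
                    k:(k + s[3] - 1L)]
      s0 <- sub - mean(sub)
      den <- denT * sqrt(sum(s0^2))
      out[i, j, k] <- if (den > 0) sum(t0 * s0) / den else 0
    }
  out
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# analytic uniaxial-compression truth in microstrain
uniaxial_truth <- function(level) c(0, 0, -level * 1e6, 0, 0, 0)
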