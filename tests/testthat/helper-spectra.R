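# shared fixture builders

axis129 <- function() wavelength_axis(420, 2.5, 129) # span L = 320 nm
axis107 <- function() wavelength_axis(420, 3, 107)   # acquisition grid

gauss_spectrum <- function(center, sigma, axis, amplitude = 1) {
  lam <- axis_wavelengths(axis)
  emission_spectrum(amplitude * exp(-(lam - center)^2 / (2 * sigma^2)), axis)
}

delta_spectrum <- function(channel, axis) {
  I <- rep(0, axis$count)
  I[channel] <- 1
  emission_spectrum(I, axis)
}

random_spectrum <- function(axis) {
  emission_spectrum(stats::runif(axis$count), axis)
}

# independent direct-summation first-harmonic oracle: one explicit loop over
# channels, no shared code with compute_phasor
phasor_oracle <- function(s, n = 1, L = axis_span(s$axis)) {
  acc_x <- 0; acc_y <- 0; acc_w <- 0
  for (k in seq_len(s$axis$count)) {
    off <- (k - 1) * s$axis$step
    acc_x <- acc_x + s$intensities[k] * cos(2 * pi * n * off / L)
    acc_y <- acc_y + s$intensities[k] * sin(2 * pi * n * off / L)
    acc_w <- acc_w + s$intensities[k]
  }
  c(X = acc_x / acc_w, Y = acc_y / acc_w)
}

tiny_scene <- function(seed = 1, noise = "none", n_particles = 8,
                       width = 64, height = 64) {
  scene_spec(width = width, height = height, n_particles = n_particles,
             size_range = c(2, 5), noise = noise, seed = seed)
}
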