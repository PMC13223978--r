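# shared fixture builders (all in code; nothing on disk)

sine_channel <- function(freq_hz, rate, duration_s, amplitude = 1,
                         units = "deg/s^2", axis = "test") {
  t <- seq(0, duration_s, by = 1 / rate)
  signal_channel(amplitude * sin(2 * pi * freq_hz * t), rate,
                 units = units, axis = axis)
}

constant_triad <- function(value_z, n = 4000, rate = 2000,
                           placement = "thoracic_T4") {
  ch <- function(v, axis) signal_channel(rep(v, n), rate,
                                         units = "deg/s^2", axis = axis)
  imu_triad(x = ch(0, "x"), y = ch(0, "y"), z = ch(value_z, "z"),
            placement = placement)
}

# amplitude of a sinusoid estimated away from filter edge transients
interior_amplitude <- function(ch, trim = 0.1) {
  n <- length(ch$samples)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  max(abs(ch$samples[i]))
}
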