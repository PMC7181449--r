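# shared fixture builders: all data are generated in code at test time

# a small, fast cohort configuration
small_cfg <- function(..., seed = 101) {
  generator_config(n_participants = 5, n_reps = 5, seed = seed, ...)
}

# all noise sources off: responses are deterministic functions of the design
noise_free_cfg <- function(..., seed = 1) {
  generator_config(weber_fraction = 0, susceptibility_sd = 0,
                   mga_sd_base_mm = 0, mga_sd_slope = 0, seed = seed, ...)
}

# hand-built trajectory data frame (raw, for constructed-fixture tests)
raw_traj <- function(t, x, y_half, z) {
  data.frame(t_s = t,
             thumb_x_cm = x, thumb_y_cm = -y_half, thumb_z_cm = z,
             finger_x_cm = x, finger_y_cm = y_half, finger_z_cm = z)
}

# long-format 2x2 within-subject table from an n x 4 matrix of cell values
# (columns: A1B1, A1B2, A2B1, A2B2)
table_2x2 <- function(cells) {
  n <- nrow(cells)
  data.frame(
    participant = rep(sprintf("S%02d", seq_len(n)), times = 4),
    A = rep(c("a1", "a1", "a2", "a2"), each = n),
    B = rep(c("b1", "b2", "b1", "b2"), each = n),
    y = as.vector(cells)
  )
}
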