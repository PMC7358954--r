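# Shared fixtures: the worked bilateral STN case and small random helpers.

dbs_case <- example_dbs_case()

dbs_landmarks <- landmark_set(dbs_case$landmarks$ac_frame,
                              dbs_case$landmarks$pc_frame,
                              dbs_case$landmarks$falx_frame)

dbs_reg <- build_3pt_transform(dbs_landmarks)

dbs_angles_right <- crw_dials_to_angles(51.8, 20.5, "right")
dbs_angles_left  <- crw_dials_to_angles(51.6, 10.1, "left")

# The five landmark pairs of the worked case, planning targets included.
dbs_pairs_anat <- list(c(12.23, 0, 0), c(-12.23, 0, 0), c(1.98, 0, 51.09),
                       c(-3, 11.5, -3), c(-3, -11.5, -3))
dbs_pairs_frame <- list(c(14.2, 2.9, 2.4), c(-10.1, 2.1, 5.0),
                        c(9.3, 5.9, 54.2), c(-1.8, 13.6, 0.3),
                        c(-0.8, -9.3, 1.7))

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Absolute-tolerance comparison (millimetre scale throughout).
expect_point_equal <- function(p, expected, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(p) - as.numeric(expected))), tol)
}
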