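# hand-built label fields for solver unit tests

# a plain conducting box (torso label) with no heart
make_box_field <- function(n = 5, dx = 0.005) {
  lab <- array(0L, dim = c(n + 2L, n + 2L, n + 2L))
  lab[2:(n + 1), 2:(n + 1), 2:(n + 1)] <- 1L
  structure(list(lab = lab, origin = -(n + 2) / 2 * dx * c(1, 1, 1), dx = dx,
                 labels = label_table(), type = "strip",
                 config = NULL),
            class = "label_field")
}

# a small ventricular block in a one-voxel torso jacket
make_heart_block_field <- function(n = 5, dx = 0.005) {
  m <- n + 4L
  lab <- array(0L, dim = c(m, m, m))
  lab[2:(m - 1), 2:(m - 1), 2:(m - 1)] <- 1L
  lab[3:(n + 2), 3:(n + 2), 3:(n + 2)] <- 10L  # ventricles
  structure(list(lab = lab, origin = -m / 2 * dx * c(1, 1, 1), dx = dx,
                 labels = label_table(), type = "strip",
                 config = NULL),
            class = "label_field")
}

linear_index <- function(field, i, j, k) {
  d <- dim(field$lab)
  i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
}
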