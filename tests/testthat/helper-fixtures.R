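# Small shared fixtures; everything generated in code, no stored data.

default_p <- model_parameters()

# a fixed, deterministic 4-cell row state used by several unit tests
fixed_state4 <- function() {
  row_state(matrix(c(1000, 2000, 3000, 4000,   # N
                     500, 600, 700, 800,       # D
                     900, 1000, 1100, 1200,    # J
                     100, 150, 200, 250,       # I
                     2000, 2500, 3000, 3500,   # VR
                     50, 150, 250, 350),       # V
                   nrow = 4))
}

# rotate a row state / mask by k positions (cell i -> i + k, periodic)
rotate_rows <- function(m, k) {
  M <- nrow(m)
  idx <- ((seq_len(M) - 1 - k) %% M) + 1
  m[idx, , drop = FALSE]
}
rotate_vec <- function(v, k) {
  M <- length(v)
  v[((seq_len(M) - 1 - k) %% M) + 1]
}
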