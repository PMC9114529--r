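# Canonical species order for row states; columns of every state matrix.
.ns_species <- c("N", "D", "J", "I", "VR", "V")

# Default upper bounds of the random initial-condition box (molecules):
# 6000 for free Notch1, Dll4, Jag1 and VEGFR; 600 for NICD and activated
# VEGFR.
.ns_ic_bounds <- c(N = 6000, D = 6000, J = 6000, I = 600, VR = 6000, V = 600)

#' Construct and validate a row state
#'
#' A row state holds, for each of the `M` cells of the periodic row, the six
#' protein quantities of the signaling model: free Notch1 (`N`), free Dll4
#' (`D`), free Jag1 (`J`), NICD (`I`), free VEGFR (`VR`) and activated VEGFR
#' (`V`), all in molecules.
#'
#' @param x A numeric `M x 6` matrix (columns in the order
#'   `N, D, J, I, VR, V`), or anything coercible to one.
#' @return A validated state matrix with class `ns_state`.
#' @export
row_state <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 6L)
    stop("a row state needs 6 species columns (N, D, J, I, VR, V)",
         call. = FALSE)
  if (nrow(x) < 2L)
    stop("a row needs at least M = 2 cells", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("state entries must be finite numbers", call. = FALSE)
  if (any(x < 0))
    stop("state entries must be nonnegative", call. = FALSE)
  colnames(x) <- .ns_species
  class(x) <- c("ns_state", class(x))
  x
}

#' External Notch1/Dll4/Jag1 content seen by one cell
#'
#' The trans-activation terms of the model: each cell sees the average free
#' ligand and receptor content of its two neighbours (periodic row, so cell
#' 1 neighbours cell `M`), plus the substrate ligand content `D_line` /
#' `J_line` if the cell sits on a functionalized line.
#'
#' @param state A row state (see [row_state()]); plain matrices are
#'   accepted.
#' @param layout A [pattern_layout()].
#' @param i Cell index in `1..M`.
#' @return Named numeric vector `c(N_ext, D_ext, J_ext)` in molecules.
#' @examples
#' st <- row_state(matrix(rep(c(10, 20, 30, 0, 0, 0), each = 4), 4, 6))
#' external_terms(st, pattern_layout(4, d_line = 3000), 1)
#' @export
external_terms <- function(state, layout, i) {
  state <- as.matrix(state)
  M <- nrow(state)
  if (layout$M != M)
    stop("layout has M = ", layout$M, " but state has ", M, " cells",
         call. = FALSE)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > M || i != round(i))
    stop("cell index i out of range 1..", M, call. = FALSE)
  left <- if (i == 1) M else i - 1
  right <- if (i == M) 1 else i + 1
  n_ext <- (state[left, "N"] + state[right, "N"]) / 2
  d_ext <- (state[left, "D"] + state[right, "D"]) / 2 +
    if (layout$on_line[i]) layout$d_line else 0
  j_ext <- (state[left, "J"] + state[right, "J"]) / 2 +
    if (layout$on_line[i]) layout$j_line else 0
  c(N_ext = unname(n_ext), D_ext = unname(d_ext), J_ext = unname(j_ext))
}

#' Time derivatives of the full row state
#'
#' Evaluates, synchronously from the current row state, the per-cell ODE
#' right-hand sides of the VEGF-Notch network: shifted-Hill regulated
#' production of Notch1, Dll4, Jag1 and VEGFR; cis-inhibition (`k_C`) and
#' trans-activation (`k_T`) of receptor and ligands scaled by the Fringe
#' factors `H^S(I, lambda_F_D, n_F)` / `H^S(I, lambda_F_J, n_F)`; NICD
#' production from trans-activation; VEGFR activation by external VEGF; and
#' first-order degradation (`gamma` for free species, `gamma_S` for NICD and
#' activated VEGFR).
#'
#' Note the printed asymmetry of the ligand equations: the trans loss of
#' free Dll4/Jag1 to neighbouring receptors is `k_T * N_ext` with no Fringe
#' factor, while the receptor equation carries the Fringe factors on both
#' cis and trans binding.
#'
#' @param state Row state matrix (`M x 6`, columns `N, D, J, I, VR, V`).
#' @param params [model_parameters()].
#' @param layout [pattern_layout()] with `layout$M == nrow(state)`.
#' @return An `M x 6` matrix of derivatives (molecules/hour).
#' @export
row_rhs <- function(state, params, layout) {
  state <- as.matrix(state)
  M <- nrow(state)
  if (layout$M != M)
    stop("layout has M = ", layout$M, " but state has ", M, " cells",
         call. = FALSE)
  p <- params
  N <- state[, 1]; D <- state[, 2]; J <- state[, 3]
  I <- state[, 4]; VR <- state[, 5]; V <- state[, 6]

  idx_l <- c(M, seq_len(M - 1L))   # i - 1 (periodic)
  idx_r <- c(seq_len(M - 1L) + 1L, 1L)  # i + 1 (periodic)
  on <- as.numeric(layout$on_line)
  N_ext <- (N[idx_l] + N[idx_r]) / 2
  D_ext <- (D[idx_l] + D[idx_r]) / 2 + layout$d_line * on
  J_ext <- (J[idx_l] + J[idx_r]) / 2 + layout$j_line * on

  HfD <- shifted_hill(I, p$I0, p$lambda_F_D, p$n_F)
  HfJ <- shifted_hill(I, p$I0, p$lambda_F_J, p$n_F)

  dN <- p$N0 * shifted_hill(I, p$I0, p$lambda_I_N, p$n_N) -
    N * ((p$k_C * D + p$k_T * D_ext) * HfD +
           (p$k_C * J + p$k_T * J_ext) * HfJ) -
    p$gamma * N
  dD <- p$D0 * shifted_hill(I, p$I0, p$lambda_I_D, p$n_D) *
    shifted_hill(V, p$V0, p$lambda_V_D, p$n_D) -
    D * (p$k_C * HfD * N + p$k_T * N_ext) - p$gamma * D
  dJ <- p$J0 * shifted_hill(I, p$I0, p$lambda_I_J, p$n_J) -
    J * (p$k_C * HfJ * N + p$k_T * N_ext) - p$gamma * J
  dI <- p$k_T * N * (D_ext * HfD + J_ext * HfJ) - p$gamma_S * I
  dVR <- p$VR0 * shifted_hill(I, p$I0, p$lambda_I_VR, p$n_VR) -
    p$k_T * VR * p$V_ext - p$gamma * VR
  dV <- p$k_T * VR * p$V_ext - p$gamma_S * V

  out <- cbind(N = dN, D = dD, J = dJ, I = dI, VR = dVR, V = dV)
  rownames(out) <- rownames(state)
  out
}
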