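#' Instar (Oja-type) update of a receptive field
#'
#' One discrete learning step of the feedforward weight column of the
#' winning category cell:
#' `w <- w + eta_in * g_v_k * (g_u - g_v_k * w)`, clamped at zero from
#' below. The forgetting term `g_v_k^2 * w` bounds weight growth; under
#' linear postsynaptic dynamics the rule conserves weight energy
#' (squared norm 1), see [oja_linear()].
#'
#' @param w_col Weight column (length N, non-negative).
#' @param g_u Presynaptic layer-2 activity (length N).
#' @param g_v_k Postsynaptic activation of the winner, in (0, 1).
#' @param eta_in Learning rate (>= 0).
#' @return Updated weight column.
#' @export
update_instar <- function(w_col, g_u, g_v_k, eta_in) {
  if (eta_in < 0) stop("`eta_in` must be non-negative")
  pmax(w_col + eta_in * g_v_k * (g_u - g_v_k * w_col), 0)
}

#' Outstar update of a projective field
#'
#' One discrete learning step of the feedback weight row of the winning
#' category cell: `w <- w + eta_out * g_v_k * (g_u - w)`. For
#' `eta_out * g_v_k <= 1` this is a convex combination of the old weights
#' and the current input, so the row converges to the empirical mean of the
#' layer-2 patterns presented while the cell wins -- the cell's expected
#' input.
#'
#' @inheritParams update_instar
#' @param w_row Weight row (length N, non-negative).
#' @param eta_out Learning rate (>= 0).
#' @return Updated weight row.
#' @export
update_outstar <- function(w_row, g_u, g_v_k, eta_out) {
  if (eta_out < 0) stop("`eta_out` must be non-negative")
  w_row + eta_out * g_v_k * (g_u - w_row)
}

#' Apply winner-gated learning for one sweep
#'
#' Updates the feedforward column and feedback row of the sweep's winner;
#' all other weights are untouched, and the winner's `used` flag is set.
#' The instar learns from the sweep's own layer-2 activity (after a
#' feedback sweep that is the residual-modulated pattern -- the signal that
#' makes variant-specific structure learnable). The outstar tracks the
#' expected *input* of the cell, so it learns from the unmodulated
#' feedforward activity (`g_u_out`): a projective field that chased its own
#' amplified re-representation would absorb the residual it generates and
#' quench the feedback signal.
#'
#' @param state Model state ([model_state()]).
#' @param sweep A sweep result: list with elements `g_u`, `g_v`, `winner`.
#' @param params Model parameters.
#' @param g_u_out Layer-2 activity for the outstar update; defaults to the
#'   sweep's own activity (appropriate for feedforward sweeps).
#' @return List with the updated `state` and a one-row `event` tibble
#'   recording the winner and the norms of both weight changes.
#' @export
apply_learning <- function(state, sweep, params, g_u_out = sweep$g_u) {
  k <- sweep$winner
  gvk <- sweep$g_v[k]
  new_col <- update_instar(state$w_in[, k], sweep$g_u, gvk, params$eta_in)
  new_row <- update_outstar(state$w_out[k, ], g_u_out, gvk, params$eta_out)
  d_in <- sqrt(sum((new_col - state$w_in[, k])^2))
  d_out <- sqrt(sum((new_row - state$w_out[k, ])^2))
  state$w_in[, k] <- new_col
  state$w_out[k, ] <- new_row
  first_use <- !state$used[k]
  state$used[k] <- TRUE
  list(
    state = state,
    event = tibble::tibble(winner = k, gv_winner = gvk,
                           delta_w_in = d_in, delta_w_out = d_out,
                           first_use = first_use)
  )
}

#' Isolated linear Oja dynamics
#'
#' Iterates the instar rule with a linear postsynaptic response
#' `v = <w, u>` under repeated presentation of a fixed input pattern `u`
#' until the update norm falls below `tol`. With balancing constant 1 the
#' squared weight norm converges to 1, the energy-conserving equilibrium of
#' the Oja rule.
#'
#' @param u Fixed input vector (non-zero).
#' @param eta Learning rate.
#' @param w0 Initial weights; default: small positive random values from
#'   the current RNG stream.
#' @param tol Stop when the update norm drops below this.
#' @param max_iter Iteration cap.
#' @return List with final `w`, squared norm `energy`, and `iterations`.
#' @export
oja_linear <- function(u, eta = 0.01, w0 = NULL, tol = 1e-10,
                       max_iter = 1e6) {
  if (all(u == 0)) stop("`u` must be non-zero")
  w <- if (is.null(w0)) stats::runif(length(u), 0.1, 0.5) else w0
  for (it in seq_len(max_iter)) {
    v <- sum(w * u)
    dw <- eta * v * (u - v * w)
    w <- w + dw
    if (sqrt(sum(dw^2)) < tol) break
  }
  list(w = w, energy = sum(w^2), iterations = it)
}
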