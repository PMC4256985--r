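#' Pool (shunting inhibition) specification
#'
#' Describes the inhibitory pool kernel \eqn{\Lambda^{pool}} used by the
#' divisive normalization stage. Three kernel types are supported:
#' \describe{
#'   \item{`"none"`}{no pool inhibition (`q = 0`).}
#'   \item{`"uniform"`}{all-to-all: every unit is inhibited by the summed
#'     (or, with `normalize = TRUE`, averaged) pool activity.}
#'   \item{`"box"`}{local neighborhood on the image grid: each pixel is
#'     inhibited by the mean activity inside a `(2 radius + 1)^2` window
#'     centered on it, optionally mixed with a global (whole-field) term
#'     via `gain_global`.}
#' }
#'
#' @param type Kernel type, one of `"uniform"`, `"box"`, `"none"`.
#' @param gain Non-negative gain of the (local) pool term.
#' @param radius Window radius in pixels (box kernel only).
#' @param normalize If `TRUE` the kernel entries are `gain / pool size`
#'   (averaging); if `FALSE` they are `gain` (summing).
#' @param gain_global Additional whole-field averaged inhibition mixed into
#'   a box kernel (ignored otherwise).
#' @return A list of class `corticat_pool`.
#' @export
pool_spec <- function(type = c("uniform", "box", "none"), gain = 1,
                      radius = NULL, normalize = TRUE, gain_global = 0) {
  type <- match.arg(type)
  stopifnot(is.numeric(gain), length(gain) == 1, gain >= 0, gain_global >= 0)
  if (type == "box" && (is.null(radius) || radius < 1)) {
    stop("box pool requires a positive `radius`")
  }
  structure(list(type = type, gain = gain, radius = radius,
                 normalize = normalize, gain_global = gain_global),
            class = "corticat_pool")
}

#' Model parameters
#'
#' Collects every dynamics and learning constant of the three-layer model.
#' Defaults are the standard training configuration; experiment presets
#' override individual entries (see [preset()]).
#'
#' @param alpha_u,beta_u Passive decay rate and input scaling of layer-2
#'   units.
#' @param alpha_v,beta_v Same for layer-3 category cells.
#' @param kappa_log,mu_log Steepness and midpoint of the layer-3 logistic
#'   transfer function; the defaults place the midpoint at roughly half the
#'   input energy (~1400 active-pixel units) of one clean pictogram.
#' @param lambda Feedback gain scaling the residual template's modulatory
#'   influence on layer 2.
#' @param eta_in,eta_out Learning rates of the instar (feedforward) and
#'   outstar (feedback) rules.
#' @param init_mu,init_sigma Mean / sd of the normal weight initialization
#'   (draws are clamped at 0).
#' @param pool_l2,pool_l3 Pool specifications ([pool_spec()]) for layers 2
#'   and 3.
#' @param fp_tol,fp_max_iter,fp_damping Fixed-point solver controls for the
#'   steady-state divisive normalization.
#' @param height,width Stimulus dimensions (layer-1/2 grid).
#' @return A list of class `corticat_params`.
#' @export
model_params <- function(alpha_u = 1, beta_u = 1.4, alpha_v = 1, beta_v = 1,
                         kappa_log = 0.0075, mu_log = 700,
                         lambda = 2^5, eta_in = 2^-4, eta_out = 2^-4,
                         init_mu = 0.75, init_sigma = 0.1,
                         pool_l2 = pool_spec("box", gain = 1.5, radius = 15,
                                             gain_global = 14),
                         pool_l3 = pool_spec("uniform", gain = 0.05,
                                             normalize = FALSE),
                         fp_tol = 1e-8, fp_max_iter = 500, fp_damping = 0.5,
                         height = 100, width = 100) {
  stopifnot(alpha_u > 0, beta_u > 0, alpha_v > 0, beta_v > 0,
            kappa_log > 0, lambda >= 0, eta_in >= 0, eta_out >= 0,
            fp_tol > 0, fp_max_iter >= 1,
            fp_damping > 0, fp_damping <= 1)
  structure(list(
    alpha_u = alpha_u, beta_u = beta_u, alpha_v = alpha_v, beta_v = beta_v,
    kappa_log = kappa_log, mu_log = mu_log, lambda = lambda,
    eta_in = eta_in, eta_out = eta_out,
    init_mu = init_mu, init_sigma = init_sigma,
    pool_l2 = pool_l2, pool_l3 = pool_l3,
    fp_tol = fp_tol, fp_max_iter = fp_max_iter, fp_damping = fp_damping,
    height = height, width = width
  ), class = "corticat_params")
}

#' Initialize model weights
#'
#' Feedforward weights `w_in` (N x M) and feedback weights `w_out` (M x N)
#' are drawn independently from `Normal(init_mu, init_sigma)` and clamped at
#' zero; `used` flags start all `FALSE`. Draws come from the current RNG
#' stream.
#'
#' @param n_input Number of layer-1/2 units N (pixels).
#' @param n_cells Number of layer-3 category cells M.
#' @param params Model parameters ([model_params()]).
#' @return A list of class `corticat_state` with elements `w_in`, `w_out`,
#'   `used`.
#' @export
model_state <- function(n_input, n_cells, params = model_params()) {
  w_in <- matrix(pmax(stats::rnorm(n_input * n_cells, params$init_mu,
                                   params$init_sigma), 0),
                 nrow = n_input, ncol = n_cells)
  w_out <- matrix(pmax(stats::rnorm(n_cells * n_input, params$init_mu,
                                    params$init_sigma), 0),
                  nrow = n_cells, ncol = n_input)
  structure(list(w_in = w_in, w_out = w_out,
                 used = rep(FALSE, n_cells)),
            class = "corticat_state")
}

#' Linear input filtering
#'
#' Weighted sum of the input activities: `r = sum_j K_j s_j`, the first
#' stage of the columnar processing cascade.
#'
#' @param s Input activity vector.
#' @param k Kernel/weight vector of the same length.
#' @return Scalar response.
#' @export
linear_filter <- function(s, k) {
  if (length(s) != length(k)) {
    stop("`s` and `k` must have equal length (", length(s), " vs ",
         length(k), ")")
  }
  sum(k * s)
}

#' Modulatory feedback combination
#'
#' Second cascade stage: `r_fb = r * (1 + net_fb)`. The feedforward signal
#' gates the feedback -- a zero driving response yields zero output for any
#' feedback strength, while zero feedback leaves the response unchanged.
#'
#' @param r Non-negative driving response(s).
#' @param net_fb Non-negative feedback strength(s).
#' @return Modulated response, vectorized over inputs.
#' @export
modulate <- function(r, net_fb) {
  if (any(r < 0) || any(net_fb < 0)) {
    stop("`r` and `net_fb` must be non-negative")
  }
  r * (1 + net_fb)
}

#' Layer-2 transfer function (rectification)
#'
#' @param u Membrane potential vector.
#' @return `max(u, 0)` elementwise.
#' @export
transfer_u <- function(u) pmax(u, 0)

#' Layer-3 logistic transfer function
#'
#' `g_v(v) = 1 / (1 + exp(kappa_log * (mu_log - v)))`, a monotone sigmoid
#' with values strictly inside (0, 1).
#'
#' @param v Response vector.
#' @param kappa_log Steepness (> 0).
#' @param mu_log Midpoint: `transfer_v(mu_log) == 0.5`.
#' @return Activation vector in (0, 1).
#' @export
transfer_v <- function(v, kappa_log = 0.0075, mu_log = 700) {
  stopifnot(kappa_log > 0)
  stats::plogis(kappa_log * (v - mu_log))
}

# q-field of a pool: inhibition received by each unit given pool input y
pool_field <- function(y, pool, height = NULL, width = NULL) {
  switch(pool$type,
    none = 0,
    uniform = {
      tot <- sum(y)
      if (pool$normalize) tot <- tot / length(y)
      rep(pool$gain * tot, length(y))
    },
    box = {
      m <- matrix(y, height, width)
      local <- box_mean(m, pool$radius)
      q <- pool$gain * local
      if (pool$gain_global > 0) q <- q + pool$gain_global * mean(y)
      as.vector(q)
    }
  )
}

# mean over a (2r+1)^2 clamped window via integral image (edge windows are
# truncated and averaged over their actual size)
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 1, w + 1)
  pad[-1, -1] <- m
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum) # (h+1) x (w+1), transposed
  ii <- t(ii)
  r0 <- pmax(seq_len(h) - r, 1); r1 <- pmin(seq_len(h) + r, h)
  c0 <- pmax(seq_len(w) - r, 1); c1 <- pmin(seq_len(w) + r, w)
  S <- ii[r1 + 1, c1 + 1, drop = FALSE] - ii[r0, c1 + 1, drop = FALSE] -
    ii[r1 + 1, c0, drop = FALSE] + ii[r0, c0, drop = FALSE]
  area <- outer(r1 - r0 + 1, c1 - c0 + 1)
  S / area
}

#' Steady-state divisive pool normalization
#'
#' Solves the fixed point of the shunting-inhibition dynamics
#' \deqn{x_j = \beta raw_j / (\alpha + q_j), \quad
#'       q_j = \sum_k \Lambda_{jk} transfer(x_k)}
#' by damped fixed-point iteration. The solution is non-negative and
#' bounded above by `beta * raw / alpha` elementwise.
#'
#' @param raw Non-negative drive vector.
#' @param alpha,beta Decay rate and input scale.
#' @param pool Pool specification ([pool_spec()]).
#' @param transfer Transfer function applied to activities before they are
#'   pooled (rectification at layer 2, the logistic at layer 3).
#' @param tol Convergence tolerance on the maximum absolute update.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @param damping Step fraction of the fixed-point map in (0, 1].
#' @param height,width Grid dimensions (required for box pools).
#' @return Steady-state activity vector.
#' @export
pool_normalize <- function(raw, alpha, beta, pool, transfer = transfer_u,
                           tol = 1e-8, max_iter = 500, damping = 0.5,
                           height = NULL, width = NULL) {
  if (any(raw < 0)) stop("`raw` must be non-negative")
  x <- beta * raw / alpha
  if (pool$type == "none" || pool$gain + pool$gain_global == 0 ||
      all(raw == 0)) {
    return(x)
  }
  for (it in seq_len(max_iter)) {
    q <- pool_field(transfer(x), pool, height, width)
    x_new <- beta * raw / (alpha + q)
    delta <- max(abs(x_new - x))
    x <- x + damping * (x_new - x)
    if (delta < tol * (1 + max(abs(x)))) return(x)
  }
  stop("pool_normalize did not converge in ", max_iter,
       " iterations (last update ", format(delta), ")")
}

#' Layer-2 steady-state response
#'
#' Computes the normalized layer-2 activity for a stimulus under residual
#' feedback modulation: the drive is `beta_u * s * (1 + lambda * res)`,
#' normalized divisively by the layer-2 pool, then rectified. With
#' `res = 0` (or `lambda = 0`) this is the pure feedforward response; a
#' zero stimulus pixel yields zero output for any feedback.
#'
#' @param s Stimulus vector (length N, values in \[0, 1\]) or matrix.
#' @param res Residual template vector (length N, >= 0) or `NULL` for a
#'   feedforward sweep.
#' @param params Model parameters.
#' @return Activity vector `g_u(u)` of length N.
#' @export
layer2_response <- function(s, res = NULL, params = model_params()) {
  s <- as.vector(s)
  if (is.null(res)) res <- 0 else res <- as.vector(res)
  if (any(res < 0)) stop("`res` must be non-negative")
  drive <- s * (1 + params$lambda * res)
  u <- pool_normalize(drive, params$alpha_u, params$beta_u, params$pool_l2,
                      transfer = transfer_u,
                      tol = params$fp_tol, max_iter = params$fp_max_iter,
                      damping = params$fp_damping,
                      height = params$height, width = params$width)
  transfer_u(u)
}

#' Layer-3 steady-state response
#'
#' Filters layer-2 activity through the feedforward weights, applies
#' divisive pool normalization across the M category cells, and converts
#' the result to activations with the logistic transfer function.
#'
#' @param g_u Layer-2 activity vector (length N).
#' @param w_in Feedforward weight matrix (N x M).
#' @param params Model parameters.
#' @return List with `v_raw` (normalized responses, length M) and `g_v`
#'   (activations in (0, 1)).
#' @export
layer3_response <- function(g_u, w_in, params = model_params()) {
  raw <- as.vector(crossprod(w_in, g_u))
  gv_fun <- function(x) transfer_v(x, params$kappa_log, params$mu_log)
  v <- pool_normalize(pmax(raw, 0), params$alpha_v, params$beta_v,
                      params$pool_l3,
                      transfer = gv_fun,
                      tol = params$fp_tol, max_iter = params$fp_max_iter,
                      damping = params$fp_damping)
  list(v_raw = v, g_v = gv_fun(v))
}

#' Winner-take-all selection
#'
#' Index of the maximally activated category cell; ties are broken in favor
#' of the lowest index.
#'
#' @param g_v Activation vector.
#' @return Single integer index.
#' @export
wta <- function(g_v) {
  if (length(g_v) == 0) stop("`g_v` must be non-empty")
  which.max(g_v)
}

#' Residual feedback template
#'
#' Rectified difference between the current layer-2 activity and the
#' winning cell's projective-field prediction:
#' `res_j = max(g_u_j - w_out_winner_j, 0)`. It vanishes exactly when the
#' input is perfectly predicted.
#'
#' @param g_u Layer-2 activity vector (length N).
#' @param w_out_winner The winner's row of the feedback weight matrix
#'   (length N).
#' @return Non-negative residual vector of length N.
#' @export
residual_template <- function(g_u, w_out_winner) {
  if (length(g_u) != length(w_out_winner)) {
    stop("`g_u` and `w_out_winner` must have equal length")
  }
  if (any(g_u < 0) || any(w_out_winner < 0)) {
    stop("activities and weights must be non-negative")
  }
  pmax(g_u - w_out_winner, 0)
}
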