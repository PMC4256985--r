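#' Training configuration
#'
#' Bundles everything one experiment needs: the stimulus categories and
#' presentation schedule, the number of layer-3 cells, the model constants
#' and the run length. [preset()] returns the four canonical
#' configurations.
#'
#' @param categories Stimulus categories, subset of `c("A", "B")`.
#' @param schedule `"blocked"` or `"random"` presentation order.
#' @param block_size Run length per variant under the blocked schedule.
#' @param n_cells Number of layer-3 category cells M. Should exceed the
#'   number of expected (sub)category representations so at least one cell
#'   stays unused.
#' @param n_steps Number of training steps (one stimulus presentation,
#'   i.e. one feedforward plus one feedback sweep, per step).
#' @param seed Integer seed; all randomness (weight init, ordering, noise)
#'   derives from it.
#' @param sigma Per-presentation clipped Gaussian noise level.
#' @param params Model parameters ([model_params()]).
#' @param snapshot_every Record full weight snapshots every this many steps
#'   (0 = never).
#' @return A list of class `corticat_config`.
#' @export
training_config <- function(categories = "A",
                            schedule = c("random", "blocked"),
                            block_size = 100, n_cells = 6, n_steps = 400,
                            seed = 1, sigma = 0.05,
                            params = model_params(),
                            snapshot_every = 0) {
  schedule <- match.arg(schedule)
  stopifnot(n_cells >= 1, n_steps >= 0)
  structure(list(categories = categories, schedule = schedule,
                 block_size = block_size, n_cells = as.integer(n_cells),
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 sigma = sigma, params = params,
                 snapshot_every = as.integer(snapshot_every)),
            class = "corticat_config")
}

#' Canonical experiment presets
#'
#' Returns the configuration of one of the four training protocols:
#' \describe{
#'   \item{1}{Category B (barred squares), blocked presentation in runs of
#'     100, M = 6 cells, learning rates `2^-5`, logistic midpoint 800,
#'     weight init mean 0.5.}
#'   \item{2}{Category A (faces), random order, M = 6, default parameters.}
#'   \item{3}{As 2 but with feedback disabled (`lambda = 0`).}
#'   \item{4}{Both categories, blocked in runs of 100 with the categories
#'     alternating between blocks, M = 12 cells, 1000 steps, otherwise the
#'     protocol-1 parameters.}
#' }
#'
#' @param experiment_id Integer in 1..4.
#' @param seed Integer seed for the run.
#' @param n_steps Optional override of the default step count.
#' @return A `corticat_config`.
#' @export
preset <- function(experiment_id, seed = 1, n_steps = NULL) {
  if (length(experiment_id) != 1 || !experiment_id %in% 1:4) {
    stop("`experiment_id` must be an integer in 1..4")
  }
  slow <- model_params(eta_in = 2^-5, eta_out = 2^-5, mu_log = 800,
                       init_mu = 0.5, init_sigma = 0.1)
  cfg <- switch(as.character(experiment_id),
    "1" = training_config(categories = "B", schedule = "blocked",
                          n_cells = 6, n_steps = 800, params = slow),
    "2" = training_config(categories = "A", schedule = "random",
                          n_cells = 6, n_steps = 400),
    "3" = {
      p <- model_params()
      p$lambda <- 0
      training_config(categories = "A", schedule = "random",
                      n_cells = 6, n_steps = 400, params = p)
    },
    "4" = training_config(categories = c("A", "B"), schedule = "blocked",
                          n_cells = 12, n_steps = 1000, params = slow)
  )
  cfg$seed <- as.integer(seed)
  if (!is.null(n_steps)) cfg$n_steps <- as.integer(n_steps)
  cfg$experiment <- as.integer(experiment_id)
  cfg
}

# one full sweep: layer 2 (optionally modulated) -> layer 3 -> WTA
sweep_once <- function(s, res, state, params) {
  g_u <- layer2_response(s, res, params)
  l3 <- layer3_response(g_u, state$w_in, params)
  list(g_u = g_u, v_raw = l3$v_raw, g_v = l3$g_v, winner = wta(l3$g_v))
}

#' Run one training step (trial)
#'
#' Executes the per-stimulus trial: feedforward sweep, winner-gated
#' adaptation, residual-template computation from the feedforward winner's
#' projective field, feedback sweep with the modulated input, and a second
#' winner-gated adaptation. Feedforward-sweep adaptation uses the
#' unmodulated layer-2 activity. After the feedback sweep, the instar
#' learns from the residual-modulated activity (which is what makes
#' variant-specific deviations learnable by fresh cells) while the outstar
#' keeps tracking the unmodulated input, the quantity its fixed point
#' represents.
#'
#' @param state Model state.
#' @param s Stimulus vector or matrix (values in \[0, 1\]).
#' @param params Model parameters.
#' @param learn Set `FALSE` to probe without touching the weights.
#' @return List with the updated `state` and a one-row `record` tibble
#'   (winners and peak activations of both sweeps, residual mass, first-use
#'   flags).
#' @export
run_step <- function(state, s, params, learn = TRUE) {
  ff <- sweep_once(s, NULL, state, params)
  ev_ff <- NULL
  if (learn) {
    up <- apply_learning(state, ff, params)
    state <- up$state
    ev_ff <- up$event
  }
  res <- residual_template(ff$g_u, state$w_out[ff$winner, ])
  fb <- sweep_once(s, res, state, params)
  ev_fb <- NULL
  if (learn) {
    # instar sees the modulated activity; outstar tracks the expected input
    up <- apply_learning(state, fb, params, g_u_out = ff$g_u)
    state <- up$state
    ev_fb <- up$event
  }
  record <- tibble::tibble(
    winner_ff = ff$winner, winner_fb = fb$winner,
    gv_ff_max = ff$g_v[ff$winner], gv_fb_max = fb$g_v[fb$winner],
    res_mass = sum(res),
    first_use_ff = if (learn) ev_ff$first_use else FALSE,
    first_use_fb = if (learn) ev_fb$first_use else FALSE,
    gv_ff = list(ff$g_v), gv_fb = list(fb$g_v)
  )
  list(state = state, record = record,
       ff = ff, fb = fb, res = res)
}

#' Run a full training experiment
#'
#' Seeds the generator, initializes weights, builds the presentation
#' stream, and iterates [run_step()] over it, collecting a per-step trace.
#'
#' @param config A `corticat_config` ([training_config()] or [preset()]).
#' @return An object of class `corticat_fit`: list with `state` (final
#'   weights and usage flags), `trace` (tibble with one row per step:
#'   stimulus labels, winners of both sweeps, peak activations, residual
#'   mass, recruitment flags), `stream`, `config`, and optional weight
#'   `snapshots`.
#' @examples
#' \donttest{
#' fit <- run_experiment(preset(3, seed = 1, n_steps = 50))
#' count_recruited(fit)
#' }
#' @export
run_experiment <- function(config) {
  params <- config$params
  set.seed(config$seed)
  set <- stimulus_set(config$categories, params$height, params$width)
  n <- params$height * params$width
  state <- model_state(n, config$n_cells, params)
  if (config$n_steps == 0) {
    return(structure(list(state = state, trace = tibble::tibble(),
                          stream = NULL, config = config,
                          snapshots = list()),
                     class = "corticat_fit"))
  }
  stream <- build_stream(set, schedule = config$schedule,
                         block_size = config$block_size,
                         n_steps = config$n_steps,
                         seed = config$seed, sigma = config$sigma)
  records <- vector("list", config$n_steps)
  snapshots <- list()
  for (i in seq_len(config$n_steps)) {
    s <- stream_stimulus(stream, i)
    out <- tryCatch(run_step(state, s, params),
                    error = function(e) stop("step ", i, ": ",
                                             conditionMessage(e)))
    state <- out$state
    records[[i]] <- dplyr::bind_cols(
      tibble::tibble(step = i, category = stream$category[i],
                     variation = stream$variation[i]),
      out$record
    )
    if (config$snapshot_every > 0 && i %% config$snapshot_every == 0) {
      snapshots[[length(snapshots) + 1]] <-
        list(step = i, w_in = state$w_in, w_out = state$w_out)
    }
  }
  structure(list(state = state, trace = dplyr::bind_rows(records),
                 stream = stream, config = config, snapshots = snapshots),
            class = "corticat_fit")
}

#' Print a concise description of a fit
#'
#' @param x A `corticat_fit`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @method print corticat_fit
#' @export
print.corticat_fit <- function(x, ...) {
  cat("<corticat_fit>\n")
  cat("  cells:", length(x$state$used),
      " steps:", x$config$n_steps,
      " categories:", paste(x$config$categories, collapse = "+"),
      " schedule:", x$config$schedule, "\n")
  cat("  recruited cells:", sum(x$state$used), "\n")
  invisible(x)
}
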