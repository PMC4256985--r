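#' Probe a trained model with the clean stimulus variants
#'
#' Presents every noise-free variant once with learning disabled and
#' records the winners of the feedforward and the feedback sweep. Probing
#' never perturbs the state.
#'
#' @param fit A `corticat_fit` (or a list with `state` and `config`).
#' @param set Optional stimulus set; defaults to the fit's categories.
#' @return Tibble with one row per variant: `category`, `variation`,
#'   `winner_ff`, `winner_fb`, `gv_ff_max`, `gv_fb_max`, `res_mass`.
#' @export
probe_variants <- function(fit, set = NULL) {
  params <- fit$config$params
  if (is.null(set)) {
    set <- stimulus_set(fit$config$categories, params$height, params$width)
  }
  purrr::pmap_dfr(set, function(category, variation, image) {
    out <- run_step(fit$state, image, params, learn = FALSE)
    tibble::tibble(category = category, variation = variation,
                   winner_ff = out$record$winner_ff,
                   winner_fb = out$record$winner_fb,
                   gv_ff_max = out$record$gv_ff_max,
                   gv_fb_max = out$record$gv_fb_max,
                   res_mass = out$record$res_mass)
  })
}

#' Classify layer-3 cells into overall / subcategory / unused roles
#'
#' Roles are derived from winner statistics on clean probes, not from the
#' weights: a cell that wins the feedforward sweep for every variant of a
#' category is that category's overall cell; a cell that wins the feedback
#' sweep for exactly one variant (and is not the overall cell) is that
#' variant's subcategory cell; cells never selected for adaptation during
#' training are unused. Any other pattern is reported as `"ambiguous"`
#' rather than silently resolved. Probing is repeated twice and a
#' subcategory assignment must be identical across both probes.
#'
#' @param fit A `corticat_fit`.
#' @return Tibble with one row per cell: `cell`, `role` (one of
#'   `"overall"`, `"subcategory"`, `"unused"`, `"ambiguous"`), `category`,
#'   `variation` (NA unless a subcategory cell).
#' @export
classify_cells <- function(fit) {
  m <- length(fit$state$used)
  probe1 <- probe_variants(fit)
  probe2 <- probe_variants(fit)
  stable <- identical(probe1[c("winner_ff", "winner_fb")],
                      probe2[c("winner_ff", "winner_fb")])
  roles <- tibble::tibble(cell = seq_len(m),
                          role = NA_character_,
                          category = NA_character_,
                          variation = NA_integer_)
  roles$role[!fit$state$used] <- "unused"
  for (cat in unique(probe1$category)) {
    p <- probe1[probe1$category == cat, ]
    ff <- unique(p$winner_ff)
    overall <- if (length(ff) == 1) ff else NA_integer_
    if (!is.na(overall) && fit$state$used[overall]) {
      roles$role[overall] <- "overall"
      roles$category[overall] <- cat
    }
    for (k in setdiff(unique(p$winner_fb), overall)) {
      vars <- p$variation[p$winner_fb == k]
      if (length(vars) == 1 && stable && fit$state$used[k] &&
          is.na(roles$role[k])) {
        roles$role[k] <- "subcategory"
        roles$category[k] <- cat
        roles$variation[k] <- vars
      }
    }
  }
  roles$role[is.na(roles$role)] <- "ambiguous"
  roles
}

#' Number of recruited cells
#'
#' Counts the distinct layer-3 cells ever selected by the winner-take-all
#' for weight adaptation over a training trace.
#'
#' @param x A `corticat_fit` or a trace tibble with columns `winner_ff`,
#'   `winner_fb`.
#' @return Integer count (0 for an empty trace).
#' @export
count_recruited <- function(x) {
  trace <- if (inherits(x, "corticat_fit")) x$trace else x
  if (is.null(trace) || nrow(trace) == 0) return(0L)
  length(unique(c(trace$winner_ff, trace$winner_fb)))
}

#' Squared Euclidean weight energy
#'
#' @param w Weight vector.
#' @return `sum(w^2)`.
#' @export
weight_energy <- function(w) sum(w^2)

#' One-line summary of a training run
#'
#' @param x A `corticat_fit`.
#' @param ... Unused.
#' @return One-row tibble: steps, number of cells, recruited / unused
#'   counts, role counts from [classify_cells()], and the mean residual
#'   mass over the last 20 steps.
#' @method glance corticat_fit
#' @export
glance.corticat_fit <- function(x, ...) {
  roles <- classify_cells(x)
  tr <- x$trace
  tibble::tibble(
    n_steps = x$config$n_steps,
    n_cells = length(x$state$used),
    n_recruited = count_recruited(x),
    n_unused = sum(roles$role == "unused"),
    n_overall = sum(roles$role == "overall"),
    n_subcategory = sum(roles$role == "subcategory"),
    n_ambiguous = sum(roles$role == "ambiguous"),
    mean_res_mass_tail = if (nrow(tr)) mean(utils::tail(tr$res_mass, 20)) else NA_real_
  )
}

#' Per-step tidy trace of a training run
#'
#' @param x A `corticat_fit`.
#' @param ... Unused.
#' @return The trace tibble without list-columns: one row per step with
#'   stimulus labels, winners of both sweeps, peak activations, residual
#'   mass, and recruitment flags.
#' @method tidy corticat_fit
#' @export
tidy.corticat_fit <- function(x, ...) {
  tr <- x$trace
  if (nrow(tr) == 0) return(tr)
  tr[, setdiff(names(tr), c("gv_ff", "gv_fb"))]
}
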