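#' Write an image to PGM (portable graymap, ASCII)
#'
#' Values in \[0, 1\] are scaled to the requested maximum gray value.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path Output file path.
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line, row-wise like the displayed image
  apply(vals, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read an ASCII PGM image
#'
#' @param path File path of a `P2` graymap.
#' @return Numeric matrix with values scaled back to \[0, 1\].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII (P2) PGM files are supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: expected ", w * h,
                                  " pixels, found ", length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write an image to PNG
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

#' Save a trained model to a directory of plain-text files
#'
#' Weight matrices go to CSV (`w_in.csv`: N x M; `w_out.csv`: M x N),
#' usage flags and configuration to JSON, and the trace (without
#' list-columns) to CSV.
#'
#' @param fit A `corticat_fit`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$state$w_in, file.path(dir, "w_in.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$state$w_out, file.path(dir, "w_out.csv"),
                   row.names = FALSE)
  meta <- list(used = fit$state$used, config = config_to_list(fit$config))
  jsonlite::write_json(meta, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(tidy(fit), file.path(dir, "trace.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a training bit-identically: the
#' configuration (including seed), package version, timestamp and output
#' paths.
#'
#' @param fit A `corticat_fit`.
#' @param dir Directory the run artifacts were written to.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(fit, dir) {
  manifest <- list(
    package = "corticat",
    version = as.character(utils::packageVersion("corticat")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = fit$config$seed,
    config = config_to_list(fit$config),
    outputs = list(dir = dir)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Re-run a training from a saved manifest
#'
#' @param path Path to a `manifest.json` written by [write_manifest()].
#' @return The reproduced `corticat_fit`.
#' @export
run_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- man$config
  pl <- cfg$params
  params <- model_params(
    alpha_u = pl$alpha_u, beta_u = pl$beta_u,
    alpha_v = pl$alpha_v, beta_v = pl$beta_v,
    kappa_log = pl$kappa_log, mu_log = pl$mu_log, lambda = pl$lambda,
    eta_in = pl$eta_in, eta_out = pl$eta_out,
    init_mu = pl$init_mu, init_sigma = pl$init_sigma,
    pool_l2 = do.call(pool_spec, pl$pool_l2[c("type", "gain", "radius",
                                              "normalize", "gain_global")]),
    pool_l3 = do.call(pool_spec, pl$pool_l3[c("type", "gain", "radius",
                                              "normalize", "gain_global")]),
    fp_tol = pl$fp_tol, fp_max_iter = pl$fp_max_iter,
    fp_damping = pl$fp_damping, height = pl$height, width = pl$width
  )
  config <- training_config(
    categories = cfg$categories, schedule = cfg$schedule,
    block_size = cfg$block_size, n_cells = cfg$n_cells,
    n_steps = cfg$n_steps, seed = cfg$seed, sigma = cfg$sigma,
    params = params, snapshot_every = cfg$snapshot_every
  )
  run_experiment(config)
}

#' Read a training configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [training_config()]; the
#' optional `params` block mirrors [model_params()] (pool specs as nested
#' maps with a `type` key).
#'
#' @param path YAML file path.
#' @return A `corticat_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  par_args <- y$params %||% list()
  for (nm in c("pool_l2", "pool_l3")) {
    if (!is.null(par_args[[nm]])) {
      par_args[[nm]] <- do.call(pool_spec, par_args[[nm]])
    }
  }
  params <- do.call(model_params, par_args)
  cfg_args <- y[setdiff(names(y), "params")]
  cfg_args$params <- params
  do.call(training_config, cfg_args)
}

# strip S3 classes so a configuration serializes to plain JSON
config_to_list <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$params <- unclass(cfg$params)
  cfg$params[c("pool_l2", "pool_l3")] <-
    lapply(cfg$params[c("pool_l2", "pool_l3")], unclass)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
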