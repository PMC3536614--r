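#' Read a run configuration file
#'
#' Loads a flat YAML configuration describing a simulation run: any
#' [sorn_params()] field plus the run controls `n_steps`, `snapshot_every`,
#' `record_raster`, `record_deltas`, `ablate`, `init_dist`, `seed`,
#' `output_dir`. Unknown keys are rejected (a typo in a parameter name must
#' not silently fall back to a default). `target_rate` may be an array for
#' per-unit targets.
#'
#' @param path Path to a YAML file.
#' @return A list with `params` (a validated `sorn_params`) and `run` (the
#'   run controls, defaults filled in).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  param_keys <- names(formals(sorn_params))
  run_keys <- c("n_steps", "snapshot_every", "record_raster", "record_deltas",
                "ablate", "init_dist", "output_dir")
  unknown <- setdiff(names(raw), c(param_keys, run_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(sorn_params, raw[intersect(names(raw), param_keys)])
  run <- list(
    n_steps = as.integer(raw$n_steps %||% 10000L),
    snapshot_every = as.integer(raw$snapshot_every %||% 200L),
    record_raster = isTRUE(raw$record_raster %||% TRUE),
    record_deltas = isTRUE(raw$record_deltas %||% FALSE),
    ablate = as.character(raw$ablate %||% character()),
    init_dist = as.character(raw$init_dist %||% "uniform"),
    output_dir = raw$output_dir
  )
  match_ablate(run$ablate)
  list(params = params, run = run)
}

#' Write a run configuration file
#'
#' Inverse of [read_config()]: serializes a `list(params, run)` pair to flat
#' YAML so that reading it back reproduces the configuration exactly.
#'
#' @param config A list with `params` and `run` as returned by
#'   [read_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- unclass(config$params)
  run <- config$run[!vapply(config$run, is.null, TRUE)]
  # precision 17 so doubles survive the text round-trip bit-exactly
  yaml::write_yaml(c(p, run), path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization of `params` plus run controls;
#' embedded in every output manifest so records and analyses can be matched
#' to the configuration that produced them.
#'
#' @param config A `list(params, run)` pair (or a bare `sorn_params`).
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  if (inherits(config, "sorn_params")) config <- list(params = config, run = list())
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  run <- config$run
  if (length(run)) run <- run[order(names(run))]
  jsonlite::write_json(list(params = unclass(config$params), run = run),
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a simulation record to a plain-text directory
#'
#' Serializes a `sorn_record` as a directory of CSV tables plus a JSON
#' manifest: `manifest.json` (parameters, seed, ablations, config hash,
#' package version), `raster_exc.csv` / `raster_inh.csv` (binary rasters,
#' one row per step), `connection_fraction.csv`, `events.csv`
#' (`post,pre,birth_step,death_step,cause`, `NA` death = alive at end),
#' `snapshots.csv` (long format `step,post,pre,w`) and optionally
#' `deltas.csv`. The in-memory checkpoint (state + RNG position) is not
#' persisted.
#'
#' @param record A `sorn_record`.
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir, force = FALSE) {
  if (dir.exists(dir)) {
    if (!force) stop("output directory exists: ", dir,
                     " (use force = TRUE to overwrite)", call. = FALSE)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), na = "NA")
  manifest <- list(
    params = unclass(record$params), seed = record$seed,
    n_steps = record$n_steps, ablate = as.list(record$ablate),
    init_dist = record$init_dist, snapshot_every = record$snapshot_every,
    config_hash = config_hash(record$params),
    has_raster = !is.null(record$raster_exc),
    has_deltas = !is.null(record$deltas),
    meta = record$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(record$raster_exc)) {
    fw(as.data.frame(record$raster_exc), "raster_exc.csv")
    fw(as.data.frame(record$raster_inh), "raster_inh.csv")
  }
  fw(data.frame(step = seq_along(record$connection_fraction) - 1L,
                fraction = record$connection_fraction),
     "connection_fraction.csv")
  fw(record$events, "events.csv")
  snaps <- data.table::rbindlist(lapply(record$snapshots, function(s) {
    data.frame(step = s$step, post = s$pairs$post, pre = s$pairs$pre,
               w = s$pairs$w)
  }))
  fw(snaps, "snapshots.csv")
  if (!is.null(record$deltas)) fw(record$deltas, "deltas.csv")
  invisible(dir)
}

#' Read a simulation record written by [write_record()]
#'
#' @param dir Record directory.
#' @return A `sorn_record` (without the in-memory checkpoint).
#' @export
read_record <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  params <- do.call(sorn_params, man$params)
  fr <- function(f) data.table::fread(file.path(dir, f), data.table = FALSE,
                                      na.strings = c("NA", ""))
  raster_exc <- raster_inh <- NULL
  if (isTRUE(man$has_raster)) {
    raster_exc <- as.matrix(fr("raster_exc.csv"))
    raster_inh <- as.matrix(fr("raster_inh.csv"))
    dimnames(raster_exc) <- dimnames(raster_inh) <- NULL
  }
  snaps_long <- fr("snapshots.csv")
  snaps <- lapply(split(snaps_long, snaps_long$step), function(d) {
    list(step = d$step[1],
         pairs = data.frame(post = d$post, pre = d$pre, w = d$w))
  })
  snaps <- snaps[order(vapply(snaps, `[[`, numeric(1), "step"))]
  names(snaps) <- NULL
  events <- fr("events.csv")
  events$cause <- as.character(events$cause)
  deltas <- if (isTRUE(man$has_deltas)) fr("deltas.csv") else NULL
  structure(list(
    params = params, seed = man$seed, n_steps = man$n_steps,
    ablate = as.character(unlist(man$ablate)), init_dist = man$init_dist,
    snapshot_every = man$snapshot_every,
    raster_exc = raster_exc, raster_inh = raster_inh,
    connection_fraction = fr("connection_fraction.csv")$fraction,
    snapshots = snaps, events = events, deltas = deltas,
    checkpoint = NULL, meta = man$meta
  ), class = "sorn_record")
}

#' Generate a test fixture
#'
#' Small deterministic inputs for estimator-recovery and first-passage
#' checks: `"tiny-net"` (a short record of a 10E/2I network),
#' `"lognormal-sample"` and `"powerlaw-sample"` (synthetic draws with known
#' parameters), and `"random-walk-lifetimes"` (first-passage times of a
#' symmetric unit-step random walk started one step above absorption, whose
#' tail follows the exponent 3/2).
#'
#' @param kind Fixture kind.
#' @param seed RNG seed.
#' @param ... Kind-specific settings: `tiny-net`: `n_steps` (default 200);
#'   `lognormal-sample`: `meanlog` (-3), `sdlog` (1), `n` (1e4);
#'   `powerlaw-sample`: `alpha` (1.5), `xmin` (2), `xmax` (1e6), `n` (1e4);
#'   `random-walk-lifetimes`: `n` (1e4), `max_steps` (250000; walks still
#'   alive there are discarded as censored).
#' @return The fixture: a `sorn_record` for `"tiny-net"`, otherwise a
#'   numeric/integer vector.
#' @export
make_fixture <- function(kind = c("tiny-net", "lognormal-sample",
                                  "powerlaw-sample", "random-walk-lifetimes"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  set.seed(seed)
  switch(kind,
    "tiny-net" = {
      p <- sorn_params(n_exc = 10L, n_inh = 2L, seed = seed)
      sorn_run(p, opts$n_steps %||% 200L, seed = seed, snapshot_every = 50L,
               record_deltas = TRUE)
    },
    "lognormal-sample" = stats::rlnorm(opts$n %||% 10000L,
                                       opts$meanlog %||% -3,
                                       opts$sdlog %||% 1),
    "powerlaw-sample" = rplaw_discrete(opts$n %||% 10000L,
                                       opts$alpha %||% 1.5,
                                       opts$xmin %||% 2L,
                                       opts$xmax %||% 1e6),
    "random-walk-lifetimes" = rw_first_passage(opts$n %||% 10000L,
                                               opts$max_steps %||% 250000L)
  )
}

# discrete power-law sampler via inverse CDF on a truncated support
rplaw_discrete <- function(n, alpha, xmin, xmax) {
  supp <- xmin:xmax
  cdf <- cumsum(supp^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  supp[findInterval(runif(n), cdf) + 1L]
}

# first-passage times to 0 of a +/-1 random walk started at 1;
# walks alive after max_steps are censored and dropped
rw_first_passage <- function(n, max_steps = 250000L) {
  pos <- rep(1L, n)
  res <- rep(NA_integer_, n)
  alive <- seq_len(n)
  t <- 0L
  while (length(alive) && t < max_steps) {
    t <- t + 1L
    pos[alive] <- pos[alive] + ifelse(runif(length(alive)) < 0.5, -1L, 1L)
    dead <- pos[alive] == 0L
    if (any(dead)) {
      res[alive[dead]] <- t
      alive <- alive[!dead]
    }
  }
  res[!is.na(res)]
}
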