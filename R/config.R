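#' Load and validate a run configuration
#'
#' A YAML file with optional sections `salient`, `contour`, `weights`,
#' `de`, `lighting`, `camera`, `range` plus global keys `rng_seed` and
#' `verbosity`. Missing keys take the package defaults; every section is
#' validated through its constructor, so invalid values fail with the
#' offending key named; unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return A named list of validated parameter objects (class
#'   `run_config`).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path) %||% list()
  known <- c("salient", "contour", "weights", "de", "lighting", "camera",
             "range", "rng_seed", "verbosity", "length_scale", "schema")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  build <- function(section, ctor) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) {
      stop("unknown keys in '", section, "': ", paste(bad, collapse = ", "))
    }
    tryCatch(do.call(ctor, args), error = function(e) {
      stop("invalid '", section, "' config: ", conditionMessage(e), call. = FALSE)
    })
  }
  cfg <- list(
    salient = build("salient", salient_params),
    contour = build("contour", contour_params),
    weights = build("weights", cost_weights),
    de = build("de", de_config),
    lighting = build("lighting", lighting_params),
    camera = if (is.null(raw$camera)) {
      camera_intrinsics(fx = 100, width = 200, height = 200)
    } else build("camera", camera_intrinsics),
    range_half = c(raw$range$rot_half %||% 15, raw$range$trans_half %||% 10),
    rng_seed = as.integer(raw$rng_seed %||% 1L),
    length_scale = raw$length_scale %||% 20,
    verbosity = as.integer(raw$verbosity %||% 1L)
  )
  structure(cfg, class = "run_config")
}

#' Save a run configuration back to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  out <- list(
    schema = "lumenreg-config-1",
    salient = unclass(cfg$salient),
    contour = unclass(cfg$contour),
    weights = unclass(cfg$weights),
    de = unclass(cfg$de),
    lighting = unclass(cfg$lighting),
    camera = unclass(cfg$camera),
    range = list(rot_half = cfg$range_half[1], trans_half = cfg$range_half[2]),
    rng_seed = cfg$rng_seed, length_scale = cfg$length_scale,
    verbosity = cfg$verbosity
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

log_msg <- function(verbosity, level, ...) {
  if (verbosity >= level) message("[lumenreg] ", ...)
}

#' Command-line pipeline entry point
#'
#' Subcommands: `simulate` (generate a scene directory), `extract-features`
#' (salient points to CSV), `register` (coarse-to-fine registration to a
#' result JSON), `evaluate` (metrics report CSV from a result and scene).
#' This is the function behind the `inst/cli/lumenreg` script.
#'
#' @param args Character vector, e.g.
#'   `c("simulate", "--out", "scene/", "--seed", "7")`.
#' @return Integer exit status (0 on success, 2 on usage error),
#'   invisibly.
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lumenreg <simulate|extract-features|register|evaluate> [options]",
    "  simulate         --out DIR [--fixture k1|k2] [--seed N] [--n-poses N] [--config C.yaml]",
    "  extract-features --scene DIR --out F.csv [--config C.yaml]",
    "  register         --scene DIR --out R.json [--view N] [--aux-view N]",
    "                   [--init pose.json] [--seed N] [--config C.yaml]",
    "  evaluate         --scene DIR --result R.json --out REPORT.csv",
    sep = "\n"
  )
  if (length(args) == 0 ||
      !args[1] %in% c("simulate", "extract-features", "register", "evaluate")) {
    message(usage)
    return(invisible(2L))
  }
  opt <- parse_cli_opts(args[-1])
  status <- tryCatch({
    switch(args[1],
      "simulate" = cli_simulate(opt),
      "extract-features" = cli_extract(opt),
      "register" = cli_register(opt),
      "evaluate" = cli_evaluate(opt)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      stop("malformed option: ", args[i])
    }
    opt[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  opt
}

cli_config <- function(opt) load_config(opt$config)

cli_simulate <- function(opt) {
  stopifnot(!is.null(opt$out))
  cfg <- cli_config(opt)
  seed <- as.integer(opt$seed %||% cfg$rng_seed)
  spec <- switch(opt$fixture %||% "k2",
                 k1 = scene_spec_k1(), k2 = scene_spec_k2(),
                 stop("unknown fixture: ", opt$fixture))
  scene <- build_scene(spec, n_poses = as.integer(opt$n_poses %||% 5),
                       intr = cfg$camera, light = cfg$lighting, seed = seed)
  save_scene(scene, opt$out)
  log_msg(cfg$verbosity, 1, "scene written to ", opt$out)
}

cli_extract <- function(opt) {
  stopifnot(!is.null(opt$scene), !is.null(opt$out))
  cfg <- cli_config(opt)
  scene <- load_scene(opt$scene)
  F_set <- extract_salient_points(scene$mesh, scene$vp, cfg$salient)
  write.csv(salient_as_tibble(F_set), opt$out, row.names = FALSE)
  log_msg(cfg$verbosity, 1, nrow(F_set$points), " salient points -> ", opt$out)
}

cli_register <- function(opt) {
  stopifnot(!is.null(opt$scene), !is.null(opt$out))
  cfg <- cli_config(opt)
  scene <- load_scene(opt$scene)
  view <- as.integer(opt$view %||% 1L)
  aux <- if (!is.null(opt$aux_view)) as.integer(opt$aux_view)
         else if (cfg$weights$w3 > 0 && length(scene$views) > 1) {
           if (view == 1L) 2L else 1L
         } else NULL
  weights <- cfg$weights
  if (is.null(aux)) weights <- cost_weights(weights$w1, weights$w2, 0)
  de <- cfg$de
  if (!is.null(opt$seed)) de$rng_seed <- as.integer(opt$seed)
  gt <- scene$gt_poses[[view]]
  T0 <- if (!is.null(opt$init)) read_pose(opt$init) else {
    perturb_pose(gt, search_range(gt, cfg$range_half[1], cfg$range_half[2]),
                 seed = de$rng_seed)
  }
  res <- register_views(scene, T0 = T0,
                        range = search_range(T0, cfg$range_half[1], cfg$range_half[2]),
                        cfg = de, weights = weights, view = view,
                        aux_view = aux, sal_params = cfg$salient,
                        con_params = cfg$contour,
                        length_scale = cfg$length_scale)
  out <- list(
    schema = "lumenreg-result-1",
    pose_coarse = as.numeric(t(unclass(res$pose_coarse))),
    pose_fine = as.numeric(t(unclass(res$pose_fine))),
    start_pose = as.numeric(t(unclass(T0))),
    view = view, aux_view = aux,
    evaluations = res$evaluations, converged = res$converged,
    cost_trace = as.list(res$cost_trace),
    config = res$config
  )
  jsonlite::write_json(out, opt$out, auto_unbox = TRUE, digits = NA)
  log_msg(cfg$verbosity, 1, "result -> ", opt$out)
}

cli_evaluate <- function(opt) {
  stopifnot(!is.null(opt$scene), !is.null(opt$result), !is.null(opt$out))
  scene <- load_scene(opt$scene)
  res <- jsonlite::read_json(opt$result, simplifyVector = TRUE)
  as_pose <- function(v) rigid_pose(reproject_rigid(matrix(v, 4, 4, byrow = TRUE)))
  gt <- scene$gt_poses[[res$view]]
  fake_result <- structure(
    list(pose_coarse = as_pose(res$pose_coarse),
         pose_fine = as_pose(res$pose_fine)),
    class = "registration_result"
  )
  ev <- evaluate_registration(fake_result, gt, scene$markers,
                              T0 = as_pose(res$start_pose))
  write.csv(ev, opt$out, row.names = FALSE)
}
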