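#' Default pipeline configuration
#'
#' One nested list governs every stage; section defaults mirror the
#' parameter objects ([retinex_params()], [clahe_params()],
#' [assigner_params()], ...).
#'
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    enhancement = list(
      t_low = 60, t_high = 150,
      mu_init = 0.05, alpha_reg = 0.001, beta_reg = 0.01,
      gamma_pen = 0.1, lambda_pen = 0.1, stages = 3L, omega = 0.5,
      clip_limit = 3.0, grid_rows = 8L, grid_cols = 8L, bins = 256L),
    text = list(bank = NULL, dim = 64L, seed = 0L),
    detector = list(stride = 4L, hidden = 16L, score_thr = 0.25,
                    nms_iou = 0.5, seed = 0L),
    training = list(alpha = 1.0, beta = 6.0, sigma = 0.5, topk = 10L,
                    lambda_mix = 0.5, epochs = 60L, lr = 0.02,
                    box_weight = 2.0, pos_weight = 8.0),
    eval = list(iou_thr = 0.5, classes = c("LU", "AA")),
    thermal = list(target = "RT", k = 2L),
    simulate = list(width = 640L, height = 480L, noise_sd = 0.1,
                    regimes = list(low = 0.33, normal = 0.34, over = 0.33))),
    class = "pipeline_config")
}

check_range <- function(cfg) {
  e <- cfg$enhancement
  if (e$t_low >= e$t_high)
    stop("config error: enhancement.t_low must be < t_high", call. = FALSE)
  if (e$omega <= 0 || e$omega > 1)
    stop("config error: enhancement.omega must lie in (0, 1]", call. = FALSE)
  if (e$clip_limit < 1)
    stop("config error: enhancement.clip_limit must be >= 1", call. = FALSE)
  if (e$grid_rows < 1 || e$grid_cols < 1 || e$bins < 2)
    stop("config error: invalid CLAHE grid/bins", call. = FALSE)
  tr <- cfg$training
  if (tr$lambda_mix < 0 || tr$lambda_mix > 1)
    stop("config error: training.lambda_mix must lie in [0, 1]", call. = FALSE)
  if (tr$alpha <= 0 || tr$beta <= 0 || tr$sigma <= 0 || tr$topk < 1)
    stop("config error: invalid assigner parameters", call. = FALSE)
  if (cfg$text$dim < 8)
    stop("config error: text.dim must be >= 8", call. = FALSE)
  invisible(cfg)
}

merge_config <- function(base, override, prefix = "") {
  for (key in names(override)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base))
      stop("config error: unknown key `", full, "`", call. = FALSE)
    if (is.list(base[[key]]) && !is.null(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], as.list(override[[key]]), full)
    } else if (!is.null(override[[key]])) {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON file, overlays it on [default_config()], rejects
#' unknown keys (naming the offending key) and validates numeric ranges.
#' An empty file yields the defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file, or `NULL` for pure
#'   defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
            else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  check_range(structure(cfg, class = "pipeline_config"))
}

#' Write a configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output `.yml`/`.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
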