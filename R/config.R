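# Run configuration: one flat list of stage parameters, validated against
# the stage preconditions at load time.

#' Default pipeline configuration
#'
#' @return named list of stage parameters: `threshold_mode` ("otsu" or
#'   "fixed"), `fixed_t`, `morph_radius`, `min_area`, `glcm_levels`,
#'   `glcm_distance`, `lsp_similarity_t`, `coarseness_kmax`,
#'   `learning_rate`, `mse_tolerance`, `max_epochs`, `sffs_max_steps`,
#'   `rng_seed`.
#' @export
default_config <- function() {
  list(
    threshold_mode = "otsu",
    fixed_t = NULL,
    morph_radius = 2L,
    min_area = 50L,
    glcm_levels = 16L,
    glcm_distance = 1L,
    lsp_similarity_t = 10,
    coarseness_kmax = 4L,
    learning_rate = 0.01,
    mse_tolerance = 0.01,
    max_epochs = 10000L,
    sffs_max_steps = 30L,
    rng_seed = 1L
  )
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$threshold_mode %in% c("otsu", "fixed"),
      "threshold_mode must be 'otsu' or 'fixed'")
  if (cfg$threshold_mode == "fixed")
    chk(is.numeric(cfg$fixed_t) && cfg$fixed_t >= 0 && cfg$fixed_t <= 255,
        "fixed_t in [0, 255] required when threshold_mode = 'fixed'")
  chk(cfg$morph_radius >= 1, "morph_radius >= 1")
  chk(cfg$min_area >= 1, "min_area >= 1")
  chk(cfg$glcm_levels >= 2, "glcm_levels >= 2")
  chk(cfg$glcm_distance >= 1, "glcm_distance >= 1")
  chk(cfg$lsp_similarity_t >= 0, "lsp_similarity_t >= 0")
  chk(cfg$coarseness_kmax >= 1, "coarseness_kmax >= 1")
  chk(cfg$learning_rate > 0, "learning_rate > 0")
  chk(cfg$mse_tolerance > 0, "mse_tolerance > 0")
  chk(cfg$max_epochs >= 1, "max_epochs >= 1")
  chk(cfg$sffs_max_steps >= 1, "sffs_max_steps >= 1")
  cfg
}

#' Load a YAML run configuration
#'
#' Explicit values override the [default_config()] defaults; unknown keys
#' and invalid values are rejected with a message naming the problem. An
#' empty file yields all defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param echo print the effective configuration.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, echo = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             "; valid keys: ", paste(names(cfg), collapse = ", "))
      cfg[names(user)] <- user
    }
  }
  cfg <- .validate_config(cfg)
  if (echo) {
    for (k in names(cfg))
      message(sprintf("  %s: %s", k,
                      if (is.null(cfg[[k]])) "NULL" else format(cfg[[k]])))
  }
  cfg
}

#' Write the effective configuration beside an output
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}
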