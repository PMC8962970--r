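qd_config_defaults <- function() {
  list(
    # non-local means reference
    nlm_search = 21, nlm_patch = 7, nlm_h = NULL, nlm_h_factor = 20,
    # gray-value compression
    gvc_step_divisor = 10, gvc_k_max = NULL, gvc_curve = NULL,
    # coefficient-of-variation estimation
    cv_P = 8, cv_window = 20, cv_variant = "sd",
    # cosine-distance nonlocal diffusion
    cnlad_search = 9, cnlad_patch = 3, exact_cosine = TRUE,
    dt = 0.2, n_iter = 200, stop_tol = 1.5e-4,
    # type-2 fuzzy gate
    gate_delta_u = 0.2, gate_delta_l = 0.1, gate_k = 2, gate_scale = 1,
    # intensity convention
    value_range = 255
  )
}

#' Pipeline configuration
#'
#' All tunables of the denoising pipeline in one validated list.  Unknown
#' keys are rejected.  `NULL` values mean "derive automatically":
#' `nlm_h` from the coefficient of variation via [nlm_h()], `gvc_k_max`
#' from the calibration curve via [iterations_from_cv()], `gvc_curve`
#' meaning the curve shipped with the package.
#'
#' Defaults: NLM search/patch 21/7 with `nlm_h_factor = 20`; GVC step
#' divisor 10; CV from 8 non-overlapping 20x20 homogeneous windows
#' (standard sd/mean variant); CNLAD search/patch 9/3, standard cosine,
#' `dt = 0.2`, up to `n_iter = 200` explicit steps with early stop when the
#' mean absolute update drops below `stop_tol = 1.5e-4` gray levels; gate
#' standard deviations 0.2/0.1 evaluated on the raw gray scale
#' (`gate_scale = 1`), mean-of-k-middle with `k = 2`.
#'
#' @param ... named overrides of the defaults.
#' @return classed list (`qd_config`).
#' @export
qd_config <- function(...) {
  qd_config_update(structure(qd_config_defaults(), class = "qd_config"), ...)
}

qd_config_update <- function(config, ...) {
  over <- list(...)
  if (length(over) == 0) return(config)
  bad <- setdiff(names(over), names(qd_config_defaults()))
  if (length(bad) || is.null(names(over)) || any(names(over) == ""))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  config[names(over)] <- over
  config
}

#' @export
print.qd_config <- function(x, ...) {
  cat("qdenoise pipeline configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "<auto>" else
                  paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips a [qd_config()] losslessly (the `gvc_curve` entry, if any,
#' is stored inline as its delta/k_max columns).
#'
#' @param config a `qd_config` object.
#' @param path YAML file path.
#' @return `write_config`: the path, invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$gvc_curve)) x$gvc_curve <- as.list(as.data.frame(x$gvc_curve))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  bad <- setdiff(names(x), names(qd_config_defaults()))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(x$gvc_curve)) x$gvc_curve <- as.data.frame(x$gvc_curve)
  cfg <- qd_config_defaults()
  cfg[names(x)] <- x
  structure(cfg, class = "qd_config")
}
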