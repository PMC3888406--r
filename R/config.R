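#' Read / write a run configuration as YAML
#'
#' A run config file has two blocks: `model` (the multipliers and
#' `tau_f_scale` handed to [make_params()]) and `tissue` (arguments of
#' [tissue_config()] except `params`).  Unknown keys raise an error naming
#' them, so a 600-run sweep cannot silently carry a typo.
#'
#' @param path YAML file path.
#' @return `read_run_config`: a validated `tissue_config`;
#'   `write_run_config`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ok_model <- c("mult_CaL", "mult_Ks", "mult_Kr", "mult_NaCa", "tau_f_scale")
  ok_tissue <- setdiff(names(formals(tissue_config)), "params")
  bad <- c(setdiff(names(raw$model), ok_model),
           setdiff(names(raw$tissue), ok_tissue),
           setdiff(names(raw), c("model", "tissue")))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  p <- do.call(make_params, raw$model %||% list())
  args <- raw$tissue %||% list()
  if (!is.null(args$barrier)) args$barrier <- as.list(args$barrier)
  do.call(tissue_config, c(args, list(params = p)))
}

#' @rdname read_run_config
#' @param cfg A `tissue_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tissue_config"))
  model <- cfg$params[c("mult_CaL", "mult_Ks", "mult_Kr", "mult_NaCa",
                        "tau_f_scale")]
  tissue <- cfg[setdiff(names(cfg), "params")]
  tissue <- tissue[!vapply(tissue, is.null, logical(1))]
  yaml::write_yaml(list(model = model, tissue = tissue), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
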