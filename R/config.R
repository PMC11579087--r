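# Config-file ingestion (YAML or JSON) and portable serialization of
# fitted parameters.

#' Read a training configuration file
#'
#' Accepts YAML (if the yaml package is installed) or JSON with keys
#' matching the arguments of [training_config()] plus an optional
#' `branches` block (list of `{inputs, target, hidden}`) defining the
#' network wiring.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return list with elements `config` ([training_config()]) and
#'   `model_spec` ([dcm_network_spec()]).
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_model_config: the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  spec <- if (!is.null(x$branches)) {
    brs <- lapply(seq_len(NROW(x$branches)), function(i) {
      b <- if (is.data.frame(x$branches)) as.list(x$branches[i, ]) else x$branches[[i]]
      branch_spec(unlist(b$inputs), b$target, b$hidden %||% 16L)
    })
    dcm_network_spec(brs)
  } else {
    dcm_network_spec()
  }
  keep <- intersect(names(x), names(formals(training_config)))
  cfg <- do.call(training_config, x[keep])
  list(config = cfg, model_spec = spec)
}

#' Save fitted population parameters
#'
#' Writes the unconstrained parameter vector together with a manifest
#' (layout sizes, error-model kind, network architecture) as JSON, so a
#' fit can be reloaded without R serialization formats.
#'
#' @param fit a `dcm_fit` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_fit_params <- function(fit, path) {
  skel <- fit$skeleton
  lay <- raw_layout(skel)
  raw <- if (nrow(fit$checkpoints) > 0L) {
    inwin <- fit$checkpoint_epochs >
      max(fit$checkpoint_epochs) - fit$config$trailing_window
    colMeans(fit$checkpoints[inwin, seq_len(lay$total), drop = FALSE])
  } else {
    fit$raw_last
  }
  arch <- lapply(skel$theta$branches, function(br) {
    list(inputs = br$spec$inputs, target = br$spec$target, hidden = br$spec$hidden)
  })
  out <- list(objective = fit$objective, raw = raw,
              layout = lay[c("nnet", "K", "nrho", "nsig")],
              residual_kind = skel$residual$kind,
              normalization = as.list(skel$theta$normalization),
              branches = arch, status = fit$status)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load fitted population parameters
#'
#' @param path a JSON file written by [save_fit_params()].
#' @return a [population_parameters()] object.
#' @export
load_fit_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  brs <- lapply(seq_len(NROW(x$branches)), function(i) {
    b <- if (is.data.frame(x$branches)) as.list(x$branches[i, ]) else x$branches[[i]]
    branch_spec(unlist(b$inputs), b$target, b$hidden)
  })
  spec <- dcm_network_spec(brs, normalization = unlist(x$normalization))
  skel <- population_parameters(
    init_network(spec, seed = 1L),
    omega_decomposition(c(0.3, 0.3)),
    residual_model(x$residual_kind, 1, if (x$residual_kind == "combined") 0.1 else 0)
  )
  pop_from_raw(as.numeric(x$raw), skel)
}
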