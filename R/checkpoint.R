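#' Save / load a network checkpoint
#'
#' Weights go to `weights.rds`; a JSON architecture fingerprint (layer list
#' plus parameter count) is written alongside for cross-version
#' verification. Loading checks the fingerprint against the stored
#' configuration.
#'
#' @param network An `mc_unet` (or `mc_unet_fit`, whose best network is saved).
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (save) or an `mc_unet` (load), invisibly for save.
#' @export
save_checkpoint <- function(network, dir) {
  if (inherits(network, "mc_unet_fit")) network <- network$network
  stopifnot(inherits(network, "mc_unet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(network, file.path(dir, "weights.rds"))
  fp <- list(config = unclass(network$config),
             layers = network_spec(network$config),
             parameter_count = network_parameters(network))
  jsonlite::write_json(fp, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  network <- readRDS(file.path(dir, "weights.rds"))
  fp <- jsonlite::read_json(file.path(dir, "architecture.json"))
  if (fp$parameter_count != network_parameters(network))
    stopf("checkpoint fingerprint mismatch: %s parameters recorded, %s loaded",
          fp$parameter_count, network_parameters(network))
  network
}
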