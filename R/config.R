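#' Pipeline run configuration
#'
#' Collects every tunable of the two-detector pipeline with the study's
#' operating values as defaults: confidence threshold `t_conf = 0.9`,
#' within-detector NMS threshold `t_iou1 = 0.15` (strict, because finger
#' joint boxes barely overlap), cross-detector merge threshold
#' `t_iou2 = 0.45`, detection-success IoU `iou_success = 0.45`, per-detector
#' caps `m1 = 20` (ankylosis, all PIP/IP + MP joints) and `m2 = 18`
#' (subluxation, thumb IPs excluded), scan window 300 px with stride 150 on
#' the half-resolution image (`resize_factor = 0.5`), and the training
#' hyper-parameters (200 epochs, batch 16, Adam with alpha 0.001,
#' beta1 0.9, beta2 0.999, weight decay 0.0005).
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    t_conf = 0.9, t_iou1 = 0.15, t_iou2 = 0.45, iou_success = 0.45,
    m1 = 20L, m2 = 18L,
    window = 300L, stride = 150L, resize_factor = 0.5,
    epochs = 200L, batch_size = 16L,
    lr = 0.001, beta1 = 0.9, beta2 = 0.999, weight_decay = 0.0005,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' @param path File path.
#' @param cfg A `run_config`.
#' @return `read_config()` returns a validated `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  rlang::exec(run_config, !!!vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
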