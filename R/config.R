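#' Analysis run configuration
#'
#' Bundles the tunable parameters of the pipeline so a run can be resolved,
#' recorded alongside its outputs and replayed. All distance bounds are in
#' bp, the proximity cutoff in nm.
#'
#' @param bin_size bin width, bp.
#' @param min_sep,max_sep anchor-pair separation bounds, bp.
#' @param cutoff_nm proximity cutoff for trace analysis, nm.
#' @param apa_window APA half-window, bins.
#' @param is_window insulation-score window, bins.
#' @param n_rand number of distance-preserving network randomizations.
#' @param boot_iters bootstrap iterations for anchor aggregates.
#' @param seed integer seed recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(bin_size = 5000, min_sep = 20e3, max_sep = 2e6,
                       cutoff_nm = 200, apa_window = 10, is_window = 8,
                       n_rand = 1000, boot_iters = 10000, seed = 1) {
  cfg <- list(bin_size = bin_size, min_sep = min_sep, max_sep = max_sep,
              cutoff_nm = cutoff_nm, apa_window = apa_window,
              is_window = is_window, n_rand = n_rand,
              boot_iters = boot_iters, seed = seed)
  if (any(vapply(cfg, length, 0L) != 1L)) stop("all config entries are scalars")
  num <- vapply(cfg, as.numeric, 0)
  if (any(num[c("bin_size", "min_sep", "max_sep", "cutoff_nm", "apa_window",
                "is_window", "n_rand", "boot_iters")] <= 0))
    stop("all bounds and sizes must be positive")
  if (cfg$min_sep >= cfg$max_sep) stop("min_sep must be < max_sep")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return [read_run_config] returns a `run_config`; [write_run_config]
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' @param cfg a `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
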