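# Map and stack I/O (NIfTI + JSON sidecars) and the command-line entry
# point binding the modules into reproducible runs.

#' Write a parameter map as float32 NIfTI with a JSON sidecar
#'
#' @param map A [parameter_map()].
#' @param path Output `.nii` / `.nii.gz` path; the sidecar is written next
#'   to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  vals <- map$values
  vals[!map$mask] <- NA_real_
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "float"), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = map$units, meta = map$meta),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter map written by [write_map_nifti()]
#' @param path NIfTI file path.
#' @return A [parameter_map()]; pixels stored as NA are masked out.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  units <- "dimensionless"; meta <- list()
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    units <- sc$units %||% units
    meta <- as.list(sc$meta)
  }
  parameter_map(vals, units, mask = !is.na(vals), meta = meta)
}

#' Write an image stack as NIfTI plus a JSON sidecar
#'
#' The sidecar records the acquisition type, TI / preparation times,
#' protocol fields, SNR and seed so the stack can be refitted without the
#' generating session.
#'
#' @param stack An [acquire()] result.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  RNifti::writeNifti(RNifti::asNifti(stack$data, datatype = "float"), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  prot <- unclass(stack$protocol)
  jsonlite::write_json(
    list(type = stack$type, times = stack$times, protocol = prot,
         protocol_class = class(stack$protocol)[1],
         snr = if (is.finite(stack$snr)) stack$snr else "Inf",
         seed = stack$seed, magnitude = stack$magnitude, eta = stack$eta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack_nifti()]
#' @param path NIfTI file path.
#' @return An `image_stack`.
#' @export
read_stack_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  prot <- sc$protocol
  protocol <- do.call(sc$protocol_class, prot)
  data <- array(as.numeric(img), dim = dim(img))
  structure(list(data = data, times = as.numeric(sc$times), type = sc$type,
                 protocol = protocol,
                 snr = if (identical(sc$snr, "Inf")) Inf else sc$snr,
                 seed = sc$seed, magnitude = isTRUE(sc$magnitude),
                 eta = sc$eta),
            class = "image_stack")
}

provenance_record <- function(command, opts, seed) {
  list(command = command, options = opts, seed = seed,
       package = "mollifit",
       version = as.character(utils::packageVersion("mollifit")),
       r_version = R.version.string)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `phantom`, `simulate`, `fit`, `eta`, `mc` and
#' `deviation`; see `inst/cli/molli` for the executable wrapper. Every run
#' writes a `provenance.json` (command, options, seed, versions) next to
#' its outputs.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Exit status (0 on success), invisibly.
#' @export
molli_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    cat("usage: molli <phantom|simulate|fit|eta|mc|deviation> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
           phantom = cli_phantom(rest),
           simulate = cli_simulate(rest),
           fit = cli_fit(rest),
           eta = cli_eta(rest),
           mc = cli_mc(rest),
           deviation = cli_deviation(rest),
           { cat("unknown command:", cmd, "\n"); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_common_opts <- function(extra = list()) {
  c(list(
    optparse::make_option("--out", type = "character", default = ".",
                          help = "output directory"),
    optparse::make_option("--seed", type = "integer", default = 1),
    optparse::make_option("--protocol", type = "character", default = NULL,
                          help = "protocol JSON/YAML (default: standard 3-3-5)")),
    extra)
}

cli_load_protocol <- function(opts, alpha = 35) {
  if (!is.null(opts$protocol)) read_protocol(opts$protocol)
  else molli_protocol(alpha_nominal = alpha)
}

finish_run <- function(outdir, cmd, opts) {
  jsonlite::write_json(provenance_record(cmd, opts, opts$seed),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  0L
}

cli_phantom <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--grid", type = "integer", default = 64),
      optparse::make_option("--snr", type = "double", default = Inf),
      optparse::make_option("--b1-profile", type = "character",
                            default = "uniform", dest = "b1_profile")))),
    args = args)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  ph <- make_tube_phantom(grid = opts$grid, b1_profile = opts$b1_profile,
                          seed = opts$seed)
  prot <- cli_load_protocol(opts)
  st <- acquire(ph, prot, snr = opts$snr, seed = opts$seed)
  write_stack_nifti(st, file.path(opts$out, "molli_stack.nii"))
  write_map_nifti(parameter_map(ph$t1, "ms", ph$labels > 0),
                  file.path(opts$out, "t1_true.nii"))
  write_map_nifti(parameter_map(ph$t2, "ms", ph$labels > 0),
                  file.path(opts$out, "t2_true.nii"))
  write_map_nifti(parameter_map(35 * ph$b1_scale, "degrees", ph$labels > 0),
                  file.path(opts$out, "alpha_true.nii"))
  finish_run(opts$out, "phantom", opts)
}

cli_simulate <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--t1", type = "double", default = 1180),
      optparse::make_option("--t2", type = "double", default = 45),
      optparse::make_option("--alpha", type = "double", default = NULL),
      optparse::make_option("--eta", type = "double", default = 0.92)))),
    args = args)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  prot <- cli_load_protocol(opts)
  alpha <- opts$alpha %||% prot$alpha_nominal
  curve <- simulate_molli(tissue_params(opts$t1, opts$t2), prot,
                          eta = opts$eta, alpha_actual = alpha)
  utils::write.csv(data.frame(ti = curve$ti, signal = curve$signal),
                   file.path(opts$out, "recovery_curve.csv"),
                   row.names = FALSE)
  finish_run(opts$out, "simulate", opts)
}

cli_fit <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--stack", type = "character"),
      optparse::make_option("--method", type = "character", default = "both"),
      optparse::make_option("--t2-map", type = "character", default = NULL,
                            dest = "t2_map"),
      optparse::make_option("--alpha-map", type = "character", default = NULL,
                            dest = "alpha_map"),
      optparse::make_option("--eta", type = "double", default = 0.92)))),
    args = args)
  if (is.null(opts$stack)) stop("--stack is required")
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  st <- read_stack_nifti(opts$stack)
  t2m <- if (!is.null(opts$t2_map)) read_map_nifti(opts$t2_map)$values
  alm <- if (!is.null(opts$alpha_map)) read_map_nifti(opts$alpha_map)$values
  maps <- fit_t1_stack(st, method = opts$method, t2_map = t2m,
                       alpha_map = alm, eta = opts$eta)
  if (!is.null(maps$standard))
    write_map_nifti(maps$standard, file.path(opts$out, "t1_standard.nii"))
  if (!is.null(maps$fit_sim))
    write_map_nifti(maps$fit_sim, file.path(opts$out, "t1_fitsim.nii"))
  summ <- lapply(maps, function(m)
    list(mean = pm_mean(m), sd = pm_sd(m), n = sum(m$mask)))
  jsonlite::write_json(summ, file.path(opts$out, "t1_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  finish_run(opts$out, "fit", opts)
}

cli_eta <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--t1", type = "double", default = 1180),
      optparse::make_option("--t2", type = "double", default = 45),
      optparse::make_option("--b0", type = "double", default = 0),
      optparse::make_option("--b1-scale", type = "double", default = 1,
                            dest = "b1_scale")))),
    args = args)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  eta <- simulate_inversion(hs_pulse(), tissue_params(opts$t1, opts$t2),
                            b0_offset = opts$b0, b1_scale = opts$b1_scale)
  jsonlite::write_json(list(eta = as.numeric(eta)),
                       file.path(opts$out, "eta.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("eta = %.4f\n", as.numeric(eta)))
  finish_run(opts$out, "eta", opts)
}

cli_mc <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--n", type = "integer", default = 2000),
      optparse::make_option("--snr", type = "double", default = 50)))),
    args = args)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  res <- run_mc(mc_config(n_samples = opts$n, snr = opts$snr,
                          seed = opts$seed))
  utils::write.csv(res$bins, file.path(opts$out, "mc_bins.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(max_cov_fitsim = max(res$bins$cov[res$bins$method == "fit-sim"],
                              na.rm = TRUE),
         max_abs_bias_fitsim = max(abs(
           res$bins$rel_bias[res$bins$method == "fit-sim"]), na.rm = TRUE)),
    file.path(opts$out, "mc_summary.json"), auto_unbox = TRUE, digits = NA)
  finish_run(opts$out, "mc", opts)
}

cli_deviation <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    option_list = cli_common_opts(list(
      optparse::make_option("--dataset", type = "integer", default = 1)))),
    args = args)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  tab <- generate_deviation_curves(dataset = opts$dataset,
                                   protocol = cli_load_protocol(opts))
  utils::write.csv(tab, file.path(opts$out,
                                  sprintf("deviation_dataset%d.csv",
                                          opts$dataset)),
                   row.names = FALSE)
  finish_run(opts$out, "deviation", opts)
}
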