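# NIfTI and tabular I/O, run manifests, and the command-line entry point.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return List with `data` (3D/4D array), `affine` (4 x 4), and
#'   `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(paste("unreadable NIfTI:", path,
                                                  "-", conditionMessage(e))))
  aff <- RNifti::xform(img)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  list(data = as.array(img), affine = unclass(aff),
       voxel_size = as.numeric(pd)[1:3])
}

#' Write one NIfTI map
#' @param data 3D/4D array.
#' @param path Output path.
#' @param reference Optional NIfTI image/list to copy spatial metadata from.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, reference = NULL) {
  img <- RNifti::asNifti(data, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write fitted parameter maps
#'
#' One NIfTI per parameter (`f`, `Dn`, `De`, `rn`, `tex`, `p2`, `loss`),
#' `NaN` outside the mask, plus a JSON run manifest.  `tex` is computed as
#' `(1 - f)/rn` with `rn` floored at 1e-6 / ms; floored voxels are listed
#' in the manifest.
#'
#' @param fit A `nexi_fit` object.
#' @param mask Logical 3D array locating the fitted voxels (in `which()`
#'   order).
#' @param out_dir Output directory (created if needed).
#' @param reference Optional NIfTI reference for spatial metadata.
#' @param manifest Extra fields merged into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_maps <- function(fit, mask, out_dir, reference = NULL,
                       manifest = list()) {
  stopifnot(inherits(fit, "nexi_fit"))
  mask <- array(as.logical(mask), dim(mask))
  vox <- which(mask)
  est <- fit$estimates
  if (length(vox) != nrow(est))
    abort("mask voxel count does not match fitted voxels")
  pars <- c("f", "Dn", "De", "rn", "tex", "p2", "loss")
  files <- character(0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pars) {
    if (!p %in% names(est) || all(is.na(est[[p]]))) next
    vol <- array(NaN, dim(mask))
    vol[vox] <- est[[p]]
    f <- file.path(out_dir, paste0(p, ".nii.gz"))
    write_volume(vol, f, reference)
    files <- c(files, f)
  }
  floored <- which(est$rn < 1e-6)
  man <- modifyList(list(
    package = "nexifit", version = as.character(packageVersion("nexifit")),
    solver = fit$solver, lmax = fit$options$lmax, loss = fit$options$loss,
    lambda = fit$options$lambda, rician_mean = fit$options$rician_mean,
    seed = fit$options$seed, n_voxels = nrow(est),
    iterations = fit$iterations, converged = isTRUE(fit$converged),
    rn_floored_voxels = as.integer(floored),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    maps = basename(files)), manifest)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, mf))
}

cli_usage <- function() {
  cat("usage: nexifit <command> [options]\n",
      "commands:\n",
      "  fit        --dwi DWI.nii --mask MASK.nii (--protocol C2 |\n",
      "             --bval F --bvec F --timing F) [--solver nlls|adam]\n",
      "             [--lmax 0|2] [--loss l1|l2|mse] [--lambda X]\n",
      "             [--rician-mean] [--sigma X|SIGMA.nii] [--seed N]\n",
      "             [--exclude-b 1] --out-dir DIR\n",
      "  invariants --dwi DWI.nii --mask MASK.nii (--protocol P | --bval ...)\n",
      "             [--roi LABELS.nii] --out-dir DIR\n",
      "  simulate   --protocol C1|C2 [--generator nexi|smex] [--delta X]\n",
      "             [--noise gaussian|rician|rician-mean] [--snr 50] [--n N]\n",
      "             [--lmax 0|2] [--seed N] --out-dir DIR\n",
      "  phantom    [--snr 50] [--protocol C2] [--n-labels 20] [--seed N]\n",
      "             --out-dir DIR\n",
      "  evaluate   --estimates DIR --truth TRUTH.tsv --labels LAB.nii\n",
      "             --out-dir DIR\n", sep = "")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) abort(paste("unexpected argument:", a))
    key <- substring(a, 3)
    if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
      flags[[key]] <- argv[i + 1]
      i <- i + 2
    } else {
      flags[[key]] <- TRUE
      i <- i + 1
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

cli_load_scheme <- function(flags) {
  if (!is.null(flags[["protocol"]])) {
    nexi_protocol(flags[["protocol"]],
                  as.integer(flag_num(flags, "directions", 64)))
  } else if (!is.null(flags[["bval"]])) {
    read_scheme(flags[["bval"]], flags[["bvec"]], flags[["timing"]])
  } else abort("either --protocol or --bval/--bvec/--timing is required")
}

cli_fit <- function(flags) {
  for (req in c("dwi", "mask", "out-dir"))
    if (is.null(flags[[req]])) abort(paste0("--", req, " is required"))
  rician <- isTRUE(flags[["rician-mean"]]) || identical(flags[["rician-mean"]], "true")
  if (rician && is.null(flags[["sigma"]]))
    abort("--rician-mean requires --sigma")
  scheme <- cli_load_scheme(flags)
  dwi <- read_volume(flags[["dwi"]])
  maskv <- read_volume(flags[["mask"]])
  mask <- maskv$data > 0
  opts <- fit_options(lmax = as.integer(flag_num(flags, "lmax", 0)),
                      loss = flags[["loss"]] %||% "l1",
                      solver = flags[["solver"]] %||% "nlls",
                      lambda = flag_num(flags, "lambda", 0),
                      rician_mean = rician,
                      exclude_b = flag_num(flags, "exclude-b", 1),
                      seed = as.integer(flag_num(flags, "seed", 1)))
  vox <- which(mask)
  dmat <- matrix(dwi$data, ncol = dim(dwi$data)[4])[vox, , drop = FALSE]
  norm <- normalize_b0(dmat, scheme)
  inv <- extract_invariants(norm$signals, norm$scheme,
                            lmax_fit = max(2, opts$lmax))
  sigma <- NULL
  if (!is.null(flags[["sigma"]])) {
    sg <- suppressWarnings(as.numeric(flags[["sigma"]]))
    sigma <- if (is.na(sg)) read_volume(flags[["sigma"]])$data[vox] else sg
  }
  fit <- if (opts$solver == "adam") {
    fit_adam(inv, scheme, opts, sigma = sigma, mask = mask,
             voxel_size = dwi$voxel_size[1:2])
  } else {
    fit_nlls(inv, scheme, opts, sigma = sigma)
  }
  write_maps(fit, mask, flags[["out-dir"]],
             manifest = list(command = "fit",
                             inputs = list(dwi = flags[["dwi"]],
                                           mask = flags[["mask"]])))
  invisible(0L)
}

cli_invariants <- function(flags) {
  for (req in c("dwi", "mask", "out-dir"))
    if (is.null(flags[[req]])) abort(paste0("--", req, " is required"))
  scheme <- cli_load_scheme(flags)
  dwi <- read_volume(flags[["dwi"]])
  mask <- read_volume(flags[["mask"]])$data > 0
  vox <- which(mask)
  dmat <- matrix(dwi$data, ncol = dim(dwi$data)[4])[vox, , drop = FALSE]
  norm <- normalize_b0(dmat, scheme)
  inv <- extract_invariants(norm$signals, norm$scheme)
  out_dir <- flags[["out-dir"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(flags[["roi"]])) {
    labs <- read_volume(flags[["roi"]])$data[vox]
    tab <- roi_average_invariants(inv, labs)
    write.table(as.data.frame(tab), file.path(out_dir, "roi_invariants.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    shells <- distinct(inv, .data$b, .data$t, .data$l) %>%
      arrange(.data$t, .data$b, .data$l)
    vols <- array(NaN, c(dim(mask), nrow(shells)))
    for (i in seq_len(nrow(shells))) {
      sub <- filter(inv, .data$b == shells$b[i], .data$t == shells$t[i],
                    .data$l == shells$l[i])
      v <- array(NaN, dim(mask)); v[vox] <- sub$value
      vols[, , , i] <- v
    }
    write_volume(vols, file.path(out_dir, "invariants.nii.gz"))
    write.table(as.data.frame(shells), file.path(out_dir, "invariants.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(0L)
}

cli_simulate <- function(flags) {
  if (is.null(flags[["out-dir"]])) abort("--out-dir is required")
  res <- run_noise_propagation(
    protocol = flags[["protocol"]] %||% "C2",
    generator = flags[["generator"]] %||% "nexi",
    delta = if (is.null(flags[["delta"]])) NULL else as.numeric(flags[["delta"]]),
    noise = flags[["noise"]] %||% "gaussian",
    snr = flag_num(flags, "snr", 50),
    n = as.integer(flag_num(flags, "n", 1000)),
    lmax = as.integer(flag_num(flags, "lmax", 0)),
    directions = as.integer(flag_num(flags, "directions", 64)),
    solver = flags[["solver"]] %||% "nlls",
    seed = as.integer(flag_num(flags, "seed", 1)))
  write_propagation(res, flags[["out-dir"]])
  invisible(0L)
}

cli_phantom <- function(flags) {
  if (is.null(flags[["out-dir"]])) abort("--out-dir is required")
  spec <- phantom_spec(snr = flag_num(flags, "snr", 50),
                       protocol = flags[["protocol"]] %||% "C2",
                       n_labels = as.integer(flag_num(flags, "n-labels", 20)),
                       seed = as.integer(flag_num(flags, "seed", 1)))
  ph <- make_phantom(spec)
  out <- flags[["out-dir"]]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$dwi, file.path(out, "dwi.nii.gz"))
  write_volume(ph$labels + 0, file.path(out, "labels.nii.gz"))
  write_volume(ph$mask + 0, file.path(out, "mask.nii.gz"))
  write_scheme(ph$scheme, file.path(out, "scheme.tsv"))
  write.table(as.data.frame(ph$truth), file.path(out, "truth.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(command = "phantom", snr = spec$snr,
                            protocol = spec$protocol, seed = spec$seed,
                            n_labels = spec$n_labels),
                       file.path(out, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(0L)
}

cli_evaluate <- function(flags) {
  for (req in c("estimates", "truth", "labels", "out-dir"))
    if (is.null(flags[[req]])) abort(paste0("--", req, " is required"))
  labs_img <- read_volume(flags[["labels"]])$data
  truth <- read.table(flags[["truth"]], header = TRUE, sep = "\t")
  pars <- intersect(c("f", "Dn", "De", "rn", "tex", "p2"), names(truth))
  est <- list()
  mask <- labs_img > 0
  for (p in pars) {
    f <- file.path(flags[["estimates"]], paste0(p, ".nii.gz"))
    if (file.exists(f)) est[[p]] <- read_volume(f)$data[mask]
  }
  tab <- evaluate_maps(as.data.frame(est), truth, labs_img[mask])
  dir.create(flags[["out-dir"]], recursive = TRUE, showWarnings = FALSE)
  write.table(as.data.frame(tab), file.path(flags[["out-dir"]], "evaluation.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(0L)
}

#' Command-line entry point
#'
#' Dispatches the `fit`, `invariants`, `simulate`, `phantom` and `evaluate`
#' subcommands.  Returns (rather than calls `quit()` with) the exit status:
#' 0 on success, 1 on runtime error, 2 on usage error, so it can be driven
#' from a wrapper script or tested in-process.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status.
#' @export
nexi_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { cli_usage(); return(2L) }
  cmd <- argv[1]
  handler <- switch(cmd, fit = cli_fit, invariants = cli_invariants,
                    simulate = cli_simulate, phantom = cli_phantom,
                    evaluate = cli_evaluate, NULL)
  if (is.null(handler)) {
    message("unknown command: ", cmd)
    cli_usage()
    return(2L)
  }
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) { message(conditionMessage(flags)); return(2L) }
  status <- tryCatch({ handler(flags); 0L }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("require|unknown|unexpected", conditionMessage(e))) 2L else 1L
  })
  status
}
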