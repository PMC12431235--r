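#' Read / write an AP waveform file
#'
#' Two-column delimited text (`time_s`, `voltage_V`) with a header line.
#' On load the time column must be strictly increasing and uniform; the
#' grid is shifted so the waveform peak sits at `t = 0` (a message is
#' emitted if a shift was needed).
#'
#' @param path File path.
#' @return An [ap_waveform()].
#' @export
read_waveform <- function(path) {
  tab <- .read_table2(path, c("time_s", "voltage_V"))
  if (any(diff(tab[[1]]) <= 0))
    stop("time column must be strictly increasing (first violation near line ",
         which(diff(tab[[1]]) <= 0)[1] + 1L, ")")
  ipk <- which.max(abs(tab[[2]]))
  if (abs(tab[[1]][ipk]) > 1e-12)
    message("read_waveform: peak at t = ", signif(tab[[1]][ipk], 3),
            " s re-centered to t = 0")
  ap_waveform(tab[[1]], tab[[2]], recenter = TRUE)
}

#' @rdname read_waveform
#' @param ap An [ap_waveform()] to write.
#' @export
write_waveform <- function(ap, path) {
  stopifnot(inherits(ap, "ap_waveform"))
  utils::write.table(
    data.frame(time_s = ap$time, voltage_V = ap$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sensitivity-profile file
#'
#' Two-column delimited text (`arclength_m`, `phi_V_per_A`) with a header,
#' e.g. a lead field exported from an external field solver sampled along a
#' fascicle center-line.
#'
#' @param path File path.
#' @param tapered Mark the loaded profile as already tapered.
#' @return A [sensitivity_profile()].
#' @export
read_profile <- function(path, tapered = FALSE) {
  tab <- .read_table2(path, c("arclength_m", "phi_V_per_A"))
  sensitivity_profile(tab[[1]], tab[[2]], label = basename(path),
                      tapered = tapered)
}

#' @rdname read_profile
#' @param profile A [sensitivity_profile()] to write.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  utils::write.table(
    data.frame(arclength_m = profile$arclength,
               phi_V_per_A = profile$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a recruitment-curve file
#'
#' Delimited text (`current_A`, `fraction`) with the reference diameter in
#' a `# d0_m:` comment line above the header.
#'
#' @param path File path.
#' @return A [recruitment_curve()].
#' @export
read_recruitment <- function(path) {
  lines <- readLines(path, n = 5L)
  d0line <- grep("^#\\s*d0_m:", lines, value = TRUE)
  if (!length(d0line)) stop("missing '# d0_m:' header comment in ", path)
  d0 <- as.numeric(sub("^#\\s*d0_m:\\s*", "", d0line[1]))
  tab <- .read_table2(path, c("current_A", "fraction"), comment = "#")
  recruitment_curve(tab[[1]], tab[[2]], d0)
}

#' @rdname read_recruitment
#' @param curve A [recruitment_curve()] to write.
#' @export
write_recruitment <- function(curve, path) {
  stopifnot(inherits(curve, "recruitment_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d0_m: %.15g", curve$d0), con)
  utils::write.table(
    data.frame(current_A = curve$current, fraction = curve$fraction),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a signal trace file
#'
#' Two-column delimited text (`time_s`, `voltage_V`) with a header.
#'
#' @param path File path.
#' @return A [signal_trace()].
#' @export
read_signal <- function(path) {
  tab <- .read_table2(path, c("time_s", "voltage_V"))
  signal_trace(tab[[1]], tab[[2]])
}

#' @rdname read_signal
#' @param s A [signal_trace()] to write.
#' @export
write_signal <- function(s, path) {
  stopifnot(inherits(s, "signal_trace"))
  utils::write.table(
    data.frame(time_s = s$time, voltage_V = s$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table2 <- function(path, expected, comment = "") {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = comment)
  if (ncol(tab) < 2L)
    stop("expected 2 columns (", paste(expected, collapse = ", "),
         ") in ", path)
  if (!all(expected %in% names(tab)))
    stop("missing header (expected columns ", paste(expected, collapse = ", "),
         ") in ", path)
  tab <- tab[, expected]
  if (anyNA(tab)) {
    bad <- which(rowSums(is.na(tab)) > 0)[1]
    stop("non-numeric value near line ", bad + 1L, " of ", path)
  }
  tab
}

#' Write / read a nerve specification as YAML
#'
#' @param spec A [nerve_spec()].
#' @param path File path.
#' @return `read_nerve_config()` returns a validated [nerve_spec()];
#'   round-tripping reproduces the specification exactly (within float
#'   formatting precision).
#' @export
write_nerve_config <- function(spec, path) {
  stopifnot(inherits(spec, "nerve_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 15L)
  invisible(path)
}

#' @rdname write_nerve_config
#' @export
read_nerve_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(nerve_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown nerve config keys: ", paste(unknown, collapse = ", "))
  do.call(nerve_spec, raw)
}

#' Run manifest of an output directory
#'
#' Records the seed, package version, the configuration and per-file MD5
#' checksums so that re-running with an identical configuration and seed
#' can be verified to reproduce identical outputs.
#'
#' @param dir Output directory.
#' @param config The configuration list that produced the outputs.
#' @param seed Seed used.
#' @param path Where to write the JSON manifest (default
#'   `dir/manifest.json`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, config, seed,
                           path = file.path(dir, "manifest.json")) {
  files <- setdiff(list.files(dir, full.names = TRUE), path)
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  man <- list(seed = seed,
              version = as.character(utils::packageVersion("ecapsim")),
              config_hash = unname(tools::md5sum(
                .write_temp_yaml(config))),
              checksums = as.list(sums))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

.write_temp_yaml <- function(x) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f, precision = 15L)
  f
}

#' Execute a scenario configuration
#'
#' Runs a complete pipeline described by a YAML configuration and writes
#' traces, tables and a manifest to an output directory. Supported `kind`s:
#' * `synth` — generate the nerve, write the spec and per-fascicle lead
#'   fields and recruitment curves.
#' * `ecap` — compute the eCAP at `current` (amperes); writes the total and
#'   per-contribution traces.
#' * `sweep` — amplitude sweep over `currents`; writes the summary table
#'   and per-current totals.
#' * `invert` — recover the gamma parameters of the myelinated-afferent
#'   diameter distribution from a reference trace (`reference` path, or
#'   self-generated from `true_shape`/`true_scale`).
#'
#' Every scenario embeds a `nerve` block (passed to [nerve_spec()]) or
#' a `nerve_config` path. Identical configuration and seed reproduce
#' identical output checksums.
#'
#' @param config_path Path to the YAML scenario configuration.
#' @param out_dir Output directory (created if needed).
#' @return Output directory path, invisibly.
#' @export
run_scenario <- function(config_path, out_dir) {
  cfg <- yaml::read_yaml(config_path)
  allowed <- c("kind", "nerve", "nerve_config", "current", "currents",
               "reference", "true_shape", "true_scale", "init_shape",
               "init_scale", "budget", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$kind) ||
      !cfg$kind %in% c("synth", "ecap", "sweep", "invert"))
    stop("config must set kind: synth | ecap | sweep | invert")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (!is.null(cfg$nerve_config)) read_nerve_config(cfg$nerve_config)
          else do.call(nerve_spec, as.list(cfg$nerve))
  if (!is.null(cfg$seed)) spec$seed <- as.integer(cfg$seed)
  nerve <- synth_nerve(spec)
  aps <- default_ap_waveforms()
  if (cfg$kind == "synth") {
    write_nerve_config(spec, file.path(out_dir, "nerve.yaml"))
    for (f in nerve$fascicles) {
      write_profile(f$sensitivity,
                    file.path(out_dir, paste0("phi_", f$id, ".tsv")))
      write_recruitment(f$recruitment$myelinated,
                        file.path(out_dir, paste0("recruitment_", f$id, ".tsv")))
    }
  } else if (cfg$kind == "ecap") {
    I <- as.numeric(cfg$current %||% spec$partial_current)
    res <- compute_ecap(nerve$fascicles, aps, I)
    write_signal(signal_trace(res$time, res$total),
                 file.path(out_dir, "ecap_total.tsv"))
    fc <- fascicle_contributions(res)
    for (id in rownames(fc))
      write_signal(signal_trace(res$time, fc[id, ]),
                   file.path(out_dir, paste0("ecap_", id, ".tsv")))
  } else if (cfg$kind == "sweep") {
    currents <- as.numeric(cfg$currents %||% spec$currents)
    sw <- amplitude_sweep(nerve$fascicles, aps, currents)
    utils::write.table(sw$summary, file.path(out_dir, "sweep_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (k in seq_along(currents))
      write_signal(signal_trace(sw$results[[k]]$time, sw$results[[k]]$total),
                   file.path(out_dir, sprintf("ecap_I%.0fuA.tsv",
                                              currents[k] * 1e6)))
  } else if (cfg$kind == "invert") {
    I <- as.numeric(cfg$current %||% spec$partial_current)
    fwd <- make_ecap_forward(nerve$fascicles, aps, I)
    truth <- NULL
    if (!is.null(cfg$reference)) {
      ref <- read_signal(cfg$reference)
    } else {
      truth <- c(as.numeric(cfg$true_shape %||% spec$gamma_myelinated[1]),
                 as.numeric(cfg$true_scale %||% spec$gamma_myelinated[2]))
      ref <- fwd(truth[1], truth[2])
    }
    init <- c(as.numeric(cfg$init_shape %||% spec$gamma_myelinated[1] * 1.3),
              as.numeric(cfg$init_scale %||% spec$gamma_myelinated[2] * 0.7))
    prob <- fit_problem(fwd, ref, init,
                        lower = init * 0 + c(init[1], init[2]) * 0.4,
                        upper = c(init[1], init[2]) * 2.5,
                        budget = as.integer(cfg$budget %||% 500L))
    fit <- fit_diameter_distribution(prob)
    report <- list(par = as.list(fit$par), value = fit$value,
                   evaluations = fit$evaluations,
                   converged = fit$converged, history = fit$history)
    if (!is.null(truth))
      report$relative_error <- as.list(abs(fit$par - truth) / truth)
    jsonlite::write_json(report, file.path(out_dir, "invert_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_manifest(out_dir, cfg, spec$seed)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
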