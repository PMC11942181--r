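.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("condstat_config_error",
                                             "error", "condition")))
}
.data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("condstat_data_error",
                                             "error", "condition")))
}

# Tidy CSV writer with '#' header lines echoing parameters and seed.
.write_stage_csv <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condstat %s | stage: %s | seed: %s",
                     as.character(utils::packageVersion("condstat")),
                     stage, seed), con)
  if (length(params))
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = " "), character(1))),
               con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.PIPELINE_STAGES <- c("generate", "align", "profile", "enrichment",
                      "contacts", "rdf_blocks", "rdf_guest", "rg", "tension")
.NEEDS_ALIGN <- c("profile", "enrichment")
.NEEDS_TRAJ <- c("align", "profile", "enrichment", "contacts",
                 "rdf_blocks", "rdf_guest", "rg")

#' Run the analysis pipeline
#'
#' Chains generate / align / analyse stages from a single configuration (an
#' R list or a YAML file). Stages execute in the order given; `profile` and
#' `enrichment` require `align` earlier in the list (or an input declared
#' `aligned: true`). Every output CSV carries `#` header lines echoing the
#' stage parameters and the seed; rerunning the same configuration
#' reproduces the outputs bit for bit.
#'
#' Configuration keys: `seed`, `outdir`, `stages` (vector of stage names),
#' `input` (optional: `gro` path, optional `annot`, optional `aligned`),
#' `generate` (morphology_spec fields), and one optional block per analysis
#' stage with its parameters (`profile: bin_width`, `enrichment:
#' central_width`, `contacts: cutoff`, `rdf_blocks`/`rdf_guest`: `n_bins`,
#' `rg: per`, `tension`: either `xvg` + `Lz` + `n_droplets` or generator
#' fields `tau_target` etc., plus `n_windows`).
#'
#' @param config List or path to a YAML file.
#' @param outdir Output directory override.
#' @return The run manifest (list: package version, seed, stages, parameter
#'   echo, output files), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .config_error("config must be a list or a YAML path")
  stages <- unlist(config$stages)
  if (!length(stages)) .config_error("config lists no stages")
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown))
    .config_error("unknown stage name: ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (!is.null(outdir)) outdir
    else if (!is.null(config$outdir)) config$outdir else "condstat_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  aligned <- isTRUE(config$input$aligned)
  for (st in stages) {
    if (st %in% .NEEDS_ALIGN && !aligned &&
        !("align" %in% stages[seq_len(match(st, stages) - 1L)]))
      .config_error("stage '", st, "' requires 'align' earlier in the ",
                    "stage list (input is not aligned)")
  }
  if (any(stages %in% .NEEDS_TRAJ) &&
      !("generate" %in% stages) && is.null(config$input$gro))
    .config_error("trajectory stages need either a 'generate' stage or ",
                  "input: gro")

  traj <- NULL
  if (!is.null(config$input$gro)) {
    if (!file.exists(config$input$gro))
      .data_error("input file not found: ", config$input$gro)
    traj <- read_gro(config$input$gro, annot = config$input$annot)
  }
  manifest <- list(package = "condstat",
                   version = as.character(utils::packageVersion("condstat")),
                   seed = seed, stages = as.list(stages),
                   parameters = list(), outputs = list())
  out_file <- function(name) file.path(outdir, name)

  for (st in stages) {
    params <- if (is.list(config[[st]])) config[[st]] else list()
    t0 <- proc.time()[["elapsed"]]
    path <- switch(
      st,
      generate = {
        gp <- params
        gp$seed <- if (is.null(gp$seed)) seed else gp$seed
        spec <- do.call(morphology_spec, gp)
        traj <- generate_condensate(spec)
        p <- out_file("frames.gro")
        write_gro(traj, p)
        write_annotation(traj$topology, out_file("annotation.csv"))
        manifest$outputs$annotation <- "annotation.csv"
        params <- spec[setdiff(names(spec), "box")]
        params$box <- spec$box
        p
      },
      align = {
        traj <- recenter_trajectory(
          traj, cutoff = if (is.null(params$cutoff)) 4.0 else params$cutoff)
        aligned <- TRUE
        p <- out_file("aligned.gro")
        write_gro(traj, p)
        p
      },
      profile = {
        bw <- if (is.null(params$bin_width)) 0.25 else params$bin_width
        prof <- density_profile(traj, bin_width = bw)
        params$bin_width <- bw
        .write_stage_csv(as.data.frame(prof), out_file("profile.csv"),
                         st, params, seed)
      },
      enrichment = {
        cw <- if (is.null(params$central_width))
          traj$frames[[1L]]$box[3L] / 6 else params$central_width
        e <- central_block_enrichment(traj, cw)
        params$central_width <- cw
        .write_stage_csv(data.frame(block = names(e), enrichment = unname(e)),
                         out_file("enrichment.csv"), st, params, seed)
      },
      contacts = {
        co <- if (is.null(params$cutoff)) 0.6 else params$cutoff
        cm <- contact_map(traj, cutoff = co)
        params$cutoff <- co
        long <- data.frame(i = rep(seq_len(nrow(cm)), ncol(cm)),
                           j = rep(seq_len(ncol(cm)), each = nrow(cm)),
                           frequency = as.vector(unclass(cm)))
        .write_stage_csv(long, out_file("contacts.csv"), st, params, seed)
      },
      rdf_blocks = {
        nb <- if (is.null(params$n_bins)) 200L else params$n_bins
        suite <- block_rdf_suite(traj, n_bins = nb)
        params$n_bins <- nb
        long <- do.call(rbind, lapply(names(suite), function(k)
          data.frame(pair = k, r = suite[[k]]$r, g = suite[[k]]$g)))
        .write_stage_csv(long, out_file("rdf_blocks.csv"), st, params, seed)
      },
      rdf_guest = {
        nb <- if (is.null(params$n_bins)) 200L else params$n_bins
        suite <- guest_environment_rdf(traj, n_bins = nb)
        params$n_bins <- nb
        long <- if (length(suite))
          do.call(rbind, lapply(names(suite), function(k)
            data.frame(native = k, r = suite[[k]]$r, g = suite[[k]]$g)))
          else data.frame(native = character(0), r = numeric(0),
                          g = numeric(0))
        .write_stage_csv(long, out_file("rdf_guest.csv"), st, params, seed)
      },
      rg = {
        per <- if (is.null(params$per)) "chain" else params$per
        rgres <- radius_of_gyration(traj, per = per)
        params$per <- per
        .write_stage_csv(summary(rgres), out_file("rg.csv"), st, params, seed)
      },
      tension = {
        nw <- if (is.null(params$n_windows)) 5L else params$n_windows
        series <- if (!is.null(params$xvg)) {
          if (!file.exists(params$xvg))
            .data_error("pressure file not found: ", params$xvg)
          read_pressure_xvg(params$xvg, Lz = params$Lz,
                            n_droplets = if (is.null(params$n_droplets)) 1L
                              else params$n_droplets)
        } else {
          generate_pressure_series(
            tau_target = if (is.null(params$tau_target)) 10 else params$tau_target,
            Lz = if (is.null(params$Lz)) 30 else params$Lz,
            n_droplets = if (is.null(params$n_droplets)) 1L else params$n_droplets,
            n_rows = if (is.null(params$n_rows)) 5000L else params$n_rows,
            noise_sd = if (is.null(params$noise_sd)) 1 else params$noise_sd,
            seed = seed)
        }
        stres <- surface_tension(series, n_windows = nw)
        params$n_windows <- nw
        .write_stage_csv(
          data.frame(tau_bar_nm = stres$tau_bar_nm,
                     tau_mn_m = stres$tau_mn_m, sd_bar_nm = stres$sd,
                     n_windows = stres$n_windows),
          out_file("tension.csv"), st, params, seed)
      })
    manifest$outputs[[st]] <- basename(path)
    manifest$parameters[[st]] <- params
    message(sprintf("[condstat] stage %-10s -> %s (%.2f s)", st,
                    basename(path), proc.time()[["elapsed"]] - t0))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$outputs$manifest <- "manifest.json"
  invisible(manifest)
}
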