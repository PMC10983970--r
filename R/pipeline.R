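# CSV dialect: comma, UTF-8, header, '.' decimal, floats at 6 significant
# digits
format_float_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}

write_csv_q <- function(df, path) {
  utils::write.csv(format_float_df(df), path, row.names = FALSE,
                   quote = FALSE)
  path
}

#' Assemble and validate a pipeline run configuration
#'
#' Every numeric field is validated by its owning parameter constructor
#' before any computation or I/O happens, so a bad config fails fast.
#'
#' @param stages character vector, ordered subset of: "simulate", "detect",
#'   "coloc", "migrate", "lifetime", "detach", "stats".
#' @param out_dir output directory (created if missing).
#' @param seed integer seed used by any simulating stage.
#' @param pixel_size_um,frame_interval_s physical calibration.
#' @param image,mask,image_b,tracks,counts,values input file paths for stages
#'   that read data (each `NULL` when the stage consumes a simulated
#'   upstream product instead).
#' @param sim a [synthetic_image_spec()] for `simulate`.
#' @param coloc_truth list(n_shared, n_a_only, n_b_only) for a simulated
#'   two-channel run.
#' @param prw a [prw_params()] for a simulated `migrate` run.
#' @param detach_sim list(n0, p_detach_per_step) for a simulated `detach`
#'   run.
#' @param detection a [detection_params()].
#' @param link a [link_params()].
#' @param lifetime a [lifetime_params()].
#' @param rout a [rout_params()].
#' @param gate_threshold chemotaxis gate threshold.
#' @param verbose log per-object detail to stderr.
#' @export
run_config <- function(stages, out_dir, seed = 1L,
                       pixel_size_um = 0.1, frame_interval_s = 0.75,
                       image = NULL, mask = NULL, image_b = NULL,
                       tracks = NULL, counts = NULL, values = NULL,
                       sim = NULL, coloc_truth = NULL, prw = NULL,
                       detach_sim = NULL,
                       detection = detection_params(),
                       link = link_params(),
                       lifetime = lifetime_params(),
                       rout = rout_params(),
                       gate_threshold = 0.8, verbose = FALSE) {
  known <- c("simulate", "detect", "coloc", "migrate", "lifetime",
             "detach", "stats")
  if (!length(stages) || !all(stages %in% known)) {
    stop("stages must be a subset of: ", paste(known, collapse = ", "))
  }
  stopifnot(pixel_size_um > 0, frame_interval_s > 0,
            inherits(detection, "detection_params"),
            inherits(link, "link_params"),
            inherits(lifetime, "lifetime_params"),
            inherits(rout, "rout_params"))
  if (!is.null(sim)) stopifnot(inherits(sim, "synthetic_image_spec"))
  if (!is.null(prw)) stopifnot(inherits(prw, "prw_params"))
  if (!(gate_threshold > 0 && gate_threshold <= 1)) {
    stop("gate_threshold must lie in (0, 1]")
  }
  structure(list(
    stages = stages, out_dir = out_dir, seed = as.integer(seed),
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    image = image, mask = mask, image_b = image_b, tracks = tracks,
    counts = counts, values = values, sim = sim, coloc_truth = coloc_truth,
    prw = prw, detach_sim = detach_sim, detection = detection, link = link,
    lifetime = lifetime, rout = rout, gate_threshold = gate_threshold,
    verbose = isTRUE(verbose)
  ), class = "run_config")
}

log_stage <- function(cfg, ...) {
  message("[adhesioquant] ", ...)
}

require_path <- function(path, what) {
  if (is.null(path)) stop("no input available for ", what)
  if (!file.exists(path)) stop(what, " input not found: ", path)
  path
}

#' Run a pipeline stage chain
#'
#' Executes the configured stages in order, never mutating inputs; all
#' outputs plus a manifest (config echo, package version, per-stage record
#' counts, warnings) are written under `out_dir`. Re-running the same config
#' and seed reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "adhesioquant",
    version = as.character(utils::packageVersion("adhesioquant")),
    seed = config$seed,
    stages = config$stages,
    counts = list(), outputs = character(0), warnings = character(0)
  )
  state <- new.env(parent = emptyenv())
  add_out <- function(p) manifest$outputs <<- c(manifest$outputs, basename(p))

  for (st in config$stages) {
    log_stage(config, "stage: ", st)
    switch(st,
      simulate = {
        sim <- if (is.null(config$sim)) {
          synthetic_image_spec(pixel_size_um = config$pixel_size_um,
                               seed = config$seed)
        } else config$sim
        if (!is.null(config$coloc_truth)) {
          ct <- config$coloc_truth
          g <- gen_two_channel(sim, ct$n_shared, ct$n_a_only, ct$n_b_only)
          state$image <- g$image_a; state$image_b <- g$image_b
          state$mask <- g$mask; state$truth <- g$truth
        } else {
          g <- gen_punctae_image(sim)
          state$image <- g$image; state$mask <- g$mask; state$truth <- g$truth
        }
        add_out(write_image(state$image, file.path(config$out_dir,
                                                   "simulated.tif")))
        if (!is.null(state$image_b)) {
          add_out(write_image(state$image_b,
                              file.path(config$out_dir, "simulated_b.tif")))
        }
        add_out(write_image(state$mask, file.path(config$out_dir,
                                                  "simulated_mask.tif")))
        jsonlite::write_json(g$truth,
                             file.path(config$out_dir, "ground_truth.json"),
                             digits = NA, auto_unbox = TRUE)
        add_out(file.path(config$out_dir, "ground_truth.json"))
        manifest$counts$simulate <- nrow(g$truth)
      },
      detect = {
        img <- if (!is.null(state$image)) state$image else
          read_image(require_path(config$image, "detect"),
                     config$pixel_size_um)
        msk <- if (!is.null(state$mask)) state$mask else if (
          !is.null(config$mask)) {
          mi <- read_image(require_path(config$mask, "mask"),
                           config$pixel_size_um)
          mi$pixels > 0
        } else segment_cell(img)
        ps <- detect_punctae(img, msk, config$detection)
        state$punctae <- ps
        add_out(write_csv_q(ps$punctae,
                            file.path(config$out_dir, "punctae.csv")))
        summ <- data.frame(
          n_punctae = nrow(ps$punctae),
          mean_area_um2 = if (nrow(ps$punctae)) mean(ps$punctae$area_um2)
          else NA_real_)
        add_out(write_csv_q(summ,
                            file.path(config$out_dir, "punctae_summary.csv")))
        manifest$counts$detect <- nrow(ps$punctae)
      },
      coloc = {
        if (is.null(state$image_b) && is.null(config$image_b)) {
          stop("coloc needs a second channel (image_b or simulated pair)")
        }
        img_b <- if (!is.null(state$image_b)) state$image_b else
          read_image(require_path(config$image_b, "coloc"),
                     config$pixel_size_um)
        msk <- state$mask
        if (is.null(msk)) msk <- segment_cell(img_b)
        ps_a <- if (!is.null(state$punctae)) state$punctae else
          detect_punctae(if (!is.null(state$image)) state$image else
            read_image(require_path(config$image, "coloc channel A"),
                       config$pixel_size_um), msk, config$detection)
        ps_b <- detect_punctae(img_b, msk, config$detection)
        cc <- colocalize(ps_a, ps_b)
        add_out(write_csv_q(
          data.frame(n_a_only = cc$n_a_only, n_b_only = cc$n_b_only,
                     n_double = cc$n_double),
          file.path(config$out_dir, "coloc.csv")))
        manifest$counts$coloc <- cc$n_double
      },
      migrate = {
        ts <- if (!is.null(config$tracks)) {
          read_tracks_csv(require_path(config$tracks, "migrate"))
        } else if (!is.null(config$prw)) {
          gen_tracks(config$prw)
        } else stop("migrate needs a tracks CSV or prw simulation params")
        speeds <- data.frame(
          track_id = vapply(ts$tracks, attr, numeric(1L), "track_id"),
          speed_um_min = vapply(ts$tracks, track_speed, numeric(1L)))
        add_out(write_csv_q(speeds,
                            file.path(config$out_dir, "speeds.csv")))
        mm <- msd(ts)
        add_out(write_csv_q(mm, file.path(config$out_dir, "msd.csv")))
        gate <- chemotaxis_gate(ts, config$gate_threshold)
        jsonlite::write_json(
          gate[c("fraction_toward", "threshold", "passed")],
          file.path(config$out_dir, "gate.json"), auto_unbox = TRUE,
          digits = NA)
        add_out(file.path(config$out_dir, "gate.json"))
        add_out(write_tracks_csv(spider_coordinates(ts),
                                 file.path(config$out_dir, "spider.csv")))
        manifest$counts$migrate <- length(ts$tracks)
      },
      lifetime = {
        stk <- if (!is.null(state$stack)) state$stack else {
          p <- require_path(config$image, "lifetime stack")
          read_image(p, config$pixel_size_um, config$frame_interval_s)
        }
        if (!inherits(stk, "image_stack")) stop("lifetime needs a stack")
        filt <- regional_maxima_3x3(stk)
        ptr <- track_punctae(filt, det_params = config$detection)
        traces <- extract_traces(filt, ptr, config$lifetime)
        fits <- lapply(traces, function(tr) {
          fit_lifetime(smooth_trace(tr, config$lifetime$smooth_window),
                       config$lifetime)
        })
        tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
          cf <- coef(fits[[i]])
          data.frame(track_id = attr(traces[[i]], "id"), t(cf),
                     converged = all(fits[[i]]$converged))
        }))
        if (is.null(tab)) {
          tab <- data.frame(track_id = integer(0))
          manifest$warnings <- c(manifest$warnings,
                                 "lifetime: no tracks survived filtering")
        }
        add_out(write_csv_q(tab, file.path(config$out_dir,
                                           "lifetime_fits.csv")))
        manifest$counts$lifetime <- nrow(tab)
      },
      detach = {
        series <- if (!is.null(config$counts)) {
          df <- utils::read.csv(require_path(config$counts, "detach"))
          detachment_series(df$flow_rate_ul_min[-1L], df$count)
        } else if (!is.null(config$detach_sim)) {
          ds <- config$detach_sim
          gen_detachment_counts(ds$n0, ds$p_detach_per_step,
                                seed = config$seed)
        } else stop("detach needs a counts CSV or simulation params")
        pct <- percent_detached(series)
        add_out(write_csv_q(pct, file.path(config$out_dir,
                                           "detachment.csv")))
        manifest$counts$detach <- nrow(pct)
      },
      stats = {
        df <- utils::read.csv(require_path(config$values, "stats"))
        if (!"value" %in% names(df)) stop("stats CSV needs a value column")
        groups <- if ("group" %in% names(df)) {
          split(df$value, df$group)
        } else list(all = df$value)
        res <- lapply(groups, rout_outliers, params = config$rout)
        kept <- do.call(rbind, lapply(names(res), function(g) {
          data.frame(group = g, value = res[[g]]$kept)
        }))
        flagged <- do.call(rbind, lapply(names(res), function(g) {
          if (length(res[[g]]$flagged)) {
            data.frame(group = g, value = res[[g]]$flagged)
          } else NULL
        }))
        if (is.null(flagged)) {
          flagged <- data.frame(group = character(0), value = numeric(0))
        }
        add_out(write_csv_q(kept, file.path(config$out_dir, "kept.csv")))
        add_out(write_csv_q(flagged,
                            file.path(config$out_dir, "flagged.csv")))
        summ <- group_summary(lapply(res, `[[`, "kept"))
        jsonlite::write_json(summ, file.path(config$out_dir,
                                             "stats_summary.json"),
                             dataframe = "rows", digits = NA)
        add_out(file.path(config$out_dir, "stats_summary.json"))
        manifest$counts$stats <- sum(vapply(res, function(r)
          length(r$flagged), integer(1L)))
      }
    )
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
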