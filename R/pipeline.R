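#' Read a pipeline configuration file
#'
#' YAML configuration with sections per stage (`detection`, `profile`,
#' `clustering`); missing entries fall back to package defaults. Values
#' given as function arguments to [run_pipeline()] override the file.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return Nested list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    detection = list(scale = 0.065, min_area = 10, max_area = 60,
                     low = 0.1, high = 0.3, closing_radius = 2,
                     exclude_border = TRUE, blur_sigma = 1),
    profile = list(window = 0.05, L = 1000, prominence = 5, smooth = 3),
    clustering = list(k = 0, linkage = "ward")
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    for (key in names(user[[sec]])) {
      defaults[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  defaults
}

#' Run the full analysis pipeline on a folder of TIFF images
#'
#' Executes every stage in order: nucleus detection in each image, angle
#' profiles, alignment and median-profile construction, landmark discovery
#' and mapping, vertical orientation, the full morphometric parameter set,
#' optional hierarchical clustering, consensus shapes and summary
#' statistics. All stage outputs are written under `out_dir`; re-running on
#' identical input reproduces identical outputs.
#'
#' @param folder Directory containing `.tif`/`.tiff` images.
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list from [read_config()], or a YAML path.
#' @param k Number of clusters (0 disables clustering), overriding the
#'   config.
#' @param verbose Log per-stage counts with [message()].
#' @return Invisibly, a list with `records` (per-nucleus measurements),
#'   `fit` (the [fit_profiles()] object), `clusters` and `summary`.
#' @export
run_pipeline <- function(folder, out_dir = file.path(folder, "analysis"),
                         config = read_config(), k = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  files <- list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no TIFF images found in '", folder, "'")
  log <- function(...) if (verbose) message(sprintf(...))
  dp <- do.call(detection_params, config$detection)
  outlines <- list()
  for (f in sort(files)) {
    dets <- tryCatch(detect_nuclei(f, dp), error = function(e) {
      warning("skipping unreadable image '", basename(f), "': ",
              conditionMessage(e))
      list()
    })
    for (d in seq_along(dets)) {
      dets[[d]]$id <- sprintf("%s#%02d", basename(f), d)
    }
    log("%s: %d nuclei", basename(f), length(dets))
    outlines <- c(outlines, dets)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!length(outlines)) {
    utils::write.csv(data.frame(), file.path(out_dir, "nuclei.csv"),
                     row.names = FALSE)
    log("no nuclei detected in %d images", length(files))
    return(invisible(list(records = data.frame(), fit = NULL,
                          clusters = NULL, summary = data.frame())))
  }
  log("total: %d nuclei from %d images", length(outlines), length(files))
  pc <- config$profile
  fit <- fit_profiles(outlines, window = pc$window, L = pc$L,
                      prominence = pc$prominence, smooth = pc$smooth)
  records <- measure_nuclei(fit)
  oriented <- attr(records, "oriented")
  kk <- if (!is.null(k)) k else config$clustering$k
  clusters <- NULL
  if (kk >= 2) {
    clusters <- cluster_profiles(fit, k = kk,
                                 linkage = config$clustering$linkage)
    records$cluster <- clusters$labels
    shapes <- lapply(split(seq_along(oriented), clusters$labels),
                     function(ix) build_consensus(oriented[ix]))
    names(shapes) <- paste0("cluster", names(shapes))
    write_consensus_svg(shapes, file.path(out_dir, "consensus_clusters.svg"))
    log("clustered into %d groups: %s", kk,
        paste(tabulate(clusters$labels, kk), collapse = ", "))
  }
  cons <- build_consensus(oriented)
  write_consensus_svg(cons, file.path(out_dir, "consensus.svg"))
  consensus_to_csv(cons, file.path(out_dir, "consensus.csv"))
  smry <- summarize_records(records)
  utils::write.csv(records, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(smry, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(position = seq_len(fit$L), median = fit$median$median,
               q1 = fit$median$q1, q3 = fit$median$q3),
    file.path(out_dir, "median_profile.csv"), row.names = FALSE)
  utils::write.csv(
    cbind(as.data.frame(fit$landmarks),
          perimeter_fraction = (fit$landmarks$index - 1) / fit$L),
    file.path(out_dir, "landmarks.csv"), row.names = FALSE)
  invisible(list(records = records, fit = fit, clusters = clusters,
                 summary = smry))
}
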