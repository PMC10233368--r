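#' Pipeline configuration
#'
#' All thresholds of the analysis live here so that every screen constant
#' (the lower-tail Z cutoff of 10, the strict twofold preference rule,
#' the replicate-SD flag level of 3) is an auditable parameter rather
#' than a hard-coded value.  The configuration round-trips losslessly
#' through YAML ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param z_threshold Lower-tail membrane Z-score exclusion cutoff
#'   (default 10).
#' @param preference_threshold Strict fold-change cutoff (default 2).
#' @param sd_flag_threshold Replicate-SD flag level (default 3).
#' @param min_replicates Minimum valid replicate ratios per set
#'   (default 3).
#' @param od_floor Minimum pre-lysis OD600 (default 0.2).
#' @param control_floor_frac Loading-control validity floor as a fraction
#'   of the bait's median control intensity (default 0.05).
#' @param detection_floor `"auto"` (95th percentile of empty-position
#'   ratios per bait; requires empty grid positions) or a numeric
#'   normalized-signal floor.
#' @param grid_rows,grid_cols Array dimensions.
#' @param max_profile_len N-terminal positions profiled for SP
#'   hydropathy (default 25).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param screen Optional [screen_config()] for simulated input; `NULL`
#'   means images and tables are read from `paths`.
#' @param paths Named list of input paths (`images` directory or vector,
#'   `plate_map`, `od_table`, `annotations`, `sp_fasta`) when running on
#'   real data.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(z_threshold = 10, preference_threshold = 2,
                            sd_flag_threshold = 3, min_replicates = 3L,
                            od_floor = 0.2, control_floor_frac = 0.05,
                            detection_floor = "auto",
                            grid_rows = 32L, grid_cols = 48L,
                            max_profile_len = 25L,
                            out_dir = NULL, seed = 1L,
                            screen = NULL, paths = list()) {
  thr <- c(z_threshold, preference_threshold, sd_flag_threshold,
           min_replicates, od_floor, control_floor_frac)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.character(detection_floor) && detection_floor != "auto")
    stop("detection_floor must be \"auto\" or a positive number")
  if (is.numeric(detection_floor) && any(detection_floor <= 0))
    stop("detection_floor must be \"auto\" or a positive number")
  structure(list(z_threshold = z_threshold,
                 preference_threshold = preference_threshold,
                 sd_flag_threshold = sd_flag_threshold,
                 min_replicates = as.integer(min_replicates),
                 od_floor = od_floor,
                 control_floor_frac = control_floor_frac,
                 detection_floor = detection_floor,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 max_profile_len = as.integer(max_profile_len),
                 out_dir = out_dir, seed = as.integer(seed),
                 screen = screen, paths = paths),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  screen <- NULL
  if (!is.null(y$screen)) {
    sc <- y$screen
    sc$category_fractions <- unlist(sc$category_fractions)
    screen <- do.call(screen_config, sc)
  }
  y$screen <- NULL
  y$paths <- if (is.null(y$paths)) list() else y$paths
  cfg <- do.call(pipeline_config, y)
  cfg$screen <- screen
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$screen)) {
    y$screen <- unclass(y$screen)
    y$screen$category_fractions <- as.list(y$screen$category_fractions)
  }
  y <- y[!vapply(y, is.null, TRUE)]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Quantify a set of membranes
#'
#' Fits the grid and measures every dot on each membrane, returning one
#' combined table.
#'
#' @param images Named list of two-channel membranes (names = membrane
#'   ids).
#' @param rows,cols Grid dimensions.
#' @return Data frame: [quantify_dots()] output per membrane with a
#'   `membrane_id` column prepended, plus an attribute `"grids"` (the
#'   fitted `array_grid` per membrane).
#' @export
quantify_membranes <- function(images, rows, cols) {
  stopifnot(!is.null(names(images)))
  grids <- list()
  tabs <- lapply(names(images), function(mid) {
    g <- fit_grid(images[[mid]], rows, cols)
    grids[[mid]] <<- g
    cbind(membrane_id = mid, quantify_dots(images[[mid]], g),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(tabs, make.row.names = FALSE))
  attr(out, "grids") <- grids
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full screen analysis pipeline
#'
#' simulate (or load) -> quantify -> normalize/QC/call -> SP hydropathy
#' profiles.  With `config$screen` set, a synthetic screen is generated
#' and analysed end to end; annotations and SP sequences are synthesized
#' from the planted truth (each true preference group receives signal
#' peptides with a distinct N-terminal hydropathy profile) so the SP
#' stage is exercised without external inputs.  With `config$paths` set,
#' images and tables are read from disk instead.
#'
#' All stages are deterministic given the configuration and seed.  When
#' `config$out_dir` is set, every stage's outputs are written there
#' (`membranes/*.tif`, `plate_map.tsv`, `od.tsv`, `dots.tsv`, `sets.tsv`,
#' `preferences.tsv`, `summary.tsv`, `profiles.tsv`, `qc_report.tsv`)
#' together with a `manifest.yaml` recording package version and all
#' parameters.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @return List of class `screen_result`: `dots`, `sets`, `pairs`,
#'   `summary`, `profiles`, `qc`, `floors`, `truth` (synthetic runs
#'   only), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  if (!is.null(config$screen)) {
    scr <- stage("simulate", generate_screen(config$screen))
    images <- scr$images
    plate_map <- scr$plate_map
    od_table <- scr$od_table
    truth <- scr$truth
    rows <- config$screen$grid_rows; cols <- config$screen$grid_cols
  } else {
    p <- config$paths
    for (need in c("images", "plate_map", "od_table"))
      if (is.null(p[[need]])) stop("[stage load] config$paths$", need,
                                   " is required when no screen is simulated")
    img_files <- if (length(p$images) == 1L && dir.exists(p$images))
      list.files(p$images, pattern = "\\.tiff?$", full.names = TRUE)
    else p$images
    missing_f <- img_files[!file.exists(img_files)]
    if (length(missing_f) > 0L)
      stop("[stage load] membrane image file not found: ",
           paste(missing_f, collapse = ", "))
    images <- stage("load", lapply(img_files, read_membrane_tiff))
    names(images) <- sub("\\.tiff?$", "", basename(img_files))
    plate_map <- stage("load", read_plate_map(p$plate_map))
    od_table <- stage("load", read_od_table(p$od_table))
    bad <- setdiff(unique(plate_map$membrane_id), names(images))
    if (length(bad) > 0L)
      stop("[stage load] plate map references membrane(s) with no image: ",
           paste(bad, collapse = ", "))
    truth <- NULL
    rows <- config$grid_rows; cols <- config$grid_cols
  }

  dots <- stage("quantify", quantify_membranes(images, rows, cols))
  sets <- stage("normalize", build_sets(dots, plate_map,
                                        min_replicates = config$min_replicates,
                                        control_floor_frac = config$control_floor_frac))
  sets <- stage("qc", apply_exclusions(sets, od_table,
                                       z_threshold = config$z_threshold,
                                       sd_flag_threshold = config$sd_flag_threshold,
                                       od_floor = config$od_floor))
  floors <- stage("call", if (identical(config$detection_floor, "auto"))
    detection_floor_auto(dots, plate_map)
  else config$detection_floor)
  pairs <- stage("call", call_preferences(sets,
                                          preference_threshold = config$preference_threshold,
                                          detection_floor = floors))
  summary_tab <- stage("call", summarize_screen(pairs))
  qc <- stage("qc", qc_report(sets))

  profiles <- NULL
  annotations <- NULL
  if (!is.null(config$paths$annotations)) {
    annotations <- stage("sp", read_annotations(config$paths$annotations))
    if (!is.null(config$paths$sp_fasta)) {
      sp <- stage("sp", read_fasta(config$paths$sp_fasta))
      idx <- match(annotations$protein_id, names(sp))
      annotations$sp_sequence <- ifelse(is.na(idx), NA, sp[idx])
    }
  } else if (!is.null(truth)) {
    annotations <- stage("sp", synthesize_annotations(truth, config$seed))
  }
  if (!is.null(annotations)) {
    profiles <- stage("sp", sp_profiles_by_category(pairs, annotations,
                                                    max_len = config$max_profile_len))
  }

  result <- structure(list(dots = dots, sets = sets, pairs = pairs,
                           summary = summary_tab, profiles = profiles,
                           qc = qc, floors = floors, truth = truth,
                           config = config),
                      class = "screen_result")
  if (!is.null(config$out_dir))
    write_results(result, images, plate_map, od_table, annotations)
  result
}

# synthetic feature annotations: interacting preys get an SP whose
# N-terminal hydropathy encodes the planted preference (hydrophobic start
# for bait A, hydrophilic for bait B, intermediate for shared clients)
synthesize_annotations <- function(truth, seed) {
  preys <- truth$preys
  profiles <- list(prefers_A = c(3.8, 3.8, 3.8, rep(2.0, 22)),
                   prefers_B = c(-3.0, -3.0, -3.0, rep(2.0, 22)),
                   equal = c(0.5, 0.5, 0.5, rep(2.0, 22)))
  counts <- table(factor(preys$category, levels = names(profiles)))
  nmax <- max(counts, 1L)
  sets <- generate_sp_set(nmax, 22L, profiles, seed = seed)
  ann <- data.frame(protein_id = preys$prey_id,
                    has_sp = preys$category != "null",
                    has_tmd = FALSE, has_mts = FALSE,
                    sp_sequence = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in names(profiles)) {
    sel <- which(preys$category == g)
    if (length(sel) > 0L)
      ann$sp_sequence[sel] <- sets[[g]][seq_along(sel)]
  }
  ann
}

#' Hydropathy profiles per preference category
#'
#' Filters preys to substrate candidates ([filter_substrates()]), groups
#' them by called preference category, and computes the per-position
#' Kyte-Doolittle profile of their signal peptides.
#'
#' @param pairs Preference calls ([call_preferences()]).
#' @param annotations Feature annotation table including `sp_sequence`.
#' @param max_len,window Passed to [group_profile()].
#' @param categories Categories profiled (default: both preferring groups
#'   and the shared-interactor group).
#' @return Data frame of stacked [group_profile()] results.
#' @export
sp_profiles_by_category <- function(pairs, annotations, max_len = 25L,
                                    window = 1L,
                                    categories = c("prefers_A", "prefers_B",
                                                   "both")) {
  cand <- filter_substrates(pairs, annotations)
  cand <- cand[!is.na(cand$candidate) & cand$candidate & cand$has_sp, ,
               drop = FALSE]
  seqs <- annotations$sp_sequence[match(cand$prey_id,
                                        annotations$protein_id)]
  keep <- !is.na(seqs) & seqs != ""
  cand <- cand[keep, , drop = FALSE]; seqs <- seqs[keep]
  rows <- lapply(categories, function(g) {
    s <- seqs[cand$category == g]
    if (length(s) == 0L) return(NULL)
    group_profile(s, max_len = max_len, group = g, window = window)
  })
  do.call(rbind, rows)
}

write_results <- function(result, images, plate_map, od_table,
                          annotations) {
  out <- result$config$out_dir
  dir.create(file.path(out, "membranes"), recursive = TRUE,
             showWarnings = FALSE)
  for (mid in names(images))
    write_membrane_tiff(images[[mid]],
                        file.path(out, "membranes", paste0(mid, ".tif")))
  write_tsv_file(plate_map, file.path(out, "plate_map.tsv"))
  write_tsv_file(od_table, file.path(out, "od.tsv"))
  dots <- result$dots
  write_tsv_file(dots, file.path(out, "dots.tsv"))
  write_tsv_file(result$sets, file.path(out, "sets.tsv"))
  pairs <- result$pairs
  pairs$category <- as.character(pairs$category)
  write_tsv_file(pairs, file.path(out, "preferences.tsv"))
  write_tsv_file(result$summary, file.path(out, "summary.tsv"))
  if (!is.null(result$profiles))
    write_tsv_file(result$profiles, file.path(out, "profiles.tsv"))
  if (!is.null(annotations))
    write_tsv_file(annotations, file.path(out, "annotations.tsv"))
  qc <- result$qc
  write_tsv_file(data.frame(metric = c("n_excluded", "n_sd_flagged",
                                       "max_replicate_sd"),
                            value = c(qc$n_excluded, qc$n_sd_flagged,
                                      qc$max_replicate_sd)),
                 file.path(out, "qc_report.tsv"))
  if (!is.null(result$truth)) {
    write_tsv_file(result$truth$preys, file.path(out, "truth_preys.tsv"))
    write_tsv_file(result$truth$strains,
                   file.path(out, "truth_strains.tsv"))
  }
  manifest <- list(package = "dotscreen",
                   version = as.character(utils::packageVersion("dotscreen")),
                   seed = result$config$seed,
                   parameters = unclass(result$config)[
                     c("z_threshold", "preference_threshold",
                       "sd_flag_threshold", "min_replicates", "od_floor",
                       "control_floor_frac", "grid_rows", "grid_cols")],
                   detection_floor = if (is.numeric(result$floors))
                     as.list(result$floors) else result$floors)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Proximity-biotinylation screen result\n")
  cat("  preys called:", nrow(x$pairs), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-14s %d\n", s$category[i], s$n[i]))
  cat("  excluded sets:", x$qc$n_excluded,
      "| replicate-SD flags:", x$qc$n_sd_flagged, "\n")
  invisible(x)
}
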