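#' Preference categories
#'
#' The five mutually exclusive, exhaustive categories a prey can receive:
#' `excluded` (failed QC on either bait), `no_interaction` (below the
#' detection floor for both baits), `both` (detected with both baits, no
#' twofold difference), `prefers_A`, `prefers_B`.
#' @return Character vector of category levels.
#' @export
preference_categories <- function()
  c("excluded", "no_interaction", "both", "prefers_A", "prefers_B")

#' Normalize a dot's biotinylation signal by its loading control
#'
#' Returns `signal_corrected / control_corrected` (the SA/LC ratio: the
#' streptavidin biotinylation signal over the anti-H3 loading control,
#' which corrects for the amount of protein spotted).  A control at or
#' below `control_floor` marks the dot invalid instead of producing an
#' unbounded ratio.
#'
#' @param signal_corrected,control_corrected Background-corrected
#'   intensities (>= 0); vectorized.
#' @param control_floor Minimum loading-control intensity for a valid
#'   ratio (same units as `control_corrected`).
#' @return Data frame with columns `ratio` (NA where invalid) and `valid`.
#' @examples
#' normalize_dot(200, 100, control_floor = 10)
#' @export
normalize_dot <- function(signal_corrected, control_corrected,
                          control_floor = 0) {
  if (any(signal_corrected < 0, na.rm = TRUE) ||
      any(control_corrected < 0, na.rm = TRUE))
    stop("corrected intensities must be >= 0")
  valid <- !is.na(control_corrected) & control_corrected > control_floor
  ratio <- ifelse(valid, signal_corrected / control_corrected, NA_real_)
  data.frame(ratio = ratio, valid = valid)
}

#' Aggregate replicate SA/LC ratios for one bait-prey set
#'
#' The screen design yields up to nine replicate ratios per set (three
#' biological x three technical).  The aggregate is the median of the
#' valid ratios -- robust to a single pin or transfer artifact -- with the
#' sample standard deviation reported for the reproducibility record.
#' Fewer than `min_replicates` valid ratios refuses aggregation.
#'
#' @param ratios Numeric vector of replicate SA/LC ratios (NA = invalid
#'   dot).
#' @param min_replicates Minimum valid replicates required (default 3).
#' @return List `aggregate` (median; NA if refused), `replicate_sd`
#'   (sample SD; 0 if a single value), `n_used`, and `reason` (NA or why
#'   aggregation was refused).
#' @export
aggregate_replicates <- function(ratios, min_replicates = 3L) {
  x <- ratios[!is.na(ratios)]
  if (any(x < 0) || any(!is.finite(x)))
    stop("ratios must be finite and >= 0")
  if (length(x) < min_replicates)
    return(list(aggregate = NA_real_, replicate_sd = NA_real_,
                n_used = length(x),
                reason = sprintf("too_few_replicates (%d < %d)",
                                 length(x), min_replicates)))
  list(aggregate = stats::median(x),
       replicate_sd = if (length(x) > 1L) stats::sd(x) else 0,
       n_used = length(x), reason = NA_character_)
}

#' Build per-(bait, prey) normalized sets from dot measurements
#'
#' Joins per-dot measurements to the plate map, normalizes each dot by
#' its loading control, and aggregates the replicates of every bait-prey
#' set.
#'
#' @param dots Data frame of dot measurements across membranes: the
#'   output of [quantify_dots()] per membrane, row-bound with a
#'   `membrane_id` column (see [quantify_membranes()]).
#' @param plate_map Data frame `membrane_id, row, col, bait_id, prey_id,
#'   bio_rep, tech_rep`.
#' @param min_replicates Passed to [aggregate_replicates()].
#' @param control_floor_frac The control floor for [normalize_dot()] is
#'   this fraction of the median corrected control intensity over all
#'   mapped dots of the same bait (scale-free, so rescaling a channel
#'   does not change validity calls).
#' @return Data frame, one row per bait-prey set: `bait_id, prey_id,
#'   aggregate_signal, replicate_sd, n_used, reason`.
#' @export
build_sets <- function(dots, plate_map, min_replicates = 3L,
                       control_floor_frac = 0.05) {
  key_d <- paste(dots$membrane_id, dots$row, dots$col)
  key_m <- paste(plate_map$membrane_id, plate_map$row, plate_map$col)
  idx <- match(key_m, key_d)
  if (anyNA(idx))
    stop("plate map references positions absent from the dot measurements (e.g. ",
         key_m[which(is.na(idx))[1L]], ")")
  m <- cbind(plate_map,
             dots[idx, c("signal_corrected", "control_corrected"),
                  drop = FALSE])
  out <- do.call(rbind, lapply(split(m, m$bait_id), function(mb) {
    floor_b <- control_floor_frac * stats::median(mb$control_corrected)
    nr <- normalize_dot(mb$signal_corrected, mb$control_corrected,
                        control_floor = floor_b)
    agg <- lapply(split(nr$ratio, mb$prey_id), aggregate_replicates,
                  min_replicates = min_replicates)
    data.frame(bait_id = mb$bait_id[1L], prey_id = names(agg),
               aggregate_signal = vapply(agg, `[[`, 0, "aggregate"),
               replicate_sd = vapply(agg, `[[`, 0, "replicate_sd"),
               n_used = vapply(agg, function(a) as.integer(a$n_used), 0L),
               reason = vapply(agg, `[[`, "", "reason"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Apply the screen's exclusion rules to normalized sets
#'
#' A set is excluded when (i) its strain was missing to begin with, as
#' indicated by a pre-lysis OD below `od_floor` (or absent from the OD
#' table), (ii) too few valid replicates survived, or (iii) its aggregate
#' normalized signal lies more than `z_threshold` standard deviations
#' *below* the rest of its membrane group (leave-one-out mean and SD over
#' the other QC-passing sets of the same bait).  The Z rule is one-sided:
#' high outliers are the strong interactors the screen is looking for and
#' are never excluded.  Sets whose replicate SD exceeds
#' `sd_flag_threshold` are flagged for the reproducibility report but not
#' excluded.
#'
#' @param sets Data frame from [build_sets()] (columns `bait_id, prey_id,
#'   aggregate_signal, replicate_sd`, optionally `reason`).
#' @param od_table Data frame `strain_id, od600` with
#'   `strain_id = "<bait>:<prey>"`.
#' @param z_threshold Lower-tail Z cutoff (default 10).
#' @param sd_flag_threshold Replicate-SD flag level (default 3).
#' @param od_floor Minimum pre-lysis OD600 (default 0.2).
#' @param min_group Z-scores are only computed when a bait group has at
#'   least this many eligible sets (default 10).
#' @return `sets` with added columns `od_ok`, `membrane_z`, `excluded`,
#'   `exclusion_reason`, `sd_flag`.
#' @export
apply_exclusions <- function(sets, od_table, z_threshold = 10,
                             sd_flag_threshold = 3, od_floor = 0.2,
                             min_group = 10L) {
  stopifnot(is.data.frame(sets), is.data.frame(od_table))
  strain <- paste(sets$bait_id, sets$prey_id, sep = ":")
  od <- od_table$od600[match(strain, od_table$strain_id)]
  out <- sets
  out$od_ok <- !is.na(od) & od >= od_floor
  out$membrane_z <- NA_real_
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_

  no_od <- is.na(od)
  missing_strain <- !no_od & od < od_floor
  too_few <- is.na(out$aggregate_signal)
  out$excluded[no_od] <- TRUE
  out$exclusion_reason[no_od] <- "no_od"
  out$excluded[missing_strain] <- TRUE
  out$exclusion_reason[missing_strain] <- "missing_strain"
  sel <- too_few & !out$excluded
  out$excluded[sel] <- TRUE
  out$exclusion_reason[sel] <- "too_few_replicates"

  for (b in unique(out$bait_id)) {
    elig <- which(out$bait_id == b & !out$excluded)
    a <- out$aggregate_signal[elig]
    if (length(elig) < min_group) {
      warning(sprintf("bait %s: only %d eligible sets; Z-score exclusion skipped",
                      b, length(elig)))
      next
    }
    s <- sum(a); s2 <- sum(a^2); n <- length(a)
    loo_mean <- (s - a) / (n - 1)
    loo_var <- pmax((s2 - a^2 - (n - 1) * loo_mean^2) / (n - 2), 0)
    z <- (a - loo_mean) / sqrt(loo_var)
    out$membrane_z[elig] <- z
    low <- elig[z < -z_threshold]
    out$excluded[low] <- TRUE
    out$exclusion_reason[low] <- "low_z"
  }
  out$sd_flag <- !is.na(out$replicate_sd) &
    out$replicate_sd > sd_flag_threshold
  out
}

#' Call the interaction preference of one prey between two baits
#'
#' Implements the twofold rule: a prey has a preference when its
#' normalized signal with one bait exceeds the other by a fold change
#' strictly greater than `preference_threshold`.  Signals below the
#' detection floor for both baits mean no interaction; when only one bait
#' is above the floor, the fold change is computed against the floor (the
#' other signal is indistinguishable from background) and the same strict
#' rule applies.  Fold change is the symmetric `max/min` form so the
#' threshold acts identically in both directions.
#'
#' @param signal_A,signal_B QC-passing aggregate normalized signals
#'   (vectorized; NA = that side excluded).
#' @param preference_threshold Strict fold-change cutoff (default 2).
#' @param detection_floor Normalized-signal floor(s): a single value or
#'   `c(A =, B =)` per-bait floors.
#' @return Data frame `signal_A, signal_B, fold_change, category`
#'   (`fold_change` NA when undefined).
#' @export
call_preference <- function(signal_A, signal_B, preference_threshold = 2,
                            detection_floor) {
  if (any(signal_A < 0, na.rm = TRUE) || any(signal_B < 0, na.rm = TRUE))
    stop("aggregate signals must be >= 0")
  fl <- if (length(detection_floor) == 2L)
    c(detection_floor[["A"]], detection_floor[["B"]])
  else rep(detection_floor, 2L)
  n <- max(length(signal_A), length(signal_B))
  signal_A <- rep_len(signal_A, n); signal_B <- rep_len(signal_B, n)
  category <- character(n)
  fold_change <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- signal_A[i]; b <- signal_B[i]
    if (is.na(a) || is.na(b)) { category[i] <- "excluded"; next }
    above_a <- a > fl[1L]; above_b <- b > fl[2L]
    if (!above_a && !above_b) { category[i] <- "no_interaction"; next }
    if (above_a && above_b) {
      fc <- max(a, b) / min(a, b)
      fold_change[i] <- fc
      category[i] <- if (fc > preference_threshold) {
        if (a > b) "prefers_A" else "prefers_B"
      } else "both"
    } else {
      # one side at background: fold change against its detection floor
      fc <- if (above_a) a / fl[1L] else b / fl[2L]
      fold_change[i] <- fc
      category[i] <- if (fc > preference_threshold) {
        if (above_a) "prefers_A" else "prefers_B"
      } else "both"
    }
  }
  data.frame(signal_A = signal_A, signal_B = signal_B,
             fold_change = fold_change,
             category = factor(category, levels = preference_categories()),
             stringsAsFactors = FALSE)
}

#' Detection floor from on-membrane blank positions
#'
#' Estimates, per bait, the normalized-signal level an empty position
#' produces: the 95th percentile of background-corrected signal-channel
#' intensities at unmapped grid positions, divided by the median
#' corrected loading control of mapped dots of the same bait.  Both
#' numerator and denominator come from the same membranes, so rescaling
#' either channel rescales the floor identically and category calls are
#' scale-invariant.
#'
#' @param dots Combined dot measurements with `membrane_id` (see
#'   [quantify_membranes()]).
#' @param plate_map Plate map covering the same membranes.
#' @param q Quantile of empty-position intensities (default 0.95).
#' @return Named numeric vector of floors, one per bait.
#' @export
detection_floor_auto <- function(dots, plate_map, q = 0.95) {
  mem_bait <- unique(plate_map[, c("membrane_id", "bait_id")])
  key_d <- paste(dots$membrane_id, dots$row, dots$col)
  key_m <- paste(plate_map$membrane_id, plate_map$row, plate_map$col)
  occupied <- key_d %in% key_m
  bait_of <- mem_bait$bait_id[match(dots$membrane_id, mem_bait$membrane_id)]
  floors <- vapply(sort(unique(mem_bait$bait_id)), function(b) {
    emp <- dots$signal_corrected[!occupied & bait_of == b]
    occ <- dots$control_corrected[occupied & bait_of == b]
    if (length(emp) == 0L)
      stop("no empty grid positions for bait ", b,
           ": supply a numeric detection_floor instead")
    as.numeric(stats::quantile(emp, q) / stats::median(occ))
  }, 0)
  floors
}

#' Pair the two baits' sets and call every prey's preference
#'
#' @param sets Output of [apply_exclusions()] covering both baits.
#' @param preference_threshold,detection_floor Passed to
#'   [call_preference()]; `detection_floor` may be a single ratio or a
#'   named per-bait vector (e.g. from [detection_floor_auto()]).
#' @param baits Two bait identifiers, in (A, B) order; defaults to the
#'   sorted unique baits present.
#' @return Data frame, one row per prey: `prey_id, signal_A, signal_B,
#'   fold_change, category, exclusion_reason, replicate_sd_A,
#'   replicate_sd_B`.
#' @export
call_preferences <- function(sets, preference_threshold = 2,
                             detection_floor, baits = NULL) {
  if (is.null(baits)) baits <- sort(unique(sets$bait_id))
  stopifnot(length(baits) == 2L)
  sa <- sets[sets$bait_id == baits[1L], , drop = FALSE]
  sb <- sets[sets$bait_id == baits[2L], , drop = FALSE]
  preys <- sort(union(sa$prey_id, sb$prey_id))
  ia <- match(preys, sa$prey_id); ib <- match(preys, sb$prey_id)
  agg_a <- sa$aggregate_signal[ia]; agg_b <- sb$aggregate_signal[ib]
  exc_a <- sa$excluded[ia]; exc_b <- sb$excluded[ib]
  agg_a[is.na(ia) | exc_a] <- NA; agg_b[is.na(ib) | exc_b] <- NA
  fl <- if (length(detection_floor) == 2L && !is.null(names(detection_floor)))
    c(A = unname(detection_floor[[baits[1L]]]),
      B = unname(detection_floor[[baits[2L]]]))
  else detection_floor
  called <- call_preference(agg_a, agg_b, preference_threshold, fl)
  reason <- ifelse(!is.na(ia) & !is.na(sa$exclusion_reason[ia]),
                   paste0(baits[1L], ":", sa$exclusion_reason[ia]), NA)
  reason_b <- ifelse(!is.na(ib) & !is.na(sb$exclusion_reason[ib]),
                     paste0(baits[2L], ":", sb$exclusion_reason[ib]), NA)
  reason <- ifelse(is.na(reason), reason_b,
                   ifelse(is.na(reason_b), reason,
                          paste(reason, reason_b, sep = ";")))
  data.frame(prey_id = preys, called,
             exclusion_reason = reason,
             replicate_sd_A = sa$replicate_sd[ia],
             replicate_sd_B = sb$replicate_sd[ib],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Category counts of a screen
#'
#' @param pairs Data frame from [call_preferences()], one row per prey.
#' @return Data frame `category, n`; counts over the five categories sum
#'   to the number of preys.
#' @export
summarize_screen <- function(pairs) {
  if (anyDuplicated(pairs$prey_id))
    stop("duplicate prey_id in preference pairs: ",
         paste(unique(pairs$prey_id[duplicated(pairs$prey_id)]),
               collapse = ", "))
  tab <- table(factor(pairs$category, levels = preference_categories()))
  data.frame(category = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Screen-level reproducibility and QC report
#'
#' @param sets Output of [apply_exclusions()].
#' @return List: `exclusions` (counts by reason), `n_sd_flagged`,
#'   `replicate_sd_summary` (quantiles of replicate SD among included
#'   sets), `max_replicate_sd`.
#' @export
qc_report <- function(sets) {
  inc <- sets[!sets$excluded, , drop = FALSE]
  list(exclusions = table(sets$exclusion_reason[sets$excluded]),
       n_excluded = sum(sets$excluded),
       n_sd_flagged = sum(sets$sd_flag, na.rm = TRUE),
       replicate_sd_summary = stats::quantile(inc$replicate_sd,
                                              c(0, 0.5, 0.95, 1),
                                              na.rm = TRUE),
       max_replicate_sd = suppressWarnings(max(inc$replicate_sd,
                                               na.rm = TRUE)))
}
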