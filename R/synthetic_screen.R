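#' Configuration for a synthetic proximity-biotinylation screen
#'
#' Bundles and validates all parameters of the synthetic screen generator.
#' The defaults reproduce the geometry and replicate design of the assay
#' the package analyses: a 32 x 48 = 1,536 dot array pinned from
#' 384-position source plates, two BirA-tagged baits, three biological
#' replicates each blotted with three technical replicates (nine
#' measurements per bait-prey set).
#'
#' Two placement layouts are supported.  `"quadrant"` (default) follows
#' the 384 -> 1,536 pinning convention: each prey occupies adjacent
#' positions of one 2 x 2 quadrant block, technical replicates filling the
#' first `n_tech_reps` positions and the remainder left empty (capacity:
#' one prey per block).  The empty quadrant positions double as on-membrane
#' blanks from which the detection floor can be estimated.  `"rowmajor"`
#' packs replicates into consecutive row-major positions and can fill the
#' whole grid (capacity `grid_rows * grid_cols / n_tech_reps` preys).
#'
#' @param n_preys Number of prey strains.
#' @param grid_rows,grid_cols Array dimensions (default 32 x 48).
#' @param n_bio_reps,n_tech_reps Biological replicates (one membrane each)
#'   and technical replicates per membrane (defaults 3 and 3).
#' @param category_fractions Named proportions over
#'   `c(null, equal, prefers_A, prefers_B)` summing to 1.
#' @param true_fold_change Planted signal ratio between the preferred and
#'   the other bait for preferring preys (> 1 whenever a preferring
#'   fraction is nonzero; >= 1 otherwise).
#' @param base_signal Planted interaction strength (integrated counts at
#'   unit load) of an interacting prey with its preferred or equal bait.
#' @param control_scale Integrated loading-control counts at unit load.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   lognormal noise applied independently to per-dot load and signal.
#' @param background_level Constant background, counts.
#' @param background_gradient Planar background slope, counts per pixel
#'   (applied along x, and at half strength along y).
#' @param read_noise_sd Per-pixel additive Gaussian noise SD, counts.
#' @param dot_sigma_px Gaussian spot SD in pixels; spots are truncated at
#'   3 sigma.
#' @param dot_spacing_px Center-to-center dot spacing in pixels.
#' @param margin_px Margin between the image border and the first dot
#'   center.
#' @param rotation_deg Rotation of the printed lattice about the image
#'   center, degrees.
#' @param missing_strain_fraction Fraction of bait-prey strains absent
#'   from the plate (near-zero pre-lysis OD and near-zero protein load).
#' @param dropout_fraction Fraction of bait-prey sets whose signal-channel
#'   dots are planted at an extreme low (membrane transfer dropout).
#' @param dropout_factor Multiplier applied to dropout signals.
#' @param missing_load Relative protein load of a missing strain.
#' @param layout `"quadrant"` or `"rowmajor"` (see Details).
#' @param bait_ids Two bait labels (default `c("A", "B")`).
#' @param seed Integer seed; identical configurations generate
#'   byte-identical screens.
#' @return Validated object of class `screen_config`.
#' @export
screen_config <- function(n_preys = 384L,
                          grid_rows = 32L, grid_cols = 48L,
                          n_bio_reps = 3L, n_tech_reps = 3L,
                          category_fractions = c(null = 0.5, equal = 0.3,
                                                 prefers_A = 0.1,
                                                 prefers_B = 0.1),
                          true_fold_change = 4,
                          base_signal = 20000,
                          control_scale = 20000,
                          replicate_cv = 0.1,
                          background_level = 500,
                          background_gradient = 0.2,
                          read_noise_sd = 5,
                          dot_sigma_px = 1.5,
                          dot_spacing_px = 12L,
                          margin_px = 24L,
                          rotation_deg = 0,
                          missing_strain_fraction = 0.02,
                          dropout_fraction = 0.01,
                          dropout_factor = 0.001,
                          missing_load = 0.01,
                          layout = c("quadrant", "rowmajor"),
                          bait_ids = c("A", "B"),
                          seed = 1L) {
  layout <- match.arg(layout)
  cfg <- list(n_preys = as.integer(n_preys),
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              n_bio_reps = as.integer(n_bio_reps),
              n_tech_reps = as.integer(n_tech_reps),
              category_fractions = category_fractions,
              true_fold_change = true_fold_change,
              base_signal = base_signal, control_scale = control_scale,
              replicate_cv = replicate_cv,
              background_level = background_level,
              background_gradient = background_gradient,
              read_noise_sd = read_noise_sd,
              dot_sigma_px = dot_sigma_px,
              dot_spacing_px = as.numeric(dot_spacing_px),
              margin_px = as.numeric(margin_px),
              rotation_deg = rotation_deg,
              missing_strain_fraction = missing_strain_fraction,
              dropout_fraction = dropout_fraction,
              dropout_factor = dropout_factor,
              missing_load = missing_load,
              layout = layout, bait_ids = as.character(bait_ids),
              seed = as.integer(seed))
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

category_levels <- function() c("null", "equal", "prefers_A", "prefers_B")

validate_screen_config <- function(cfg) {
  fr <- cfg$category_fractions
  if (!all(category_levels() %in% names(fr)))
    stop("category_fractions must be named over null/equal/prefers_A/prefers_B")
  fr <- fr[category_levels()]
  if (abs(sum(fr) - 1) > 1e-9)
    stop("category_fractions must sum to 1 (got ", sum(fr), ")")
  if (any(fr < 0)) stop("category_fractions must be nonnegative")
  if (cfg$true_fold_change < 1 ||
      (cfg$true_fold_change <= 1 && sum(fr[c("prefers_A", "prefers_B")]) > 0))
    stop("true_fold_change must be > 1 when preferring categories are planted")
  noise <- c(cfg$replicate_cv, cfg$background_level, cfg$background_gradient,
             cfg$read_noise_sd)
  if (any(noise < 0)) stop("noise parameters must be >= 0")
  if (cfg$n_preys < 1L) stop("n_preys must be >= 1")
  if (length(cfg$bait_ids) != 2L || anyDuplicated(cfg$bait_ids))
    stop("exactly two distinct bait_ids are required")
  cap <- grid_capacity(cfg)
  if (cfg$n_preys > cap)
    stop(sprintf("capacity exceeded: %d preys > %d positions available (%s layout, %d x %d grid, %d technical replicates)",
                 cfg$n_preys, cap, cfg$layout, cfg$grid_rows, cfg$grid_cols,
                 cfg$n_tech_reps))
  invisible(cfg)
}

grid_capacity <- function(cfg) {
  if (cfg$layout == "quadrant") {
    if (cfg$n_tech_reps > 4L)
      stop("quadrant layout holds at most 4 technical replicates per block")
    (cfg$grid_rows %/% 2L) * (cfg$grid_cols %/% 2L)
  } else {
    (cfg$grid_rows * cfg$grid_cols) %/% cfg$n_tech_reps
  }
}

# lognormal multiplicative noise with mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# grid positions (row, col) for prey x technical replicate, fixed across
# membranes (the pinning robot revisits the same source wells)
assign_positions <- function(cfg, prey_order) {
  n <- cfg$n_preys; tr <- cfg$n_tech_reps
  if (cfg$layout == "quadrant") {
    half_cols <- cfg$grid_cols %/% 2L
    block <- seq_len(n)                       # one block per prey
    br <- (block - 1L) %/% half_cols          # 0-based block row
    bc <- (block - 1L) %% half_cols           # 0-based block col
    offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))[seq_len(tr)]
    do.call(rbind, lapply(seq_len(tr), function(t) {
      data.frame(prey_id = prey_order,
                 tech_rep = t,
                 row = 2L * br + offs[[t]][1L] + 1L,
                 col = 2L * bc + offs[[t]][2L] + 1L,
                 stringsAsFactors = FALSE)
    }))
  } else {
    idx <- seq_len(n * tr) - 1L               # consecutive row-major slots
    data.frame(prey_id = rep(prey_order, each = tr),
               tech_rep = rep(seq_len(tr), times = n),
               row = idx %/% cfg$grid_cols + 1L,
               col = idx %% cfg$grid_cols + 1L,
               stringsAsFactors = FALSE)
  }
}

# nominal dot centers in pixel coordinates (x = column axis, y = row axis),
# rotated about the image center
dot_centers <- function(cfg, row, col) {
  w <- cfg$margin_px * 2 + (cfg$grid_cols - 1) * cfg$dot_spacing_px + 1
  h <- cfg$margin_px * 2 + (cfg$grid_rows - 1) * cfg$dot_spacing_px + 1
  x0 <- cfg$margin_px + (col - 1) * cfg$dot_spacing_px + 1
  y0 <- cfg$margin_px + (row - 1) * cfg$dot_spacing_px + 1
  th <- cfg$rotation_deg * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  list(x = cx + cos(th) * (x0 - cx) - sin(th) * (y0 - cy),
       y = cy + sin(th) * (x0 - cx) + cos(th) * (y0 - cy),
       width = w, height = h)
}

# add a 2-D Gaussian spot, truncated at 3 sigma and renormalized so the
# rendered pixel sum equals `amp` exactly
add_spot <- function(img, cx, cy, amp, sigma) {
  r <- 3 * sigma
  px <- seq.int(max(1L, ceiling(cx - r)), min(ncol(img), floor(cx + r)))
  py <- seq.int(max(1L, ceiling(cy - r)), min(nrow(img), floor(cy + r)))
  d2 <- outer((py - cy)^2, (px - cx)^2, `+`)
  k <- exp(-d2 / (2 * sigma^2))
  k[d2 > r^2] <- 0
  k <- k / sum(k)
  img[py, px] <- img[py, px] + amp * k
  img
}

#' Generate a complete synthetic screen with planted ground truth
#'
#' Produces two-channel membrane images (streptavidin signal and anti-H3
#' loading control), the plate maps linking grid positions to bait, prey
#' and replicate, a pre-lysis OD table, and the planted ground truth.  One
#' membrane is generated per bait and biological replicate; each carries
#' `n_tech_reps` dots per prey at fixed positions.
#'
#' Signal model, per dot: the loading-control integrated intensity is
#' `control_scale * load` and the signal integrated intensity is
#' `true_signal * load * e`, where `load` and `e` are independent
#' lognormal factors with mean 1 and CV `replicate_cv` (`load` is shared
#' between the channels of a dot, as both see the same spotted material).
#' Missing strains have `load` scaled to `missing_load`; planted dropout
#' sets have their signal multiplied by `dropout_factor`.  Spots are
#' rendered as 2-D Gaussians truncated at 3 sigma on a planar background,
#' with optional per-pixel Gaussian read noise, and quantized to 16-bit
#' counts.
#'
#' @param config A [screen_config()].
#' @return List of class `synthetic_screen`:
#' \describe{
#'   \item{images}{named list (one per membrane) of
#'     `list(signal =, control =)` integer matrices.}
#'   \item{plate_map}{data frame `membrane_id, row, col, bait_id, prey_id,
#'     bio_rep, tech_rep` (1-based indices).}
#'   \item{od_table}{data frame `strain_id, od600`, one row per bait-prey
#'     strain (`strain_id = "<bait>:<prey>"`).}
#'   \item{truth}{list with `preys` (prey-level categories and planted
#'     signals per bait), `strains` (bait-prey level: `true_signal`,
#'     `is_missing_strain`, `dropout`), and `dots` (per-dot planted
#'     integrated intensities after multiplicative noise -- the oracle for
#'     quantification accuracy).}
#'   \item{config}{the configuration used.}
#' }
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  validate_screen_config(config)
  cfg <- config
  set.seed(cfg$seed)

  preys <- sprintf("P%04d", seq_len(cfg$n_preys))
  fr <- cfg$category_fractions[category_levels()]
  counts <- round(fr * cfg$n_preys)
  # fix rounding drift on the largest class so counts sum to n_preys
  counts[which.max(counts)] <- counts[which.max(counts)] +
    (cfg$n_preys - sum(counts))
  category <- sample(rep(category_levels(), times = counts))
  fc <- cfg$true_fold_change; s0 <- cfg$base_signal
  sig_A <- ifelse(category == "null", 0,
           ifelse(category == "prefers_B", s0 / fc, s0))
  sig_B <- ifelse(category == "null", 0,
           ifelse(category == "prefers_A", s0 / fc, s0))
  truth_preys <- data.frame(prey_id = preys, category = category,
                            true_signal_A = sig_A, true_signal_B = sig_B,
                            stringsAsFactors = FALSE)

  baits <- cfg$bait_ids
  strains <- data.frame(bait_id = rep(baits, each = cfg$n_preys),
                        prey_id = rep(preys, 2L),
                        true_signal = c(sig_A, sig_B),
                        stringsAsFactors = FALSE)
  ns <- nrow(strains)
  strains$is_missing_strain <-
    seq_len(ns) %in% sample.int(ns, round(cfg$missing_strain_fraction * ns))
  strains$dropout <- FALSE
  pool <- which(!strains$is_missing_strain)
  ndrop <- round(cfg$dropout_fraction * ns)
  if (ndrop > 0L)
    strains$dropout[sample(pool, min(ndrop, length(pool)))] <- TRUE
  strains$strain_id <- paste(strains$bait_id, strains$prey_id, sep = ":")

  od_table <- data.frame(strain_id = strains$strain_id,
                         od600 = round(ifelse(strains$is_missing_strain,
                                        stats::runif(ns, 0.005, 0.03),
                                        pmax(stats::rnorm(ns, 1.2, 0.15), 0.3)),
                                       4),
                         stringsAsFactors = FALSE)

  prey_order <- sample(preys)                 # plate scrambling, fixed per screen
  pos <- assign_positions(cfg, prey_order)
  pos <- pos[order(pos$row, pos$col), , drop = FALSE]

  images <- list()
  plate_rows <- list()
  dot_rows <- list()
  geo <- dot_centers(cfg, pos$row, pos$col)
  xg <- seq_len(geo$width); yg <- seq_len(geo$height)
  background <- cfg$background_level +
    outer(yg - 1, xg - 1, function(y, x)
      cfg$background_gradient * x + 0.5 * cfg$background_gradient * y)

  for (bait in baits) {
    st <- strains[strains$bait_id == bait, , drop = FALSE]
    st_idx <- match(pos$prey_id, st$prey_id)
    for (br in seq_len(cfg$n_bio_reps)) {
      mid <- sprintf("%s_b%d", bait, br)
      load <- ifelse(st$is_missing_strain[st_idx], cfg$missing_load, 1) *
        rlnorm_cv(nrow(pos), cfg$replicate_cv)
      e <- rlnorm_cv(nrow(pos), cfg$replicate_cv)
      sig_int <- st$true_signal[st_idx] * load * e *
        ifelse(st$dropout[st_idx], cfg$dropout_factor, 1)
      ctl_int <- cfg$control_scale * load
      sig_img <- matrix(0, geo$height, geo$width)
      ctl_img <- matrix(0, geo$height, geo$width)
      for (i in seq_len(nrow(pos))) {
        if (sig_int[i] > 0)
          sig_img <- add_spot(sig_img, geo$x[i], geo$y[i], sig_int[i],
                              cfg$dot_sigma_px)
        ctl_img <- add_spot(ctl_img, geo$x[i], geo$y[i], ctl_int[i],
                            cfg$dot_sigma_px)
      }
      sig_img <- sig_img + background
      ctl_img <- ctl_img + background
      if (cfg$read_noise_sd > 0) {
        sig_img <- sig_img + stats::rnorm(length(sig_img), 0, cfg$read_noise_sd)
        ctl_img <- ctl_img + stats::rnorm(length(ctl_img), 0, cfg$read_noise_sd)
      }
      images[[mid]] <- list(
        signal = matrix(as.integer(pmin(pmax(round(sig_img), 0), 65535)),
                        geo$height, geo$width),
        control = matrix(as.integer(pmin(pmax(round(ctl_img), 0), 65535)),
                         geo$height, geo$width))
      plate_rows[[mid]] <- data.frame(membrane_id = mid, row = pos$row,
                                      col = pos$col, bait_id = bait,
                                      prey_id = pos$prey_id, bio_rep = br,
                                      tech_rep = pos$tech_rep,
                                      stringsAsFactors = FALSE)
      dot_rows[[mid]] <- data.frame(membrane_id = mid, row = pos$row,
                                    col = pos$col, prey_id = pos$prey_id,
                                    signal_integrated = sig_int,
                                    control_integrated = ctl_int,
                                    stringsAsFactors = FALSE)
    }
  }

  structure(list(images = images,
                 plate_map = do.call(rbind, c(plate_rows,
                                              make.row.names = FALSE)),
                 od_table = od_table,
                 truth = list(preys = truth_preys,
                              strains = strains[, c("bait_id", "prey_id",
                                                    "strain_id", "true_signal",
                                                    "is_missing_strain",
                                                    "dropout")],
                              dots = do.call(rbind, c(dot_rows,
                                                      make.row.names = FALSE))),
                 config = cfg),
            class = "synthetic_screen")
}

#' Generate labelled synthetic signal-peptide sets
#'
#' Draws groups of amino-acid sequences whose expected Kyte-Doolittle
#' hydropathy at each position matches a per-position target profile.  At
#' each position the residue is sampled from the two scale values
#' bracketing the target, with mixing weights chosen so the expected
#' hydropathy equals the target exactly; residues sharing a scale value
#' are chosen uniformly.  A target of 4.5 therefore yields Ile at every
#' draw, and group profile means converge to their targets as
#' `n_per_group` grows.
#'
#' @param n_per_group Sequences per group.
#' @param length Sequence length (>= 1).
#' @param group_profiles Named list of numeric target-mean vectors, one
#'   per group; each value must lie in `[-4.5, 4.5]`.  Vectors shorter
#'   than `length` are recycled from their last value.
#' @param seed Integer seed.
#' @return Named list of character vectors of sequences, one per group;
#'   sequence names are `<group>_<i>`.
#' @export
generate_sp_set <- function(n_per_group, length, group_profiles, seed = 1L) {
  if (length < 1L) stop("'length' must be >= 1")
  if (n_per_group < 1L) stop("'n_per_group' must be >= 1")
  if (is.null(names(group_profiles)) || any(names(group_profiles) == ""))
    stop("'group_profiles' must be a named list")
  rng <- range(kd_scale)
  set.seed(as.integer(seed))
  vals <- sort(unique(kd_scale))
  by_val <- split(names(kd_scale), kd_scale)[as.character(vals)]
  draw_residue <- function(target, n) {
    i <- findInterval(target, vals, rightmost.closed = TRUE)
    lo <- vals[i]; hi <- vals[min(i + 1L, length(vals))]
    p_hi <- if (hi > lo) (target - lo) / (hi - lo) else 0
    pick_hi <- stats::runif(n) < p_hi
    res <- character(n)
    res[pick_hi] <- sample(by_val[[as.character(hi)]], sum(pick_hi),
                           replace = TRUE)
    res[!pick_hi] <- sample(by_val[[as.character(lo)]], sum(!pick_hi),
                            replace = TRUE)
    res
  }
  out <- lapply(names(group_profiles), function(g) {
    prof <- group_profiles[[g]]
    if (any(prof < rng[1] | prof > rng[2]))
      stop(sprintf("group '%s': target mean outside the hydropathy scale range [%g, %g]",
                   g, rng[1], rng[2]))
    prof <- c(prof, rep(prof[base::length(prof)],
                        max(0L, length - base::length(prof))))[seq_len(length)]
    mat <- vapply(seq_len(length),
                  function(p) draw_residue(prof[p], n_per_group),
                  character(n_per_group))
    seqs <- if (n_per_group == 1L) paste(mat, collapse = "") else
      apply(matrix(mat, nrow = n_per_group), 1L, paste, collapse = "")
    stats::setNames(seqs, sprintf("%s_%d", g, seq_len(n_per_group)))
  })
  stats::setNames(out, names(group_profiles))
}
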