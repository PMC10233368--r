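# Shared fixtures: small synthetic screens built in code.

# 16 x 24 grid, 96 preys in quadrant blocks -- fast enough for unit tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_preys = 96L, grid_rows = 16L, grid_cols = 24L,
                   seed = 101L)
  do.call(screen_config, utils::modifyList(defaults, args))
}

# noise-free variant: no replicate noise, no read noise, no artifacts
clean_config <- function(...) {
  tiny_config(replicate_cv = 0, read_noise_sd = 0,
              missing_strain_fraction = 0, dropout_fraction = 0, ...)
}

# independent leave-one-out Z oracle: plain loop, one value at a time
loo_z_oracle <- function(x) {
  vapply(seq_along(x), function(i) {
    rest <- x[-i]
    (x[i] - mean(rest)) / stats::sd(rest)
  }, 0)
}

# planted dot centers recomputed from first principles (margin + spacing,
# rotated about the image center), independent of grid_centers()
planted_centers <- function(cfg, row, col) {
  w <- cfg$margin_px * 2 + (cfg$grid_cols - 1) * cfg$dot_spacing_px + 1
  h <- cfg$margin_px * 2 + (cfg$grid_rows - 1) * cfg$dot_spacing_px + 1
  x0 <- cfg$margin_px + (col - 1) * cfg$dot_spacing_px + 1
  y0 <- cfg$margin_px + (row - 1) * cfg$dot_spacing_px + 1
  th <- cfg$rotation_deg * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  list(x = cx + cos(th) * (x0 - cx) - sin(th) * (y0 - cy),
       y = cy + sin(th) * (x0 - cx) + cos(th) * (y0 - cy))
}

# match quantified dots to the generator's per-dot truth for one membrane
match_truth <- function(dots, truth_dots, membrane_id) {
  tr <- truth_dots[truth_dots$membrane_id == membrane_id, , drop = FALSE]
  d <- dots[dots$membrane_id == membrane_id | is.null(dots$membrane_id), ,
            drop = FALSE]
  idx <- match(paste(tr$row, tr$col), paste(d$row, d$col))
  cbind(tr, d[idx, c("signal_corrected", "control_corrected"),
              drop = FALSE])
}
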