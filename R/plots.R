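# Report figures: the combined grayscale sensitivity / color-coded
# total-deviation composite, and the three-panel progression (PLR/PoPLR)
# report. Both draw one Voronoi tile per test location so regular and
# irregular grids render identically. Figures are deterministic artifacts
# of record: no RNG is used.

# Probability-category border palette (stable across releases; documented
# in the methods vignette).
category_colors <- c("<0.5%" = "#d7191c", "<1%" = "#fdae61",
                     "<2%" = "#a6d96a", "<5%" = "#2b83ba")

#' Grayscale fill for a sensitivity value
#'
#' Linear map of the dB dynamic range onto gray levels: the floor renders
#' black, the ceiling white; monotone non-decreasing in sensitivity.
#'
#' @param db sensitivity values (dB); `NA` gives `NA` (unfilled tile).
#' @param floor_db,ceiling_db the dB dynamic range.
#' @return vector of colors.
#' @export
gray_from_db <- function(db, floor_db = 0, ceiling_db = 40) {
  g <- clamp((db - floor_db) / (ceiling_db - floor_db), 0, 1)
  ifelse(is.na(db), NA_character_, grDevices::gray(ifelse(is.na(g), 0, g)))
}

draw_tiles <- function(tess, fill, border_col, lwd = 2) {
  for (i in seq_along(tess$polygons)) {
    poly <- tess$polygons[[i]]
    if (nrow(poly) < 3) next
    graphics::polygon(poly[, 1], poly[, 2],
                      col = fill[i], border = "gray60", lwd = 0.5)
    if (!is.na(border_col[i]))
      graphics::polygon(poly[, 1], poly[, 2], col = NA,
                        border = border_col[i], lwd = lwd)
  }
}

open_device <- function(out_path, width, height) {
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") grDevices::svg(out_path, width = width, height = height)
  else grDevices::png(out_path, width = width * 100, height = height * 100,
                      res = 100)
}

#' Composite sensitivity / total-deviation map
#'
#' One Voronoi tile per location: the fill is a grayscale of the estimated
#' sensitivity (darker = lower), the printed number is the total deviation
#' rounded to an integer, and the tile border is colored by the TD
#' probability category (no border when normal). Blind-spot tiles are
#' rendered unfilled and carry no number.
#'
#' @param field a one-row `vf` table.
#' @param deviation a `deviation_map` from [analyze_field()].
#' @param tess a `vf_tessellation` of the field's grid.
#' @param out_path output file (`.png` or `.svg`).
#' @param floor_db,ceiling_db dB range for the grayscale.
#' @return `out_path`, invisibly.
#' @export
plot_field_composite <- function(field, deviation, tess, out_path,
                                 floor_db = 0, ceiling_db = 40) {
  stopifnot(nrow(field) == 1)
  sens <- vf_sens_matrix(field)[1, ]
  open_device(out_path, 8, 7)
  on.exit(grDevices::dev.off())
  composite_panel(sens, deviation$td, deviation$td_category, tess,
                  floor_db, ceiling_db,
                  main = sprintf("%s %s  age %.0f  MD %.1f dB",
                                 field$id[1], field$eye[1], field$age[1],
                                 deviation$md))
  invisible(out_path)
}

composite_panel <- function(sens, td, categories, tess, floor_db, ceiling_db,
                            main = "") {
  bb <- tess$clip_boundary
  graphics::plot(NA, xlim = range(bb[, 1]), ylim = range(bb[, 2]),
                 asp = 1, axes = FALSE, xlab = "x (degrees)",
                 ylab = "y (degrees)", main = main)
  fill <- gray_from_db(sens, floor_db, ceiling_db)
  border <- unname(category_colors[categories])
  draw_tiles(tess, fill, border)
  lab <- ifelse(is.na(td), "", sprintf("%d", round(td)))
  txt_col <- ifelse(!is.na(sens) & sens < (floor_db + ceiling_db) / 2,
                    "white", "black")
  graphics::text(tess$points[, 1], tess$points[, 2], lab, cex = 0.7,
                 col = txt_col)
  graphics::axis(1); graphics::axis(2)
}

#' Progression (PLR / PoPLR) report figure
#'
#' Three panels. Left: per-location slope tiles with sparklines of the
#' series values (drawn in red when the location's residual MAD exceeds the
#' variability threshold), tile borders colored by the one-sided slope
#' p-value category. Top right: composite of the baseline values (the
#' intercept of the pointwise regression on sensitivities). Bottom right:
#' histogram of the permutation S/n distribution with the observed S/n
#' marked and the combined p-value printed to three decimals.
#'
#' @param series the analyzed `vf` series (for the sparkline values).
#' @param result a [poplr()] result.
#' @param tess a `vf_tessellation` of the series' grid.
#' @param out_path output file (`.png` or `.svg`).
#' @param floor_db,ceiling_db dB range for the baseline grayscale.
#' @return `out_path`, invisibly.
#' @export
plot_progression_report <- function(series, result, tess, out_path,
                                    floor_db = 0, ceiling_db = 40) {
  trends <- result$trends
  open_device(out_path, 11, 6)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2, 1, 3), 2, 2), widths = c(1.5, 1))

  # p-value categories for slope tiles reuse the deviation category scale
  pcat <- rep(NA_character_, nrow(tess$points))
  pcut <- c(0.005, 0.01, 0.02, 0.05)
  plab <- names(category_colors)
  for (r in seq_len(nrow(trends))) {
    hit <- which(trends$p[r] < pcut)
    if (length(hit)) pcat[trends$location[r]] <- plab[hit[1]]
  }
  bb <- tess$clip_boundary
  graphics::plot(NA, xlim = range(bb[, 1]), ylim = range(bb[, 2]), asp = 1,
                 axes = FALSE, xlab = "x (degrees)", ylab = "y (degrees)",
                 main = "Pointwise linear regression (dB/year)")
  draw_tiles(tess, rep("white", nrow(tess$points)),
             unname(category_colors[pcat]))
  times <- attr(trends, "times")
  values <- attr(trends, "values")
  half <- min(stats::dist(tess$points)) * 0.38
  for (r in seq_len(nrow(trends))) {
    i <- trends$location[r]
    cx <- tess$points[i, 1]; cy <- tess$points[i, 2]
    v <- values[, r]
    vs <- (v - floor_db) / (ceiling_db - floor_db) - 0.5
    graphics::lines(cx - half + 2 * half * times / max(times),
                    cy + half * clamp(vs, -0.5, 0.5) * 1.2,
                    col = if (trends$flagged[r]) "red" else "gray30",
                    lwd = if (trends$flagged[r]) 1.6 else 0.8)
    graphics::text(cx, cy - half * 0.75, sprintf("%.1f", trends$slope[r]),
                   cex = 0.55)
  }

  base_sens <- plr_matrix(vf_sens_matrix(series)[, trends$location,
                                                 drop = FALSE],
                          times)$intercept
  base_full <- rep(NA_real_, nrow(tess$points))
  base_full[trends$location] <- base_sens
  composite_panel(base_full, rep(NA_real_, length(base_full)),
                  rep(NA_character_, length(base_full)), tess,
                  floor_db, ceiling_db, main = "Baseline (intercept, dB)")

  sn <- result$permutation_s / result$n_locations
  graphics::hist(sn, breaks = 30, col = "gray80", border = "white",
                 main = "Permutation S/n", xlab = "S/n",
                 xlim = range(c(sn, result$s_over_n)))
  graphics::abline(v = result$s_over_n, col = "red", lwd = 2)
  graphics::mtext(sprintf("observed S/n = %.3f, p = %.3f",
                          result$s_over_n, result$p_value),
                  side = 3, line = -1.5, cex = 0.8)
  invisible(out_path)
}
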