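#' Radial diagram of per-column relative connectivity
#'
#' One polygon per column over the retained targets, drawn on a radial grid
#' (relative connectivity 0 at the center, 1 at the rim).
#'
#' @param profiles data.frame from [column_profiles()] or the per-subject
#'   average (`column`, `target`, `relative`).
#' @param file optional output path (`.png` or `.svg`); `NULL` draws on the
#'   current device.
#' @param colors named vector of colors per column.
#' @return invisibly, the matrix of plotted values (columns x targets).
#' @export
radial_profile_plot <- function(profiles, file = NULL, colors = NULL) {
  cols <- unique(profiles$column)
  targets <- unique(profiles$target)
  m <- matrix(0, length(cols), length(targets),
              dimnames = list(cols, targets))
  m[cbind(match(profiles$column, cols), match(profiles$target, targets))] <-
    profiles$relative
  if (is.null(colors))
    colors <- setNames(grDevices::hcl.colors(length(cols), "Dark 3"), cols)
  open_dev <- !is.null(file)
  if (open_dev) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  nt <- length(targets)
  ang <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)] + pi / 2
  graphics::plot.new()
  graphics::plot.window(c(-1.4, 1.4), c(-1.4, 1.4), asp = 1)
  for (rr in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(rr * cos(seq(0, 2 * pi, length.out = 121)),
                      rr * sin(seq(0, 2 * pi, length.out = 121)),
                      border = "grey85")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey85")
  graphics::text(1.25 * cos(ang), 1.25 * sin(ang), targets, cex = 0.8)
  for (ci in seq_along(cols)) {
    r <- m[ci, ]
    graphics::polygon(r * cos(ang), r * sin(ang), border = colors[cols[ci]],
                      col = grDevices::adjustcolor(colors[cols[ci]], 0.2),
                      lwd = 2)
  }
  graphics::legend("topleft", legend = cols, col = colors[cols], lwd = 2,
                   bty = "n")
  invisible(m)
}
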