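#' Plot a flow trace
#'
#' Time-flow curve with phase markers.
#'
#' @param x a [flow_trace()]
#' @param ... passed to [graphics::plot()]
#' @export
plot.flow_trace <- function(x, ...) {
  graphics::plot(x$time_s / 60, x$flow, type = "l", col = "steelblue",
                 xlab = "time (min)", ylab = "flow (ml/min)",
                 main = x$animal_id, ...)
  for (m in names(x$markers))
    graphics::abline(v = x$markers[[m]] / 60, lty = 3, col = "grey40")
  invisible(x)
}

png_capability_check <- function() {
  ok <- isTRUE(capabilities("png")) || isTRUE(capabilities("cairo"))
  if (!ok)
    stop_with("thrombolyzer_capability_error",
              "no PNG graphics device available in this R build")
  invisible(TRUE)
}

#' Render study figures
#'
#' For each group, two figures in the style of the flow-monitoring panels:
#' a continuous bar graph of group minute means (mean +/- SD) and a
#' spaghetti plot of every animal's time-flow curve. Fails cleanly, writing
#' no files, if no PNG device is available.
#'
#' @param report a [run_study()] report
#' @param dir output directory
#' @return character vector of created files, invisibly
#' @export
plot_study <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (length(report$reports) == 0L)
    stop_with("thrombolyzer_invalid_input", "empty report")
  png_capability_check()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (g in unique(report$group)) {
    sel <- which(report$group == g)
    slug <- gsub("[^A-Za-z0-9]+", "-", g)

    mms <- lapply(report$reports[sel], function(r) r$minute_means)
    minutes <- sort(Reduce(intersect, lapply(mms, function(m) m$minute)))
    mat <- vapply(mms, function(m)
      m$flow_mean[match(minutes, m$minute)], numeric(length(minutes)))
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)

    f1 <- file.path(dir, paste0(slug, "_minute_bars.png"))
    grDevices::png(f1, width = 900, height = 420)
    graphics::barplot(mu, names.arg = minutes, border = NA,
                      col = "grey60", xlab = "minute from drug start",
                      ylab = "flow (ml/min)",
                      main = sprintf("%s: group minute means (mean +/- SD)", g))
    bp <- graphics::barplot(mu, plot = FALSE)
    ok <- !is.na(sdv) & sdv > 1e-3 * max(mu, 1e-12)
    if (any(ok))
      graphics::arrows(bp[ok], mu[ok] - sdv[ok], bp[ok], mu[ok] + sdv[ok],
                       angle = 90, code = 3, length = 0.02, col = "grey30")
    grDevices::dev.off()
    files <- c(files, f1)

    f2 <- file.path(dir, paste0(slug, "_timeflow.png"))
    grDevices::png(f2, width = 900, height = 420)
    graphics::matplot(minutes, mat, type = "l", lty = 1,
                      col = grDevices::hcl.colors(ncol(mat), "Dark 3"),
                      xlab = "minute from drug start", ylab = "flow (ml/min)",
                      main = sprintf("%s: per-animal time-flow curves", g))
    grDevices::dev.off()
    files <- c(files, f2)
  }
  invisible(files)
}
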