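#' Plot the stress-strain loops of a biaxial trace
#'
#' Overlays the loading/unloading loops of both axes, faceted by axis, for a
#' quick look at toe region, hysteresis and preconditioning.
#'
#' @param trace A `mech_trace`.
#' @return A ggplot object.
#' @export
plot_stress_strain <- function(trace) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_stress_strain() needs the ggplot2 package", call. = FALSE)
  }
  ss <- compute_stress_strain(trace)
  d <- rbind(
    data.frame(axis = "longitudinal (x)", strain = ss$x$strain,
               stress = ss$x$stress_MPa),
    data.frame(axis = "transverse (y)", strain = ss$y$strain,
               stress = ss$y$stress_MPa)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strain * 100, y = .data$stress)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.7) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "strain (%)", y = "nominal stress (MPa)",
                  title = trace$specimen_id) +
    ggplot2::theme_minimal()
}
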