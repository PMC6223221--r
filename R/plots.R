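#' Metagene profile over the twenty promoter bins
#'
#' Line plot of a per-bin quantity (mean CpG count, mean methylation or
#' correlation with expression) against the bin index, with the TSS marked
#' between bins -1 and 1.
#'
#' @param bin_values named numeric vector; names are bin indices.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted values.
#' @export
plot_bin_profile <- function(bin_values, ylab = "value", ...) {
  k <- as.integer(names(bin_values))
  ord <- order(k)
  x <- seq_along(k)
  graphics::plot(x, bin_values[ord], type = "b", xaxt = "n",
                 xlab = "promoter bin", ylab = ylab, ...)
  graphics::axis(1, at = x, labels = k[ord], las = 2, cex.axis = 0.7)
  graphics::abline(v = mean(x[which(k[ord] %in% c(-1L, 1L))]), lty = 2,
                   col = "grey50")
  invisible(bin_values[ord])
}
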