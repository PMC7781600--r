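# base-graphics figure helpers for the report bundle

#' Fitness time-course heat map
#'
#' @param timecourse Matrix from \code{\link{fitness_timecourse}} (sgRNAs x
#'   days).
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @return Invisibly, the row order used (rows sorted by final-day fitness).
#' @export
plot_fitness_heatmap <- function(timecourse, ...) {
  ord <- order(timecourse[, ncol(timecourse)])
  m <- timecourse[ord, , drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(51, "Blue-Red 2", rev = TRUE),
                  xlab = "day", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(ord)
}

#' Sorted-bin enrichment heat map with two-way clustering
#'
#' @param enrichment Matrix from \code{\link{bin_enrichment}}.
#' @param clustering Optional \code{\link{two_way_cluster}} output; computed
#'   when omitted.
#' @return Invisibly, the clustering used.
#' @export
plot_enrichment_heatmap <- function(enrichment, clustering = NULL) {
  clustering <- clustering %||% two_way_cluster(enrichment)
  m <- enrichment[clustering$row_order, clustering$col_order, drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(51, "Blue-Red 2", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(clustering)
}

#' Estimated-versus-observed fitness scatter
#'
#' @param observed Observed fitness vector (per guide).
#' @param result \code{deconvolution_result} (or estimated vector).
#' @return Invisibly, the \code{\link{consistency_report}} fit.
#' @export
plot_consistency <- function(observed, result) {
  est <- if (inherits(result, "deconvolution_result")) result$R else result
  fit <- consistency_report(observed, result)
  graphics::plot(as.numeric(observed), as.numeric(est),
                 xlab = "observed relative fitness (log2)",
                 ylab = "estimated real relative fitness (log2)",
                 pch = 19)
  graphics::abline(fit$intercept, fit$slope, col = "red3")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(fit)
}
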