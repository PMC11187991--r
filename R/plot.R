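#' Plot a community trajectory
#'
#' Quick base-graphics view of the log10 densities: phage solid, lysogens
#' dashed, one colour per immunity class.
#'
#' @param x A `phage_trajectory`.
#' @param what `"density"` plots log10 densities; `"ratio"` plots the
#'   log10 phage-to-lysogen ratio of each temperate strain, with the floor
#'   estimate `b*gamma/delta` as a dashed horizontal line.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.phage_trajectory <- function(x, what = c("density", "ratio"), ...) {
  what <- match.arg(what)
  tab <- x$config$strains
  ns <- x$config$n_strains
  if (what == "density") {
    m <- x$log_state[, seq_len(ns + x$config$n_lysogens),
                     drop = FALSE] / log(10)
    col <- tab$class
    lty <- c(rep(1, ns), rep(2, x$config$n_lysogens))
    col <- c(tab$class, tab$class[!is.na(tab$lysogen_index)])
    graphics::matplot(x$times, m, type = "l", lty = lty, col = col,
                      xlab = "time (generations)",
                      ylab = "log10 density", ...)
  } else {
    temperate <- which(!is.na(tab$lysogen_index))
    if (!length(temperate)) stop("no temperate strains to plot",
                                 call. = FALSE)
    r <- (x$log_state[, tab$phage_index[temperate], drop = FALSE] -
            x$log_state[, ns + tab$lysogen_index[temperate],
                        drop = FALSE]) / log(10)
    graphics::matplot(x$times, r, type = "l", lty = 1,
                      col = tab$class[temperate],
                      xlab = "time (generations)",
                      ylab = "log10 P/L", ...)
    graphics::abline(h = log10(homeostatic_ratio(x$params, 0)), lty = 2)
  }
  invisible(x)
}
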