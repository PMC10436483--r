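# condition helpers: every user-facing error carries a subclass so callers
# (and the CLI) can distinguish geometry failures from format problems or
# from the legitimate "no cluster signal" outcome

vcStop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("vc_", class, "_error"), "vc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

vcAssert <- function(cond, msg, class) {
  if (!isTRUE(cond)) vcStop(msg, class)
}

#' Default histogram breaks for normalized cell sizes
#'
#' 200 equal-width bins on the normalized-size interval \eqn{[0, 5]}, which
#' carries more than 99.99\% of the mass of both Poisson-Voronoi gamma
#' approximations.
#'
#' @return Numeric vector of 201 increasing bin edges.
#' @export
#' @examples
#' head(defaultBreaks())
defaultBreaks <- function() seq(0, 5, length.out = 201L)

binCenters <- function(breaks) (breaks[-1L] + breaks[-length(breaks)]) / 2
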