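#' A single dilution step
#'
#' Either a plain dilution factor (e.g. 500 for a 500-fold dilution) or a
#' transfer of `transfer_volume` into `receiving_volume`, which multiplies
#' the concentration by `transfer_volume / (transfer_volume +
#' receiving_volume)`. Volumes must share a unit; the result is
#' unit-agnostic.
#'
#' @param dilution_factor Dimensionless factor > 0; `1` leaves the
#'   concentration unchanged.
#' @param transfer_volume,receiving_volume Positive volumes (same unit).
#'   Supply either the factor or both volumes, not both.
#' @return An object of class `dilution_step`.
#' @export
#' @examples
#' dilution_step(dilution_factor = 500)
#' dilution_step(transfer_volume = 5, receiving_volume = 25)
dilution_step <- function(dilution_factor = NULL, transfer_volume = NULL,
                          receiving_volume = NULL) {
  by_factor <- !is.null(dilution_factor)
  by_volume <- !is.null(transfer_volume) || !is.null(receiving_volume)
  .check(xor(by_factor, by_volume),
         "give either dilution_factor or transfer/receiving volumes")
  if (by_factor) {
    .check(dilution_factor > 0, "dilution_factor must be > 0")
    step <- list(dilution_factor = dilution_factor)
  } else {
    .check(!is.null(transfer_volume) && !is.null(receiving_volume),
           "both transfer_volume and receiving_volume are required")
    .check(transfer_volume > 0 && receiving_volume > 0,
           "volumes must be > 0")
    step <- list(transfer_volume = transfer_volume,
                 receiving_volume = receiving_volume)
  }
  structure(step, class = "dilution_step")
}

#' Final concentration after sequential dilution steps
#'
#' Applies each step in order: a factor step divides the concentration by
#' its factor; a volume step multiplies by
#' `transfer / (transfer + receiving)`. This reproduces the screening
#' dilution scheme, e.g. a 10 mM stock diluted 500-fold and then added in
#' equal volume gives 10 uM, and 5 ul of a 150 uM working solution into
#' 25 ul of medium gives 25 uM.
#'
#' @param stock_concentration Starting concentration (any unit; the result
#'   keeps it).
#' @param steps A `dilution_step` or list of them.
#' @return Final concentration in the stock's unit.
#' @export
#' @examples
#' # 10 mM stock -> 500-fold dilution -> equal-volume addition = 0.01 mM (10 uM)
#' final_concentration(10, list(dilution_step(dilution_factor = 500),
#'                              dilution_step(transfer_volume = 1,
#'                                            receiving_volume = 1)))
final_concentration <- function(stock_concentration, steps) {
  .check(is.numeric(stock_concentration) && stock_concentration >= 0,
         "stock_concentration must be a non-negative number")
  if (inherits(steps, "dilution_step")) steps <- list(steps)
  .check(length(steps) >= 1 &&
           all(vapply(steps, inherits, logical(1), "dilution_step")),
         "steps must be dilution_step objects")
  conc <- stock_concentration
  for (s in steps) {
    conc <- if (!is.null(s$dilution_factor)) {
      conc / s$dilution_factor
    } else {
      conc * s$transfer_volume / (s$transfer_volume + s$receiving_volume)
    }
  }
  conc
}
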