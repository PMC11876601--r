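#' @include doseResponse.R
NULL

#' Z-prime plate-quality statistic
#'
#' \deqn{Z' = 1 - \frac{3 SD_{pos} + 3 SD_{neg}}{|mean_{pos} + mean_{neg}|}}
#' with sample standard deviations. `mode = "printed"` uses the sum of the
#' control means in the denominator; `mode = "standard"` uses the textbook
#' difference \eqn{|mean_{pos} - mean_{neg}|}. For luminescence viability
#' plates the positive controls (killed wells) read near zero, where both
#' forms agree; the printed form is the default.
#'
#' @param pos,neg Numeric control-well values, at least 2 each.
#' @param mode `"printed"` (default) or `"standard"`.
#' @return The Z-prime statistic (at most 1; 1 exactly when both SDs are 0).
#' @examples
#' zPrime(pos = c(0, 0, 0, 0), neg = c(100, 100, 90, 110))
#' @export
zPrime <- function(pos, neg, mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("zPrime() needs at least 2 finite values per control group")
  denom <- if (mode == "printed") abs(mean(pos) + mean(neg)) else
    abs(mean(pos) - mean(neg))
  if (denom == 0)
    stop("zPrime(): degenerate plate, control means cancel (denominator 0)")
  1 - (3 * stats::sd(pos) + 3 * stats::sd(neg)) / denom
}

#' Normalize plate signals to the vehicle controls
#'
#' Divides every well's raw signal by the mean negative-control (vehicle)
#' signal of its own plate and scales to percent, so a vehicle-level well
#' reads 100%. Control wells are retained with their normalized values.
#'
#' @param plate Data frame with at least columns `plate`, `role` and
#'   `signal`; `role` uses `"neg"` for vehicle wells, `"pos"` for kill
#'   controls and `"sample"` otherwise.
#' @return The input with a `response` column (percent of vehicle) added.
#' @examples
#' p <- data.frame(plate = "P1", role = c("neg", "neg", "sample"),
#'                 signal = c(2e6, 2e6, 1.1e6))
#' normalizeToVehicle(p)$response
#' @export
normalizeToVehicle <- function(plate) {
  stopifnot(all(c("plate", "role", "signal") %in% colnames(plate)))
  negMean <- tapply(plate$signal[plate$role == "neg"],
                    plate$plate[plate$role == "neg"], mean)
  missing <- setdiff(unique(plate$plate), names(negMean))
  if (length(missing))
    stop("plate(s) without negative controls: ",
         paste(missing, collapse = ", "))
  plate$response <- 100 * plate$signal / as.numeric(negMean[as.character(plate$plate)])
  plate
}

#' Per-plate quality-control table
#'
#' Computes control-well summary statistics and the Z-prime for every plate.
#'
#' @param plate Data frame as in [normalizeToVehicle()], with both `"pos"`
#'   and `"neg"` roles on every plate.
#' @param mode Z-prime denominator mode, see [zPrime()].
#' @return Data frame with one row per plate: control means/SDs and
#'   `z_prime`.
#' @export
plateQC <- function(plate, mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  ids <- unique(plate$plate)
  rows <- lapply(ids, function(p) {
    pos <- plate$signal[plate$plate == p & plate$role == "pos"]
    neg <- plate$signal[plate$plate == p & plate$role == "neg"]
    data.frame(plate = p,
               mean_pos = mean(pos), sd_pos = stats::sd(pos),
               mean_neg = mean(neg), sd_neg = stats::sd(neg),
               z_prime = zPrime(pos, neg, mode = mode))
  })
  do.call(rbind, rows)
}
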