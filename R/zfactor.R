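#' Z factor (screening-window coefficient) from control wells
#'
#' `z = 1 - 3 * (sd_pos + sd_neg) / |mu_pos - mu_neg|` with sample standard
#' deviations (n - 1 denominator), the standard assay-robustness statistic:
#' values above ~0.5 indicate a screening window well separated from control
#' noise; `z = 1` only for zero-variance, separated controls.
#'
#' @param pos,neg Numeric control values (>= 2 each); typically the
#'   positive-control and cell-control wells of one plate, or any two
#'   designated well sets (e.g. mutant- vs wild-type-expressing wells in the
#'   imaging arm).
#' @param plate_id Identifier carried into the result.
#' @return An object of class `zfactor_result`: list with `plate_id`,
#'   `mu_pos`, `mu_neg`, `sd_pos`, `sd_neg`, `z`.
#' @export
#' @examples
#' z_factor(c(8, 12), c(-2, 2))$z  # 1 - 3 * 5.657 / 10 = -0.697
z_factor <- function(pos, neg, plate_id = NA_character_) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  .check(length(pos) >= 2 && length(neg) >= 2,
         "need >= 2 non-missing values per control arm (have %d and %d)",
         length(pos), length(neg))
  mu_pos <- mean(pos); mu_neg <- mean(neg)
  .check(mu_pos != mu_neg,
         "undefined separation on %s: both control means equal %s",
         plate_id, format(mu_pos))
  z <- 1 - 3 * (sd(pos) + sd(neg)) / abs(mu_pos - mu_neg)
  structure(list(plate_id = plate_id, mu_pos = mu_pos, mu_neg = mu_neg,
                 sd_pos = sd(pos), sd_neg = sd(neg), z = z),
            class = "zfactor_result")
}

#' Aggregate per-plate Z factors as mean +/- SEM
#'
#' Mirrors the screen-level reporting convention (e.g. a pilot screen
#' summarized as Z = 0.56 +/- 0.089, mean +/- SEM over plates).
#'
#' @param results A list of [z_factor()] results, or a numeric vector of z
#'   values.
#' @return List with `mean`, `sem` (sample SD / sqrt(n); missing when
#'   n = 1) and `n`.
#' @export
#' @examples
#' aggregate_z(c(0.4, 0.6))  # mean 0.5, SEM 0.1
aggregate_z <- function(results) {
  z <- if (is.numeric(results)) results else {
    vapply(results, function(r) {
      stopifnot(inherits(r, "zfactor_result")); r$z
    }, numeric(1))
  }
  z <- z[!is.na(z)]
  .check(length(z) >= 1, "no Z factors to aggregate")
  list(mean = mean(z),
       sem = if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_,
       n = length(z))
}
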