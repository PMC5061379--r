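#' Call hits above mean + k standard deviations
#'
#' The screen's selection rule: a compound is a hit when its readout lies
#' strictly more than `k` (default 3) sample standard deviations above the
#' mean of all tested compounds. Mean and SD are computed over the test
#' compounds themselves — controls are excluded upstream — so the threshold
#' adapts to each readout. Ties at the threshold are non-hits.
#'
#' @param values Named numeric vector (compound ID -> value) or a data frame
#'   with columns `compound_id` and `value`. At least 3 non-missing values.
#' @param k SD multiplier (default 3).
#' @param readout_name Label for the readout.
#' @return An object of class `hit_table`: list with `readout_name`, `n`,
#'   `mean`, `sd`, `k`, `threshold` (`mean + k * sd`) and `table`, a data
#'   frame of `compound_id`, `value`, `is_hit` sorted by decreasing value.
#' @export
#' @examples
#' v <- c(rep(1, 100), 2)
#' names(v) <- sprintf("C%03d", seq_along(v))
#' call_hits(v)$table$compound_id[call_hits(v)$table$is_hit]
call_hits <- function(values, k = 3, readout_name = "readout") {
  if (is.data.frame(values)) {
    .check(all(c("compound_id", "value") %in% names(values)),
           "values data frame needs columns compound_id, value")
    v <- setNames(values$value, values$compound_id)
  } else {
    .check(!is.null(names(values)), "values must carry compound IDs as names")
    v <- values
  }
  .check(k > 0, "k must be > 0")
  keep <- !is.na(v)
  .check(sum(keep) >= 3,
         "need >= 3 compounds with non-missing values (have %d)", sum(keep))
  m <- mean(v[keep]); s <- sd(v[keep])
  if (s == 0) warning("all compound values identical; zero hits by construction")
  threshold <- m + k * s
  tab <- data.frame(compound_id = names(v)[keep], value = unname(v[keep]))
  tab$is_hit <- tab$value > threshold
  tab <- tab[order(-tab$value), ]
  rownames(tab) <- NULL
  structure(list(readout_name = readout_name, n = nrow(tab), mean = m,
                 sd = s, k = k, threshold = threshold, table = tab),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf(
    "Hit table for '%s': %d compounds, mean %.4g, SD %.4g, threshold mean + %g SD = %.4g\n",
    x$readout_name, x$n, x$mean, x$sd, x$k, x$threshold))
  hits <- x$table[x$table$is_hit, ]
  cat(nrow(hits), "hit(s)\n")
  if (nrow(hits)) print(utils::head(hits, 20), row.names = FALSE)
  invisible(x)
}
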