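# Longitudinal growth traits: stage-wise average daily gain (ADG) from weekly
# body weights.

#' Compute stage-wise average daily gains from a weekly weight series
#'
#' Seventeen weekly weights per animal cover four consecutive 4-week growth
#' stages. The average daily gain at each stage (`ADG_1`..`ADG_4`, kg/day) is
#' the ordinary-least-squares slope of weight on day over five weight points;
#' consecutive windows share their boundary point (points 1-5, 5-9, 9-13,
#' 13-17), which is the only layout that reconciles 4 windows of five points
#' with 17 records. Regression uses the recorded day offsets, not nominal week
#' indices, so schedule jitter is tolerated.
#'
#' @param days integer vector of day offsets, strictly increasing (17 values
#'   for the standard layout).
#' @param weights numeric vector of body weights (kg), same length as `days`.
#' @return numeric vector of 4 slopes (kg/day), named `ADG_1`..`ADG_4`.
#' @examples
#' d <- seq(0, 112, by = 7)
#' compute_adg(d, 300 + 1.2 * d)  # all four slopes are 1.2
#' @export
compute_adg <- function(days, weights) {
  if (length(days) != length(weights))
    stopf("days and weights differ in length (%d vs %d)", length(days), length(weights))
  if (length(days) != 17L)
    stopf("expected 17 weight points per animal, got %d", length(days))
  if (anyDuplicated(days)) stopf("duplicate day stamps in weight series")
  if (is.unsorted(days, strictly = TRUE)) stopf("days must be strictly increasing")
  if (any(!is.finite(weights))) stopf("non-finite weight encountered")
  idx <- list(1:5, 5:9, 9:13, 13:17)
  adg <- vapply(idx, function(i) {
    x <- days[i] - mean(days[i])
    sum(x * (weights[i] - mean(weights[i]))) / sum(x^2)
  }, numeric(1))
  names(adg) <- paste0("ADG_", 1:4)
  adg
}

#' Compute the ADG table for all animals in a long-format weight table
#'
#' @param weights_df data frame with columns `animal`, `day`, `weight_kg`
#'   (the canonical weights TSV layout).
#' @return data frame with one row per animal: `animal`, `ADG_1`..`ADG_4`.
#' @export
adg_table <- function(weights_df) {
  need <- c("animal", "day", "weight_kg")
  if (!all(need %in% names(weights_df)))
    stopf("weights table must have columns: %s", paste(need, collapse = ", "))
  if (!is.numeric(weights_df$weight_kg))
    stopf("non-numeric weight_kg values in weights table")
  sp <- split(weights_df, weights_df$animal)
  out <- t(vapply(sp, function(d) {
    d <- d[order(d$day), ]
    compute_adg(d$day, d$weight_kg)
  }, numeric(4)))
  data.frame(animal = names(sp), out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}
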