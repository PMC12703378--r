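#' Gradient (rank-stratified) calibration/prediction split
#'
#' Deterministic rank-based partition of samples by a reference value.
#' Samples are sorted ascending by `y` (stable, so ties keep input order)
#' and walked in consecutive blocks of `sum(ratio)`; within each complete
#' block the samples ranked 2..(1+ratio\[2\]) go to the prediction set and
#' the rest to calibration; leftover samples (`n %% sum(ratio)`) go to
#' calibration. Because rank 1 and rank n are never in a block's prediction
#' slots, the minimum and maximum of `y` always land in the calibration
#' set, so the calibration range encloses the prediction range.
#'
#' With the default 3:1 ratio, `|prediction| = floor(n / 4)`; 145 samples
#' split into 109 calibration and 36 prediction samples.
#'
#' @param y finite numeric reference values, one per sample.
#' @param ids optional sample ids (defaults to indices).
#' @param ratio calibration:prediction ratio as an integer pair,
#'   default `c(3, 1)`.
#' @param target_parameter optional label of the reference variable that
#'   ordered the split (bookkeeping only).
#' @return an object of class `split_result`: a list with
#'   `calibration`/`prediction` index vectors (in original input order),
#'   the corresponding id vectors, `ratio` and `target_parameter`.
#' @examples
#' sp <- gradient_split(runif(145))
#' lengths(sp[c("calibration", "prediction")])  # 109, 36
#' @export
gradient_split <- function(y, ids = NULL, ratio = c(3, 1),
                           target_parameter = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y must be finite")
  ratio <- as.integer(ratio)
  if (length(ratio) != 2L || any(ratio < 1L))
    stop("ratio must be two positive integers (calibration, prediction)")
  n <- length(y)
  block <- sum(ratio)
  if (n < block) stop("need at least ", block, " samples for a ",
                      ratio[1L], ":", ratio[2L], " split")
  ids <- ids %||% as.character(seq_len(n))
  ord <- order(y)                       # stable: ties keep input order
  nblocks <- n %/% block
  pred_pos <- as.vector(outer(1L + seq_len(ratio[2L]),
                              (seq_len(nblocks) - 1L) * block, "+"))
  prediction <- sort(ord[pred_pos])
  calibration <- setdiff(seq_len(n), prediction)
  structure(list(calibration = calibration, prediction = prediction,
                 calibration_ids = ids[calibration],
                 prediction_ids = ids[prediction],
                 ratio = ratio, target_parameter = target_parameter),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction (ratio %d:%d%s)\n",
              length(x$calibration), length(x$prediction),
              x$ratio[1L], x$ratio[2L],
              if (!is.null(x$target_parameter))
                paste0(", ordered by ", x$target_parameter) else ""))
  invisible(x)
}

#' Write a split manifest
#'
#' Two-column CSV (`sample_id`, `subset`) recording set membership, for
#' reproducibility of a partition outside R.
#'
#' @param split a [gradient_split()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$calibration_ids, split$prediction_ids),
    subset = rep(c("calibration", "prediction"),
                 c(length(split$calibration), length(split$prediction))),
    stringsAsFactors = FALSE)
  df <- df[order(match(df$sample_id,
                       c(split$calibration_ids, split$prediction_ids))), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
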