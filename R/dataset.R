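#' Activity tables and rank-ordered train/test splitting
#'
#' Activity records are held as a plain data frame with columns `id`
#' (character), `logk7` (numeric, finite) and optionally `structure` (a list
#' column of [molecular_graph()] objects) or `smiles`.
#'
#' @param id character ids.
#' @param logk7 numeric activities, log10 of the chain-termination rate
#'   constant in L mol^-1 s^-1.
#' @param structure optional list of graphs (or anything else to carry along).
#' @return data.frame of class `activity_table`.
#' @export
activity_table <- function(id, logk7, structure = NULL) {
  id <- as.character(id)
  logk7 <- as.numeric(logk7)
  stopifnot(length(id) == length(logk7))
  if (anyDuplicated(id)) stop("duplicate record ids")
  if (any(!is.finite(logk7))) stop("logk7 must be finite")
  df <- data.frame(id = id, logk7 = logk7, stringsAsFactors = FALSE)
  if (!is.null(structure)) {
    stopifnot(length(structure) == length(id))
    df$structure <- I(unname(structure))
  }
  class(df) <- c("activity_table", "data.frame")
  df
}

#' Rank-ordered rational train/test split
#'
#' Records are sorted in ascending activity (ties broken by id), then every
#' `step`-th rank starting at `start_offset` is transferred to the test set
#' and the remainder forms the training set. With `step = 6` this is the 5:1
#' "every sixth compound" scheme; the starting rank is explicit because the
#' two printed set sizes of the source splits require different conventions
#' (148 -> 123/25 selects rank 1 first, 123 -> 103/20 selects rank 6 first).
#'
#' @param records an [activity_table()] (or data frame with `id`, `logk7`).
#' @param step integer >= 2, the split period (default 6).
#' @param start_offset first selected rank, in `1..step` (default 1).
#' @return List of class `split_result` with `train`, `test` (activity
#'   tables in rank order), `step`, `start_offset`.
#' @examples
#' recs <- activity_table(sprintf("c%03d", 1:148), seq(1, 8, length.out = 148))
#' s <- rational_split(recs, step = 6, start_offset = 1)
#' nrow(s$train); nrow(s$test)
#' @export
rational_split <- function(records, step = 6L, start_offset = 1L) {
  step <- as.integer(step); start_offset <- as.integer(start_offset)
  if (step < 2L) stop("step must be >= 2")
  if (start_offset < 1L || start_offset > step)
    stop("start_offset must lie in 1..step")
  ord <- order(records$logk7, records$id, method = "radix")
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  if (n < step) {
    warning("fewer records than step; all records assigned to training set")
    test_ranks <- integer(0)
  } else {
    test_ranks <- seq.int(start_offset, n, by = step)
  }
  structure(list(train = records[setdiff(seq_len(n), test_ranks), , drop = FALSE],
                 test = records[test_ranks, , drop = FALSE],
                 step = step, start_offset = start_offset),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("rational split (step %d, start %d): %d train / %d test\n",
              x$step, x$start_offset, nrow(x$train), nrow(x$test)))
  invisible(x)
}

#' Summary of a train/test split
#'
#' Reports, per set, the size, mean and range of `logk7`, and the percentage
#' of test records falling within +/- 0.5, 1.0, 1.5, 2.0 log-units of the
#' test mean and of the train mean (the usual response-distribution summary
#' for rationally split sets).
#'
#' @param s a [rational_split()] result.
#' @return List with `train` and `test` summaries (`n`, `mean`, `range`) and
#'   `bands`: data frame of band half-widths and percentages around each mean.
#' @export
split_report <- function(s) {
  stopifnot(inherits(s, "split_result"))
  if (!nrow(s$train) || !nrow(s$test)) stop("empty train or test set")
  y_tr <- s$train$logk7; y_ts <- s$test$logk7
  bands <- c(0.5, 1.0, 1.5, 2.0)
  pct <- function(center) vapply(bands, function(b)
    100 * mean(abs(y_ts - center) <= b), 0)
  list(train = list(n = length(y_tr), mean = mean(y_tr), range = diff(range(y_tr))),
       test = list(n = length(y_ts), mean = mean(y_ts), range = diff(range(y_ts))),
       bands = data.frame(half_width = bands,
                          pct_within_test_mean = pct(mean(y_ts)),
                          pct_within_train_mean = pct(mean(y_tr))))
}
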