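#' Nonparametric (cluster) bootstrap of an estimator
#'
#' Resampling engine used both as a fallback variance estimator and as an
#' independent check of the analytic sandwich/delta-method standard errors.
#' Rows are resampled with replacement; when `cluster` is given, whole
#' clusters are resampled (keeping within-cluster dependence intact).
#'
#' @param data data.frame to resample.
#' @param statistic function `data -> numeric vector` (e.g. refit +
#'   standardize + contrast); replicates where it errors are dropped with a
#'   message (non-degenerate fixtures should never error).
#' @param B number of bootstrap replicates.
#' @param cluster optional cluster column name.
#' @param seed integer seed for the resampling.
#' @return list with `se` (vector), `est` (B_ok x k matrix of replicate
#'   estimates), `B_ok` (replicates that succeeded).
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.3))
#' bootstrap_se(d, function(dd) mean(dd$y), B = 50, seed = 1)$se
#' @export
bootstrap_se <- function(data, statistic, B = 200, cluster = NULL, seed = 1) {
  stopifnot(is.function(statistic), B >= 2)
  set.seed(as.integer(seed))
  cl_ids <- if (!is.null(cluster)) {
    if (!cluster %in% names(data)) stop("cluster column '", cluster, "' not found")
    split(seq_len(nrow(data)), data[[cluster]])
  } else NULL
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- if (is.null(cl_ids)) {
      sample.int(nrow(data), replace = TRUE)
    } else {
      unlist(cl_ids[sample.int(length(cl_ids), replace = TRUE)],
             use.names = FALSE)
    }
    reps[[b]] <- tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
                          error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (any(!ok)) message(sum(!ok), " bootstrap replicate(s) failed and were dropped")
  est <- do.call(rbind, reps[ok])
  list(se = apply(est, 2L, stats::sd), est = est, B_ok = sum(ok))
}
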