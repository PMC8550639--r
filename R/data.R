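#' Longitudinal CTHMM dataset
#'
#' Irregularly timed longitudinal records for N subjects, stored in a
#' stacked (long) layout for fast likelihood evaluation: observation times,
#' a scalar outcome and a covariate matrix whose first column is the
#' intercept.  Each subject's times must be strictly increasing with the
#' first observation at time 0.
#'
#' @param df data frame in long format with columns \code{subject},
#'   \code{time}, \code{outcome} and optional covariate columns
#'   \code{z1, z2, ...} (\code{z1} is the intercept column of ones; if no
#'   covariate columns are present an intercept column is added).
#' @return An object of class \code{cthmm_data}.
#' @export
as_cthmm_data <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject", "time", "outcome")
  if (!all(need %in% names(df)))
    stop("data must have columns subject, time, outcome")
  zc <- grep("^z[0-9]+$", names(df), value = TRUE)
  zc <- zc[order(as.integer(sub("^z", "", zc)))]
  ids <- unique(df$subject)
  df$.sid <- match(df$subject, ids)
  df <- df[order(df$.sid, df$time), , drop = FALSE]
  if (length(zc) == 0L) {
    Z <- matrix(1, nrow(df), 1, dimnames = list(NULL, "z1"))
  } else {
    Z <- as.matrix(df[zc])
    if (any(Z[, 1] != 1)) stop("covariate column z1 must be the intercept (all ones)")
  }
  n_obs <- tabulate(df$.sid, nbins = length(ids))
  if (any(n_obs < 1L)) stop("every subject needs at least one observation")
  offsets <- c(0L, cumsum(n_obs))
  first <- df$time[offsets[-length(offsets)] + 1L]
  if (any(first != 0)) stop("each subject's first observation time must be 0")
  for (n in seq_along(ids)) {
    tt <- df$time[(offsets[n] + 1L):offsets[n + 1L]]
    if (any(diff(tt) <= 0)) stop("observation times must be strictly increasing per subject")
  }
  structure(list(n_subjects = length(ids), subject_ids = ids,
                 subject = df$.sid, time = as.numeric(df$time),
                 outcome = as.numeric(df$outcome), Z = Z,
                 offsets = as.integer(offsets)),
            class = "cthmm_data")
}

#' @export
print.cthmm_data <- function(x, ...) {
  cat(sprintf("<cthmm_data: %d subjects, %d observations, %d covariate column(s)>\n",
              x$n_subjects, length(x$outcome), ncol(x$Z)))
  invisible(x)
}

#' @export
as.data.frame.cthmm_data <- function(x, ...) {
  out <- data.frame(subject = x$subject_ids[x$subject], time = x$time,
                    outcome = x$outcome)
  cbind(out, as.data.frame(x$Z))
}

#' Read or write a CTHMM dataset as a delimited table
#'
#' Long format with header \code{subject,time,outcome,z1..zD}; the schema is
#' validated strictly on read.
#'
#' @param path file path.
#' @return [read_cthmm_data()] returns a \code{cthmm_data} object.
#' @export
read_cthmm_data <- function(path) {
  as_cthmm_data(read.csv(path, check.names = TRUE))
}

#' @rdname read_cthmm_data
#' @param data a \code{cthmm_data} object.
#' @export
write_cthmm_data <- function(data, path) {
  stopifnot(inherits(data, "cthmm_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subjects of one component; keeps the stacked layout
data_subset <- function(data, subjects) {
  subjects <- sort(unique(as.integer(subjects)))
  if (length(subjects) == 0L)
    return(structure(list(n_subjects = 0L, subject_ids = integer(0),
                          subject = integer(0), time = numeric(0),
                          outcome = numeric(0),
                          Z = data$Z[0, , drop = FALSE], offsets = 0L),
                     class = "cthmm_data"))
  keep <- data$subject %in% subjects
  sid <- match(data$subject[keep], subjects)
  n_obs <- tabulate(sid, nbins = length(subjects))
  structure(list(n_subjects = length(subjects),
                 subject_ids = data$subject_ids[subjects],
                 subject = sid, time = data$time[keep],
                 outcome = data$outcome[keep],
                 Z = data$Z[keep, , drop = FALSE],
                 offsets = as.integer(c(0L, cumsum(n_obs)))),
            class = "cthmm_data")
}

# empty dataset (flat-likelihood runs: every likelihood is 0)
empty_cthmm_data <- function(D = 1L) {
  structure(list(n_subjects = 0L, subject_ids = integer(0),
                 subject = integer(0), time = numeric(0), outcome = numeric(0),
                 Z = matrix(1, 0, D), offsets = 0L),
            class = "cthmm_data")
}
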