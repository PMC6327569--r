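#' Construct a longitudinal trial object
#'
#' Container for a two-arm longitudinal trial on the analysis scale
#' (e.g. square-root CD4 count): a wide outcome matrix with an
#' observed-data mask, per-patient arm labels and baseline age, and a
#' time-varying treatment-status indicator (e.g. ART).
#'
#' @param Y numeric matrix, patients x visits, outcome on the analysis
#'   scale. Cells that are missing must be `NA`.
#' @param arm integer vector per patient; 0 = control/placebo,
#'   1 = active.
#' @param visit_times numeric vector of visit times in months, strictly
#'   increasing, one per column of `Y`.
#' @param age numeric vector of baseline age in years per patient.
#' @param art matrix (patients x visits) of 0/1 treatment-status
#'   indicators, fully observed. Defaults to all zero.
#' @param patient_id identifiers; defaults to `1:N`.
#' @param R optional 0/1 mask; derived from `is.na(Y)` when omitted.
#'
#' @return An object of class `longitudinal_trial` with fields
#'   `Y`, `R`, `arm`, `visit_times`, `age`, `art`, `patient_id`.
#' @export
longitudinal_trial <- function(Y, arm, visit_times, age = NULL, art = NULL,
                               patient_id = NULL, R = NULL) {
  Y <- as.matrix(Y)
  N <- nrow(Y); J <- ncol(Y)
  if (is.null(R)) R <- 1L * !is.na(Y)
  R <- matrix(as.integer(R), N, J)
  if (length(visit_times) != J) stop("visit_times must match ncol(Y)")
  if (any(duplicated(visit_times)) || is.unsorted(visit_times, strictly = TRUE))
    stop("visit_times must be strictly increasing with no duplicates")
  if (length(arm) != N) stop("arm must have one entry per patient")
  if (is.null(age)) age <- rep(NA_real_, N)
  if (is.null(art)) art <- matrix(0L, N, J)
  art <- matrix(as.integer(art), N, J)
  if (is.null(patient_id)) patient_id <- seq_len(N)
  if (any(!is.na(Y) & R == 0L) || any(is.na(Y) & R == 1L))
    stop("Y[i,j] must be present iff R[i,j] == 1")
  if (any(R[, 1] == 0L))
    stop("baseline column must be fully observed")
  structure(
    list(patient_id = patient_id, Y = Y, R = R, arm = as.integer(arm),
         visit_times = as.numeric(visit_times), age = as.numeric(age),
         art = art),
    class = "longitudinal_trial")
}

#' @export
print.longitudinal_trial <- function(x, ...) {
  cat(sprintf(
    "longitudinal_trial: %d patients x %d visits (months %s)\n",
    nrow(x$Y), ncol(x$Y), paste(x$visit_times, collapse = ", ")))
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s=%d", names(table(x$arm)), table(x$arm)),
                    collapse = ", ")))
  cat(sprintf("  incomplete patients: %d (%.0f%%)\n",
              sum(rowSums(x$R) < ncol(x$R)),
              100 * mean(rowSums(x$R) < ncol(x$R))))
  invisible(x)
}

#' Number of patients / visits in a trial
#' @param trial a `longitudinal_trial`.
#' @return integer count.
#' @export
n_patients <- function(trial) nrow(trial$Y)

#' @rdname n_patients
#' @export
n_visits <- function(trial) ncol(trial$Y)

#' Load a trial from a long-format delimited file
#'
#' Reads a delimited text file with columns `id`, `arm`, `month`,
#' `outcome`, `art`, `age` (one row per patient-visit; `NA` or empty
#' outcome = missing) and reshapes it onto the scheduled visit grid.
#' Rows absent from the file at a scheduled month become missing.
#' Patients whose baseline outcome is missing, or with fewer than two
#' observed outcomes, are excluded with a message (mirroring the usual
#' inclusion rule of requiring at least two measurements).
#'
#' @param path file path.
#' @param schedule numeric vector of scheduled visit months.
#' @param sep field separator (default comma).
#' @return a [longitudinal_trial].
#' @export
load_trial <- function(path, schedule = c(0, 0.5, 1, 3, 6), sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("id", "arm", "month", "outcome", "art", "age")
  if (!all(need %in% names(d)))
    stop("file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d[, c("id", "month")]))
    stop("duplicate (id, month) rows in ", path)
  bad <- setdiff(unique(d$month), schedule)
  if (length(bad))
    stop("months not in schedule: ", paste(bad, collapse = ", "))
  ids <- unique(d$id)
  J <- length(schedule); N <- length(ids)
  Y <- matrix(NA_real_, N, J)
  art <- matrix(NA_integer_, N, J)
  arm <- integer(N); age <- numeric(N)
  for (i in seq_len(N)) {
    di <- d[d$id == ids[i], ]
    j <- match(di$month, schedule)
    Y[i, j] <- di$outcome
    art[i, j] <- di$art
    arm[i] <- di$arm[1]
    age[i] <- di$age[1]
  }
  # treatment status is a known covariate: carry the last seen value
  # forward (and the first seen value backward) over absent rows
  for (i in seq_len(N)) {
    v <- art[i, ]
    if (all(is.na(v))) { art[i, ] <- 0L; next }
    for (j in seq_len(J)) if (is.na(v[j])) v[j] <- if (j > 1) v[j - 1] else NA
    for (j in rev(seq_len(J - 1))) if (is.na(v[j])) v[j] <- v[j + 1]
    art[i, ] <- v
  }
  no_base <- is.na(Y[, 1])
  if (any(no_base))
    warning(sum(no_base), " patient(s) excluded: baseline outcome missing")
  few <- rowSums(!is.na(Y)) < 2
  drop <- no_base | few
  if (any(few & !no_base))
    message(sum(few & !no_base),
            " patient(s) excluded: fewer than two observed outcomes")
  keep <- !drop
  longitudinal_trial(Y[keep, , drop = FALSE], arm[keep], schedule,
                     age[keep], art[keep, , drop = FALSE],
                     patient_id = ids[keep])
}

#' Write a trial to a long-format delimited file
#'
#' Inverse of [load_trial()]: one row per patient per scheduled visit
#' with an observed outcome (missing cells are omitted, so the file
#' round-trips through `load_trial`).
#'
#' @param trial a [longitudinal_trial].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, sep = ",") {
  N <- n_patients(trial); J <- n_visits(trial)
  rows <- do.call(rbind, lapply(seq_len(N), function(i) {
    j <- which(trial$R[i, ] == 1L)
    data.frame(id = trial$patient_id[i], arm = trial$arm[i],
               month = trial$visit_times[j], outcome = trial$Y[i, j],
               art = trial$art[i, j], age = trial$age[i])
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a trial to long format
#'
#' @param trial a [longitudinal_trial].
#' @param observed_only drop rows whose outcome is missing (default
#'   `TRUE`).
#' @return data.frame with columns `id`, `arm` (`trt`), `month`, `y`,
#'   `art`, `age`.
#' @export
as_long <- function(trial, observed_only = TRUE) {
  N <- n_patients(trial); J <- n_visits(trial)
  d <- data.frame(
    id = rep(trial$patient_id, each = J),
    trt = rep(trial$arm, each = J),
    month = rep(trial$visit_times, N),
    y = as.vector(t(trial$Y)),
    art = as.vector(t(trial$art)),
    age = rep(trial$age, each = J))
  if (observed_only) d <- d[as.vector(t(trial$R)) == 1L, ]
  rownames(d) <- NULL
  d
}

#' Last observed visit and intermittent gaps per patient
#'
#' For each patient, `n_last` is the index (1-based over the schedule)
#' of the last observed visit -- the deviation time; `intermittent`
#' lists missing visit indices strictly before it. A patient (and a
#' trial) is monotone when there are no intermittent gaps.
#'
#' @param trial a [longitudinal_trial].
#' @return list with `n_last` (integer vector), `intermittent` (list of
#'   integer vectors) and `is_monotone` (logical vector).
#' @export
deviation_time <- function(trial) {
  N <- n_patients(trial)
  n_last <- integer(N)
  inter <- vector("list", N)
  for (i in seq_len(N)) {
    obs <- which(trial$R[i, ] == 1L)
    n_last[i] <- max(obs)
    inter[[i]] <- setdiff(seq_len(n_last[i] - 1L), obs)
  }
  list(n_last = n_last, intermittent = inter,
       is_monotone = lengths(inter) == 0L)
}

#' Tabulate missingness patterns by arm
#'
#' Groups patients by their observed/missing vector over the visit
#' schedule and tallies counts and proportions per arm, together with
#' per-pattern per-visit means of the observed outcomes. The observed
#' data distribution is then a mixture over these patterns with the
#' per-arm proportions as weights.
#'
#' @param trial a [longitudinal_trial].
#' @return object of class `pattern_table`: `patterns` (U x J 0/1
#'   matrix, ordered with completers first), `counts` and `proportions`
#'   (U x arms matrices), `means` (U x J x arms array, `NA` where a
#'   pattern has no observation at a visit), `arms` (arm labels).
#' @export
classify_patterns <- function(trial) {
  J <- n_visits(trial)
  key <- apply(trial$R, 1, paste, collapse = "")
  # order patterns by number of observed visits (completers first),
  # then lexicographically for determinism
  uk <- unique(key)
  uk <- uk[order(-vapply(strsplit(uk, ""), function(s) sum(s == "1"), 0),
                 uk)]
  U <- length(uk)
  arms <- sort(unique(trial$arm))
  patterns <- t(vapply(strsplit(uk, ""), function(s) as.integer(s),
                       integer(J)))
  counts <- matrix(0L, U, length(arms),
                   dimnames = list(NULL, paste0("arm", arms)))
  means <- array(NA_real_, c(U, J, length(arms)))
  for (a in seq_along(arms)) {
    ina <- trial$arm == arms[a]
    for (u in seq_len(U)) {
      inu <- ina & key == uk[u]
      counts[u, a] <- sum(inu)
      if (any(inu)) {
        for (j in which(patterns[u, ] == 1L))
          means[u, j, a] <- mean(trial$Y[inu, j])
      }
    }
  }
  props <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  structure(list(patterns = patterns, counts = counts,
                 proportions = props, means = means, arms = arms),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("pattern_table: %d patterns x %d arms\n",
              nrow(x$counts), length(x$arms)))
  lab <- apply(x$patterns, 1, paste, collapse = "")
  df <- data.frame(pattern = lab, x$counts, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Chi-squared homogeneity test of patterns across arms
#'
#' Pearson chi-squared test of whether the distribution of missingness
#' patterns differs between treatment arms, computed on the
#' arms x patterns contingency table. Patterns with zero total count
#' are dropped (their expected counts would be zero); the degrees of
#' freedom reflect kept patterns only.
#'
#' @param table a `pattern_table` from [classify_patterns()], or a
#'   counts matrix (patterns x arms).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pattern_arm_chisq <- function(table) {
  counts <- if (inherits(table, "pattern_table")) table$counts else
    as.matrix(table)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < 2)
    stop("need at least 2 patterns with nonzero total count")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Pattern summary report
#'
#' One row per pattern per arm with count, percentage of the arm and
#' per-visit means of the observed outcomes, plus the fraction of each
#' arm deviating (1 - completers / arm size, reported to the whole
#' percent).
#'
#' @param trial a [longitudinal_trial].
#' @return data.frame with columns `arm`, `pattern` (observed/missing
#'   string), `n`, `pct`, `deviating_pct` (per arm, repeated), and one
#'   `mean_m<month>` column per visit (`NA` where unobserved).
#' @export
summarize_patterns <- function(trial) {
  pt <- classify_patterns(trial)
  J <- n_visits(trial)
  complete <- which(rowSums(pt$patterns) == J)
  out <- list()
  for (a in seq_along(pt$arms)) {
    sz <- sum(pt$counts[, a])
    n_comp <- if (length(complete)) sum(pt$counts[complete, a]) else 0L
    dev_pct <- round(100 * (1 - n_comp / sz))
    for (u in seq_len(nrow(pt$counts))) {
      if (pt$counts[u, a] == 0) next
      row <- data.frame(
        arm = pt$arms[a],
        pattern = paste(pt$patterns[u, ], collapse = ""),
        n = pt$counts[u, a],
        pct = round(100 * pt$proportions[u, a]),
        deviating_pct = dev_pct)
      m <- as.data.frame(t(pt$means[u, , a]))
      names(m) <- paste0("mean_m", trial$visit_times)
      out[[length(out) + 1L]] <- cbind(row, m)
    }
  }
  do.call(rbind, out)
}

#' Write a pattern report as delimited text
#'
#' Mirrors the usual published layout: pattern id, per-visit mean or
#' `-`, N and percentage, by arm.
#'
#' @param trial a [longitudinal_trial].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(trial, path, sep = ",") {
  rep <- summarize_patterns(trial)
  mcols <- grep("^mean_m", names(rep))
  for (j in mcols) {
    v <- sprintf("%.2f", rep[[j]])
    v[is.na(rep[[j]])] <- "-"
    rep[[j]] <- v
  }
  utils::write.table(rep, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
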