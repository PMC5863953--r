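#' Root-mean-squared tracking error
#'
#' RMS of the pointwise difference between cursor and target over a trial.
#'
#' @param cursor,target Equal-length numeric series (degrees).
#' @return RMS error in the input units.
#' @export
tracking_error <- function(cursor, target) {
  if (length(cursor) != length(target)) {
    stop("length mismatch: cursor has ", length(cursor),
         " samples, target has ", length(target), call. = FALSE)
  }
  sqrt(mean((cursor - target)^2))
}

#' Simulated effort proxy
#'
#' Mean absolute motor torque over the trial, the simulation analogue of the
#' torque-calibrated mean muscle activation measured empirically.
#'
#' @param u Torque series, Nm.
#' @return Mean |u| in Nm.
#' @export
simulated_effort <- function(u) mean(abs(u))

#' Relative interaction effort
#'
#' `alpha_c / alpha - 1` by default: positive when more effort is spent
#' connected than solo. The reciprocal convention (`alpha / alpha_c - 1`) is
#' available via `definition = "solo_over_connected"`.
#'
#' @param alpha_solo Solo-trial effort (> 0).
#' @param alpha_connected Connected-trial effort.
#' @param definition `"connected_over_solo"` (default) or
#'   `"solo_over_connected"`.
#' @return Dimensionless relative effort; `NA` (with a warning) when the
#'   denominator is zero.
#' @export
interaction_effort <- function(alpha_solo, alpha_connected,
                               definition = c("connected_over_solo",
                                              "solo_over_connected")) {
  definition <- match.arg(definition)
  denom <- if (definition == "connected_over_solo") alpha_solo else alpha_connected
  num <- if (definition == "connected_over_solo") alpha_connected else alpha_solo
  out <- num / denom - 1
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero denominator effort excluded")
    out[zero] <- NA_real_
  }
  out
}

#' Pair solo trials with their preceding connected trials
#'
#' Each solo trial is paired with the nearest preceding connected trial
#' within the same stiffness block; solo trials with no preceding connected
#' trial in the block are dropped (their count is reported as an attribute).
#' From each pair and for each subject the paired outcomes are computed:
#' improvement `delta_c = 1 - e_c/e`, relative error `delta_p = 1 - e_p/e`
#' and interaction effort `E`.
#'
#' @param metrics A data.frame with one row per (trial, subject):
#'   columns `trial`, `subject` (1 or 2), `error_deg`, `effort`.
#' @param schedule A [build_schedule()] object covering those trials.
#' @param dyad Dyad identifier attached to the output (default 1).
#' @param effort_definition Passed to [interaction_effort()].
#' @param direction `"solo_after_connected"` (default: a solo trial is
#'   scored against the connected trial before it) or
#'   `"connected_after_solo"` (the reverse reading).
#' @return A data.frame of paired outcomes, one row per (pair, subject):
#'   `dyad`, `subject`, `block`, `level`, `stiffness`, `kappa`
#'   (log10 stiffness), `solo_trial`, `conn_trial`, `e`, `e_c`, `e_p`,
#'   `alpha`, `alpha_c`, `delta_c`, `delta_p`, `effort` — with attribute
#'   `n_unpaired`.
#' @export
pair_trials <- function(metrics, schedule, dyad = 1,
                        effort_definition = "connected_over_solo",
                        direction = c("solo_after_connected",
                                      "connected_after_solo")) {
  direction <- match.arg(direction)
  stopifnot(all(c("trial", "subject", "error_deg", "effort") %in%
                  names(metrics)))
  sched <- as.data.frame(schedule)
  rows <- list()
  n_unpaired <- 0L
  for (b in unique(sched$block)) {
    blk <- sched[sched$block == b, ]
    solo_tr <- blk$trial[!blk$connected]
    conn_tr <- blk$trial[blk$connected]
    if (direction == "connected_after_solo") {
      # reverse reading: each connected trial against the preceding solo
      anchor <- conn_tr; pool <- solo_tr
    } else {
      anchor <- solo_tr; pool <- conn_tr
    }
    for (tr in anchor) {
      prev <- pool[pool < tr]
      if (length(prev) == 0) {
        n_unpaired <- n_unpaired + 1L
        next
      }
      mate <- max(prev)
      solo_t <- if (direction == "solo_after_connected") tr else mate
      conn_t <- if (direction == "solo_after_connected") mate else tr
      m_solo <- metrics[metrics$trial == solo_t, ]
      m_conn <- metrics[metrics$trial == conn_t, ]
      if (nrow(m_solo) < 2 || nrow(m_conn) < 2) next
      for (subj in 1:2) {
        e <- m_solo$error_deg[m_solo$subject == subj]
        e_p <- m_solo$error_deg[m_solo$subject == (3 - subj)]
        e_c <- m_conn$error_deg[m_conn$subject == subj]
        a <- m_solo$effort[m_solo$subject == subj]
        a_c <- m_conn$effort[m_conn$subject == subj]
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = dyad, subject = subj, block = b, level = blk$level[1],
          stiffness = blk$stiffness[1], kappa = log10(blk$stiffness[1]),
          solo_trial = solo_t, conn_trial = conn_t,
          e = e, e_c = e_c, e_p = e_p, alpha = a, alpha_c = a_c,
          delta_c = 1 - e_c / e, delta_p = 1 - e_p / e,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    warning("no valid solo/connected pairs in any block")
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    out$effort <- interaction_effort(out$alpha, out$alpha_c,
                                     definition = effort_definition)
  }
  attr(out, "n_unpaired") <- n_unpaired
  class(out) <- c("paired_outcomes", "data.frame")
  out
}

#' Per-dyad role means of paired outcomes
#'
#' Labels the better and worse partner of each dyad (by mean relative error:
#' the worse partner has `delta_p > 0` on average, i.e. a larger solo error
#' than the partner) and averages improvement and effort per
#' dyad x role x stiffness cell, the layout the repeated-measures ANOVA and
#' the one-sample effort tests operate on.
#'
#' @param paired A [pair_trials()] table (possibly several dyads).
#' @return data.frame with `dyad`, `role` ("better"/"worse"), `level`,
#'   `stiffness`, `kappa`, `delta_c`, `effort`.
#' @export
role_means <- function(paired) {
  out <- list()
  for (d in unique(paired$dyad)) {
    pd <- paired[paired$dyad == d, ]
    mean_dp <- tapply(pd$delta_p, pd$subject, mean)
    worse <- as.integer(names(which.max(mean_dp)))
    for (subj in unique(pd$subject)) {
      role <- if (subj == worse) "worse" else "better"
      for (lev in unique(pd$level)) {
        cell <- pd[pd$subject == subj & pd$level == lev, ]
        if (nrow(cell) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          dyad = d, role = role, level = lev,
          stiffness = cell$stiffness[1], kappa = cell$kappa[1],
          delta_c = mean(cell$delta_c), delta_p = mean(cell$delta_p),
          effort = mean(cell$effort, na.rm = TRUE),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Write a paired-outcome table to CSV
#'
#' @param paired A [pair_trials()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(paired, path) {
  utils::write.csv(as.data.frame(paired), path, row.names = FALSE)
  invisible(path)
}
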